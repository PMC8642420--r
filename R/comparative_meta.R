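#' Meta-analyze MR estimates across strata
#'
#' Inverse-variance fixed-effects pooling with weights `1/se^2`; when the
#' between-study Cochran-Q p-value falls below `het_alpha`, a
#' DerSimonian-Laird random-effects model is used instead, with
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` and weights
#' `1/(se^2 + tau^2)`.
#'
#' @param estimates list of at least two [mr_estimate()] objects for the
#'   same outcome and direction convention.
#' @param het_alpha heterogeneity trigger for switching to random effects.
#'   Default 0.05.
#' @return list of class `meta_result`: `pooled` ([mr_estimate()]), `model`
#'   (`"fixed"` or `"random"`), `tau2`, `q_stat`/`q_df`/`q_pval`, and
#'   `inputs` (stratum labels).
#' @export
meta_analyze <- function(estimates, het_alpha = 0.05) {
  if (length(estimates) < 2L) {
    stop("meta-analysis requires at least 2 estimates", call. = FALSE)
  }
  b <- vapply(estimates, function(e) e$beta, numeric(1))
  s <- vapply(estimates, function(e) e$se, numeric(1))
  labs <- vapply(estimates, function(e)
    paste(stats::na.omit(c(e$stratum, e$outcome)), collapse = "|"),
    character(1))
  w <- 1 / s^2
  beta_fe <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta_fe)^2)
  df <- length(b) - 1L
  q_pval <- stats::pchisq(q, df, lower.tail = FALSE)

  model <- "fixed"
  tau2 <- 0
  if (q_pval < het_alpha) {
    model <- "random"
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  }
  wstar <- 1 / (s^2 + tau2)
  beta <- sum(wstar * b) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  pooled <- mr_estimate(
    beta, se, method = paste0("meta_", model),
    n_snps = max(vapply(estimates, function(e) e$n_snps, integer(1))),
    q_stat = q, q_df = df, q_pval = q_pval,
    outcome = estimates[[1]]$outcome
  )
  structure(list(pooled = pooled, model = model, tau2 = tau2,
                 q_stat = q, q_df = df, q_pval = q_pval, inputs = labs),
            class = "meta_result")
}

#' Test the difference between two stratum estimates
#'
#' Two-sample z-test assuming independent strata:
#' `z = (beta1 - beta2)/sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value. Used for sex differences within a population and for ethnic
#' differences between populations.
#'
#' @param e1,e2 [mr_estimate()] objects for the same outcome.
#' @return list of class `difference_test`: `delta`, `se_delta`, `z`,
#'   `pval`, `pair`.
#' @export
difference_test <- function(e1, e2) {
  delta <- e1$beta - e2$beta
  se_delta <- sqrt(e1$se^2 + e2$se^2)
  z <- delta / se_delta
  structure(list(
    delta = delta, se_delta = se_delta, z = z,
    pval = 2 * stats::pnorm(-abs(z)),
    pair = c(e1$stratum %||% "stratum1", e2$stratum %||% "stratum2")
  ), class = "difference_test")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate. Default 0.05.
#' @param n_phenotypes number of phenotypes tested (>= 1).
#' @return `alpha / n_phenotypes`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_phenotypes) {
  if (n_phenotypes < 1) stop("n_phenotypes must be >= 1", call. = FALSE)
  alpha / n_phenotypes
}

#' Annotate p-values against nominal and Bonferroni thresholds
#'
#' @param pval numeric vector of p-values.
#' @param alpha nominal level. Default 0.05.
#' @param n_phenotypes number of phenotypes for the Bonferroni correction.
#'   Default 10.
#' @return character vector: `"significant"` (below the corrected
#'   threshold), `"nominal"` (below `alpha` but not the corrected
#'   threshold), or `"null"`.
#' @export
annotate_significance <- function(pval, alpha = 0.05, n_phenotypes = 10) {
  thr <- bonferroni_threshold(alpha, n_phenotypes)
  ifelse(pval < thr, "significant",
         ifelse(pval < alpha, "nominal", "null"))
}
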