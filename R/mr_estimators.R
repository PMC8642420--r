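Z95 <- stats::qnorm(0.975)

#' Construct an MR estimate
#'
#' Container for a causal estimate on the log odds ratio scale per SD unit
#' of the exposure. The 95% CI uses the normal reference distribution
#' (beta +/- 1.959964 se) and the p-value is the two-sided normal tail,
#' matching the reporting convention of summary-level MR.
#'
#' @param beta causal log-OR per SD of exposure.
#' @param se standard error of `beta` (> 0).
#' @param method one of `"wald"`, `"ivw_fixed"`, `"ivw_random"`,
#'   `"ivw_correlated"`, or a meta-analysis label.
#' @param n_snps number of instruments behind the estimate.
#' @param q_stat,q_df,q_pval Cochran-Q heterogeneity results (NA when
#'   `n_snps < 2`).
#' @param outcome,stratum optional labels for reporting.
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(beta, se, method, n_snps,
                        q_stat = NA_real_, q_df = NA_real_,
                        q_pval = NA_real_,
                        outcome = NA_character_, stratum = NA_character_) {
  stopifnot(is.finite(beta), is.finite(se), se > 0, n_snps >= 1)
  structure(list(
    beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pval = 2 * stats::pnorm(-abs(beta) / se),
    method = method, n_snps = as.integer(n_snps),
    q_stat = q_stat, q_df = q_df, q_pval = q_pval,
    outcome = outcome, stratum = stratum
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s, %d SNP%s]\n", x$method, x$n_snps,
              if (x$n_snps > 1) "s" else ""))
  cat(sprintf("  log-OR %.4f (SE %.4f)  OR %.2f (95%% CI %.2f, %.2f)  p = %.3g\n",
              x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
              x$pval))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Cochran Q = %.3f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pval))
  }
  invisible(x)
}

#' Bundle harmonized instruments with their correlation structure
#'
#' @param instruments a `harmonized` data.frame (dropped rows are removed).
#' @param correlation optional [ld_matrix()] aligned to the instruments
#'   (required for `mode = "all_correlated"`).
#' @param mode `"lead_snp"` (exactly one instrument), `"independent"`
#'   (pairwise r-squared below the pruning threshold), or
#'   `"all_correlated"` (every SNP plus its correlation matrix).
#' @return list of class `instrument_set`.
#' @export
instrument_set <- function(instruments, correlation = NULL,
                           mode = c("independent", "lead_snp",
                                    "all_correlated")) {
  mode <- match.arg(mode)
  instruments <- instruments[!instruments$dropped, , drop = FALSE]
  if (nrow(instruments) == 0L) stop("empty instrument set", call. = FALSE)
  if (mode == "lead_snp" && nrow(instruments) != 1L) {
    stop("lead_snp mode requires exactly one instrument", call. = FALSE)
  }
  if (mode == "all_correlated") {
    if (is.null(correlation)) {
      stop("all_correlated mode requires a correlation matrix",
           call. = FALSE)
    }
    if (!identical(rownames(correlation), instruments$snp_id)) {
      stop("correlation matrix order must equal the instrument order",
           call. = FALSE)
    }
  }
  structure(list(instruments = instruments, correlation = correlation,
                 mode = mode), class = "instrument_set")
}

as_instruments <- function(x) {
  if (inherits(x, "instrument_set")) x$instruments
  else x[!x$dropped, , drop = FALSE]
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect is the ratio of the SNP-outcome association to the
#' SNP-exposure association. The standard error uses the first-order delta
#' method (outcome noise only), the form whose inverse square is the IVW
#' weight; the second-order term adding exposure noise is available via
#' `second_order_se`.
#'
#' @param inst one-row `harmonized` data.frame (or `instrument_set` with
#'   one instrument).
#' @param second_order_se include the exposure-noise term
#'   `se_out^2/bx^2 + by^2 se_x^2/bx^4` in the variance. Default FALSE.
#' @return [mr_estimate()] with `method = "wald"`.
#' @export
wald_ratio <- function(inst, second_order_se = FALSE) {
  h <- as_instruments(inst)
  stopifnot(nrow(h) == 1L)
  bx <- h$beta_exposure; by <- h$beta_outcome
  if (bx == 0) stop("null instrument: beta_exposure is zero", call. = FALSE)
  beta <- by / bx
  v <- h$se_outcome^2 / bx^2
  if (second_order_se) v <- v + by^2 * h$se_exposure^2 / bx^4
  mr_estimate(beta, sqrt(v), method = "wald", n_snps = 1L)
}

ratio_components <- function(h) {
  if (any(h$beta_exposure == 0)) {
    stop("null instrument: beta_exposure is zero", call. = FALSE)
  }
  list(theta = h$beta_outcome / h$beta_exposure,
       w = (h$beta_exposure / h$se_outcome)^2)
}

#' Cochran's Q heterogeneity statistic for a set of Wald ratios
#'
#' Q is the IVW-weighted sum of squared deviations of the per-SNP ratios
#' from a pooled estimate; under homogeneity it is chi-square with
#' `n_snps - 1` degrees of freedom.
#'
#' @param instruments `harmonized` data.frame or `instrument_set` with at
#'   least two instruments.
#' @param beta_ivw pooled estimate to measure deviations from; defaults to
#'   the fixed-effects IVW estimate of the same instruments.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(instruments, beta_ivw = NULL) {
  h <- as_instruments(instruments)
  if (nrow(h) < 2L) stop("Cochran Q requires at least 2 SNPs", call. = FALSE)
  rc <- ratio_components(h)
  if (is.null(beta_ivw)) beta_ivw <- sum(rc$w * rc$theta) / sum(rc$w)
  q <- sum(rc$w * (rc$theta - beta_ivw)^2)
  df <- nrow(h) - 1L
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance weighted estimate from independent instruments
#'
#' Per-SNP Wald ratios are pooled with weights `(beta_exposure/se_outcome)^2`
#' (equivalently, weighted least squares of the outcome betas on the
#' exposure betas through the origin with weights `1/se_outcome^2`). With
#' `random_effects_min_snps` instruments or more, a multiplicative
#' overdispersion model is applied: the SE is scaled by
#' `max(1, sqrt(Q/(n-2)))`, never shrinking below the fixed-effects SE.
#' With fewer instruments the fixed-effects estimate is returned, following
#' the rule of fixed effects for three SNPs or fewer and random effects for
#' four or more.
#'
#' @param instruments `harmonized` data.frame or `instrument_set` with
#'   `mode` `"independent"` or `"lead_snp"`.
#' @param random_effects_min_snps minimum SNP count at which the
#'   multiplicative random-effects scaling applies. Default 4.
#' @return [mr_estimate()] with `method` `"ivw_fixed"` or `"ivw_random"`
#'   (or `"wald"` for a single instrument).
#' @export
ivw <- function(instruments, random_effects_min_snps = 4L) {
  h <- as_instruments(instruments)
  if (nrow(h) == 0L) stop("empty instrument set", call. = FALSE)
  if (nrow(h) == 1L) return(wald_ratio(h))
  rc <- ratio_components(h)
  beta <- sum(rc$w * rc$theta) / sum(rc$w)
  se <- 1 / sqrt(sum(rc$w))
  q <- cochran_q(h, beta)
  method <- "ivw_fixed"
  if (nrow(h) >= random_effects_min_snps) {
    phi <- max(1, sqrt(q$q_stat / (nrow(h) - 2)))
    se <- se * phi
    method <- "ivw_random"
  }
  mr_estimate(beta, se, method = method, n_snps = nrow(h),
              q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval)
}

#' IVW estimate for correlated instruments (generalized least squares)
#'
#' With instruments in linkage disequilibrium, the outcome betas are
#' correlated: `Omega = S rho S` where `S = diag(se_outcome)` and `rho` is
#' the signed LD correlation matrix aligned to the harmonized effect
#' alleles. The estimate is the GLS solution
#' `beta = (x' Omega^-1 x)^-1 x' Omega^-1 y` with
#' `se = sqrt((x' Omega^-1 x)^-1)`, solved through a Cholesky
#' decomposition rather than an explicit inverse. A singular `Omega`
#' (e.g. duplicate SNPs in perfect LD) is an error; a small `ridge` added
#' to the diagonal of `rho` can regularize near-singular blocks.
#'
#' @param instruments `instrument_set` with `mode = "all_correlated"`, or a
#'   `harmonized` data.frame plus `correlation`.
#' @param correlation [ld_matrix()] aligned to the instruments; taken from
#'   the `instrument_set` when absent.
#' @param ridge nonnegative diagonal inflation of `rho`. Default 0.
#' @return [mr_estimate()] with `method = "ivw_correlated"`.
#' @export
ivw_correlated <- function(instruments, correlation = NULL, ridge = 0) {
  h <- as_instruments(instruments)
  if (is.null(correlation) && inherits(instruments, "instrument_set")) {
    correlation <- instruments$correlation
  }
  if (is.null(correlation)) {
    stop("correlated IVW requires a correlation matrix", call. = FALSE)
  }
  if (!identical(rownames(correlation), h$snp_id)) {
    stop("correlation matrix order must equal the instrument order",
         call. = FALSE)
  }
  x <- h$beta_exposure
  y <- h$beta_outcome
  s <- h$se_outcome
  rho <- unclass(correlation)
  if (ridge > 0) {
    rho <- rho + diag(ridge, nrow(rho))
    rho <- rho / (1 + ridge)
  }
  omega <- rho * tcrossprod(s)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) <= max(diag(ch)) * 1e-10)) {
    stop("singular outcome covariance; consider estimator.ridge > 0 ",
         "or removing duplicate SNPs in perfect LD", call. = FALSE)
  }
  # whitened regression through the origin: solve L z = v for x and y
  zx <- backsolve(ch, x, transpose = TRUE)
  zy <- backsolve(ch, y, transpose = TRUE)
  xtox <- sum(zx^2)
  beta <- sum(zx * zy) / xtox
  se <- 1 / sqrt(xtox)
  q <- if (nrow(h) >= 2) cochran_q(h) else
    list(q_stat = NA_real_, q_df = NA_real_, q_pval = NA_real_)
  mr_estimate(beta, se, method = "ivw_correlated", n_snps = nrow(h),
              q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval)
}
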