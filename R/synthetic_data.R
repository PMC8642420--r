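#' Autoregressive LD block
#'
#' Correlation `r[i,j] = decay^|i-j|`, the standard AR(1) stand-in for the
#' decaying correlation structure of a small cis region. Positive
#' semi-definite by construction for `decay` in `[0, 1)`.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param decay correlation between adjacent SNPs, in `[0, 1)`.
#' @param snp_ids optional rsIDs; defaults to `snp1..snpN`.
#' @return an [ld_matrix()].
#' @export
make_ld_block <- function(n_snps, decay, snp_ids = NULL) {
  stopifnot(n_snps >= 1)
  if (decay < 0 || decay >= 1) {
    stop("decay must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snps))
  idx <- seq_len(n_snps)
  r <- decay^abs(outer(idx, idx, "-"))
  ld_matrix(r, snp_ids)
}

#' Parameterize a two-sample summary-statistics simulation
#'
#' Describes a full two-sample MR world with known ground truth: per-SNP
#' true exposure effects and allele frequencies, an LD correlation
#' structure, exposure and outcome sample sizes, the outcome case
#' fraction, the true causal log-OR per SD of exposure, an optional
#' balanced-pleiotropy knob, and the scale on which the outcome GWAS
#' reports (log-OR directly, or linear-probability as large biobank
#' linear-regression GWAS do).
#'
#' @param n_snps number of instruments.
#' @param ld [ld_matrix()] or a scalar AR(1) decay parameter.
#' @param beta_gx per-SNP true exposure effects (SD units per allele).
#' @param maf per-SNP effect-allele frequencies, in (0, 0.5].
#' @param n_exposure,n_outcome sample sizes of the two (non-overlapping)
#'   GWAS.
#' @param k outcome case fraction, in (0,1).
#' @param theta true causal log-OR per SD increase in the exposure.
#' @param pleiotropy_sd SD of per-SNP direct effects on the outcome
#'   (balanced pleiotropy). Default 0.
#' @param outcome_scale `"log_or"` or `"linear"`.
#' @param snp_ids optional rsIDs.
#' @param seed integer seed making the draw reproducible.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_snps = 6L,
                         ld = 0.7,
                         beta_gx = NULL,
                         maf = NULL,
                         n_exposure = 361194L,
                         n_outcome = 192000L,
                         k = 0.04,
                         theta = 0,
                         pleiotropy_sd = 0,
                         outcome_scale = c("log_or", "linear"),
                         snp_ids = NULL,
                         seed = 1L) {
  outcome_scale <- match.arg(outcome_scale)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snps))
  if (is.null(beta_gx)) {
    # lead-SNP-dominant profile: one strong cis signal, weaker satellites
    beta_gx <- c(0.062, 0.035, 0.030, 0.028, 0.025, 0.020,
                 rep(0.02, max(0, n_snps - 6L)))[seq_len(n_snps)]
  }
  if (is.null(maf)) {
    maf <- c(0.39, 0.47, 0.35, 0.13, 0.42, 0.22,
             rep(0.3, max(0, n_snps - 6L)))[seq_len(n_snps)]
  }
  if (is.numeric(ld) && length(ld) == 1L) {
    ld <- make_ld_block(n_snps, ld, snp_ids)
  }
  stopifnot(length(beta_gx) == n_snps, length(maf) == n_snps,
            nrow(ld) == n_snps,
            all(maf > 0), all(maf <= 0.5),
            k > 0, k < 1, n_exposure > 0, n_outcome > 0,
            pleiotropy_sd >= 0)
  structure(list(
    n_snps = as.integer(n_snps), ld = ld_matrix(unclass(ld), snp_ids),
    beta_gx = beta_gx, maf = maf,
    n_exposure = n_exposure, n_outcome = n_outcome, k = k,
    theta = theta, pleiotropy_sd = pleiotropy_sd,
    outcome_scale = outcome_scale, snp_ids = snp_ids,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

#' Default scenario: a statin-target-like cis region
#'
#' Six correlated SNPs in one gene region with a dominant lead SNP, an
#' exposure GWAS of 361,194 individuals on the SD scale (the size of the
#' UK Biobank lipid GWAS), and a hospital-registry-scale binary outcome
#' GWAS (192,000 individuals, 4% cases, reported on the log-OR scale).
#' Adjacent-SNP correlation 0.7 keeps every pair above the r-squared
#' pruning threshold of 0.01, so pruning retains only the lead SNP, as in
#' a single-lead-SNP main analysis.
#'
#' @param ... overrides passed to [sim_scenario()].
#' @return a `sim_scenario`.
#' @export
hmgcr_like_scenario <- function(...) {
  args <- list(...)
  defaults <- list(
    n_snps = 6L, ld = 0.7,
    snp_ids = c("rs12916", "rs17238484", "rs5909", "rs2303152",
                "rs10066707", "rs2006760")
  )
  do.call(sim_scenario, utils::modifyList(defaults, args))
}

# multivariate normal draw via Cholesky of a PSD covariance
rmvn_chol <- function(n, mu, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * length(mu)), n, length(mu))
  sweep(z %*% rt, 2, mu, "+")
}

# analytic GWAS sampling SE for a marginal per-allele coefficient on a
# trait of unit variance, given 2p(1-p) allele-dosage variance
analytic_se_sd <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Summary-level simulation: the estimated exposure betas are drawn from
#' `MVN(beta_gx, D_x rho D_x)` and the estimated outcome betas from
#' `MVN(theta * beta_gx + alpha, D_y rho D_y)`, where `rho` is the LD
#' correlation, `alpha` are optional per-SNP pleiotropic effects, and the
#' diagonal SE matrices use the analytic GWAS sampling variances
#' `se_x = 1/sqrt(2 maf (1-maf) n_exposure)` (SD-scaled trait) and
#' `se_y = 1/sqrt(2 maf (1-maf) n_outcome k (1-k))` (binary trait,
#' log-OR scale). With `outcome_scale = "linear"` the outcome is reported
#' in linear-probability units instead: true effects are pre-multiplied by
#' `k(1-k)` and SEs take the linear-scale analytic form, so a downstream
#' [linear_to_log_or()] must undo the transformation.
#'
#' @param scenario a [sim_scenario()].
#' @param n_reps number of independent replicate draws. Default 1.
#' @return for `n_reps = 1`, list with `exposure` and `outcome`
#'   association-record data.frames and `ld` (the [ld_matrix()]); for
#'   `n_reps > 1`, the same plus matrices `beta_exp_reps`/`beta_out_reps`
#'   (`n_reps` x `n_snps`) holding every replicate's drawn betas, with the
#'   data.frames describing replicate 1.
#' @export
simulate_two_sample <- function(scenario, n_reps = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  rho <- unclass(scenario$ld)
  se_x <- analytic_se_sd(scenario$maf, scenario$n_exposure)
  se_y_logor <- 1 / sqrt(2 * scenario$maf * (1 - scenario$maf) *
                           scenario$n_outcome * scenario$k *
                           (1 - scenario$k))
  sigma_x <- rho * tcrossprod(se_x)

  alpha <- if (scenario$pleiotropy_sd > 0) {
    stats::rnorm(scenario$n_snps, 0, scenario$pleiotropy_sd)
  } else rep(0, scenario$n_snps)
  mu_y_logor <- scenario$theta * scenario$beta_gx + alpha

  if (scenario$outcome_scale == "linear") {
    d <- scenario$k * (1 - scenario$k)
    mu_y <- mu_y_logor * d
    se_y <- se_y_logor * d
  } else {
    mu_y <- mu_y_logor
    se_y <- se_y_logor
  }
  sigma_y <- rho * tcrossprod(se_y)

  bx <- rmvn_chol(n_reps, scenario$beta_gx, sigma_x)
  by <- rmvn_chol(n_reps, mu_y, sigma_y)

  # non-palindromic allele pairs, cycled across SNPs
  pairs <- matrix(c("C", "T", "A", "G", "G", "T", "A", "C"),
                  ncol = 2, byrow = TRUE)
  pi <- ((seq_len(scenario$n_snps) - 1L) %% nrow(pairs)) + 1L

  exposure <- data.frame(
    snp_id = scenario$snp_ids,
    effect_allele = pairs[pi, 1], other_allele = pairs[pi, 2],
    eaf = scenario$maf,
    beta = bx[1, ], se = se_x,
    pval = 2 * stats::pnorm(-abs(bx[1, ] / se_x)),
    n = scenario$n_exposure,
    n_cases = NA_real_, n_controls = NA_real_,
    scale = "sd", stringsAsFactors = FALSE
  )
  n_cases <- round(scenario$k * scenario$n_outcome)
  outcome <- data.frame(
    snp_id = scenario$snp_ids,
    effect_allele = pairs[pi, 1], other_allele = pairs[pi, 2],
    eaf = scenario$maf,
    beta = by[1, ], se = se_y,
    pval = 2 * stats::pnorm(-abs(by[1, ] / se_y)),
    n = scenario$n_outcome,
    n_cases = n_cases, n_controls = scenario$n_outcome - n_cases,
    scale = scenario$outcome_scale, stringsAsFactors = FALSE
  )
  out <- list(exposure = validate_sumstats(exposure),
              outcome = validate_sumstats(outcome),
              ld = scenario$ld,
              se_exposure = se_x, se_outcome = se_y)
  if (n_reps > 1L) {
    out$beta_exp_reps <- bx
    out$beta_out_reps <- by
  }
  out
}
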