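#' Variance in the exposure explained by one SNP
#'
#' For a biallelic SNP with per-allele effect `beta` (in SD units of the
#' exposure) and minor allele frequency `maf`, the variance explained is
#' `2 beta^2 maf (1 - maf)` under Hardy-Weinberg equilibrium.
#'
#' @param beta per-allele association with the exposure, SD units.
#' @param maf minor allele frequency, in (0, 0.5].
#' @return R-squared contribution (scalar or vector).
#' @export
r2_from_beta_maf <- function(beta, maf) {
  if (any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]; pass the minor allele frequency",
         call. = FALSE)
  }
  2 * beta^2 * maf * (1 - maf)
}

#' Sample size required for an MR study
#'
#' Heuristic: the sample size needed for the corresponding
#' exposure-on-outcome study divided by the instrument R-squared.
#'
#' @param n_epi sample size for exposure on outcome.
#' @param r2 instrument-on-exposure variance explained, > 0.
#' @return required MR sample size.
#' @export
required_n <- function(n_epi, r2) {
  if (any(r2 <= 0)) stop("r2 must be > 0", call. = FALSE)
  n_epi / r2
}

#' Smallest detectable odds ratio at a target power
#'
#' Normal approximation for a binary outcome: the z-statistic of the causal
#' log-OR `b` has expectation `b * sqrt(n r2 k (1-k))`, so the smallest
#' detectable effect at two-sided level `alpha` and power `power` is
#' `b = (z_{1-alpha/2} + z_{power}) / sqrt(n r2 k (1-k))`, returned as
#' `exp(b)`.
#'
#' @param n outcome-GWAS sample size.
#' @param k case fraction, in (0,1).
#' @param r2 instrument-on-exposure variance explained, in (0,1).
#' @param power target power. Default 0.8.
#' @param alpha two-sided significance level. Default 0.05.
#' @return detectable OR (> 1) per SD unit of the exposure.
#' @export
detectable_or <- function(n, k, r2, power = 0.8, alpha = 0.05) {
  stopifnot(n > 0, k > 0, k < 1, r2 > 0, r2 < 1,
            power > 0, power < 1, alpha > 0, alpha < 1)
  b <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    sqrt(n * r2 * k * (1 - k))
  exp(b)
}
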