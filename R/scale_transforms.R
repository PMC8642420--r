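#' Convert a linear-model coefficient on a binary trait to a log odds ratio
#'
#' Large biobank GWAS of all-or-nothing outcomes are often run as linear
#' regressions on the 0/1 disease indicator. For a modest effect, the
#' logistic coefficient is approximately the linear-probability coefficient
#' divided by `k(1-k)`, where `k` is the case fraction of the sample. Both
#' the coefficient and its standard error are divided by the same factor,
#' so the z-statistic (and hence the p-value) is preserved exactly.
#'
#' @param beta_linear coefficient in linear-probability units.
#' @param se_linear its standard error (> 0).
#' @param k case fraction `n_cases/n`, in (0,1).
#' @return list with `beta` and `se` on the log-OR scale.
#' @export
linear_to_log_or <- function(beta_linear, se_linear, k) {
  if (any(!is.finite(k)) || any(k <= 0) || any(k >= 1)) {
    stop("case fraction k must lie in (0,1)", call. = FALSE)
  }
  if (any(se_linear <= 0)) stop("se must be > 0", call. = FALSE)
  d <- k * (1 - k)
  list(beta = beta_linear / d, se = se_linear / d)
}

#' Apply the linear-to-log-OR conversion to harmonized outcome columns
#'
#' Rows whose `scale_outcome` is `"linear"` are converted in place using
#' the per-row case fraction `k_outcome`; other rows are untouched.
#'
#' @param harmonized output of [harmonize()].
#' @return the table with outcome betas/SEs on the log-OR scale and
#'   `scale_outcome` set to `"log_or"`.
#' @export
outcome_to_log_or <- function(harmonized) {
  lin <- !is.na(harmonized$scale_outcome) &
    harmonized$scale_outcome == "linear"
  if (any(lin)) {
    k <- harmonized$k_outcome[lin]
    if (any(is.na(k))) {
      stop("linear-scale outcome rows need n_cases and n to derive k",
           call. = FALSE)
    }
    tr <- linear_to_log_or(harmonized$beta_outcome[lin],
                           harmonized$se_outcome[lin], k)
    harmonized$beta_outcome[lin] <- tr$beta
    harmonized$se_outcome[lin] <- tr$se
    harmonized$scale_outcome[lin] <- "log_or"
  }
  harmonized
}

#' Re-express an estimate per SD decrease in the exposure
#'
#' Drug-target analyses that mimic an inhibitor report effects for a
#' reduction in the biomarker (the direction of treatment). The log-OR is
#' negated and the CI endpoints are swapped and negated; SE, p-value and CI
#' width are unchanged. Applying the function twice is the identity.
#'
#' @param estimate an [mr_estimate()] expressed per SD increase.
#' @return the estimate per SD decrease.
#' @export
to_per_sd_decrease <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  out <- estimate
  out$beta <- -estimate$beta
  out$ci_low <- -estimate$ci_high
  out$ci_high <- -estimate$ci_low
  out
}
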