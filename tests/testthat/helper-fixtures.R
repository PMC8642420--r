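# tiny in-code fixtures shared across test files

make_records <- function(n = 3, snp_id = paste0("rs", seq_len(n)),
                         effect_allele = rep("A", n),
                         other_allele = rep("G", n),
                         eaf = rep(0.3, n),
                         beta = seq(0.05, by = 0.01, length.out = n),
                         se = rep(0.01, n),
                         pval = 2 * pnorm(-abs(beta / se)),
                         nn = rep(1e5, n),
                         n_cases = rep(NA_real_, n),
                         n_controls = rep(NA_real_, n),
                         scale = rep("sd", n)) {
  validate_sumstats(data.frame(
    snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pval = pval, n = nn, n_cases = n_cases, n_controls = n_controls,
    scale = scale, stringsAsFactors = FALSE))
}

# harmonized table built directly, for estimator tests
make_harmonized <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome,
                            snp_id = paste0("rs", seq_along(beta_exposure)),
                            pval_exposure =
                              2 * pnorm(-abs(beta_exposure / se_exposure))) {
  out <- data.frame(
    snp_id = snp_id, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta_exposure = beta_exposure, se_exposure = se_exposure,
    pval_exposure = pval_exposure, beta_outcome = beta_outcome,
    se_outcome = se_outcome, n_outcome = NA_real_, k_outcome = NA_real_,
    scale_outcome = "log_or", flipped = FALSE, dropped = FALSE,
    dropped_reason = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("harmonized", "data.frame")
  out
}
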