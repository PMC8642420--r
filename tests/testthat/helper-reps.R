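# turn replicate i of a multi-rep simulation into record tables
rep_records <- function(sim, i) {
  e <- sim$exposure
  e$beta <- sim$beta_exp_reps[i, ]
  e$pval <- 2 * pnorm(-abs(e$beta / e$se))
  o <- sim$outcome
  o$beta <- sim$beta_out_reps[i, ]
  o$pval <- 2 * pnorm(-abs(o$beta / o$se))
  list(exposure = e, outcome = o)
}

# main-analysis estimate (LD-prune to lead SNP, then IVW) for one replicate
lead_snp_estimate <- function(sim, i) {
  rr <- rep_records(sim, i)
  h <- harmonize(rr$exposure, rr$outcome)
  pr <- ld_prune(h, align_ld(sim$ld, h), r2_threshold = 0.01)
  ivw(pr$records)
}
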