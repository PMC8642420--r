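# build a full synthetic analysis grid on disk and return a config list:
# European strata mimic a linear-scale biobank GWAS, the East Asian
# stratum a log-OR hospital-registry GWAS
build_grid_config <- function(dir, outcomes, theta = NULL, seed = 1,
                              strata = c("EUR:all", "EUR:male",
                                         "EUR:female", "EAS:all"),
                              mode = "lead_snp") {
  if (is.null(theta)) theta <- stats::setNames(rep(0, length(outcomes)),
                                               outcomes)
  pop_of <- function(s) strsplit(s, ":")[[1]][1]
  scen_for <- function(s, th, sd) {
    if (pop_of(s) == "EUR") {
      hmgcr_like_scenario(n_exposure = 361194, n_outcome = 361194,
                          k = 0.1, outcome_scale = "linear", theta = th,
                          seed = sd)
    } else {
      hmgcr_like_scenario(n_exposure = 72866, n_outcome = 192000,
                          k = 0.04, outcome_scale = "log_or", theta = th,
                          seed = sd)
    }
  }
  exposures <- list()
  for (i in seq_along(strata)) {
    s <- strata[i]
    sim <- simulate_two_sample(scen_for(s, 0, seed * 1000 + i))
    f <- file.path(dir, sprintf("exposure_%d.tsv", i))
    write_sumstats(sim$exposure, f)
    exposures[[s]] <- f
    if (i == 1) write_correlation_matrix(sim$ld, file.path(dir, "ld.tsv"))
  }
  out_cfg <- list()
  cell <- 0
  for (oc in outcomes) {
    out_cfg[[oc]] <- list()
    for (i in seq_along(strata)) {
      s <- strata[i]
      cell <- cell + 1
      sim <- simulate_two_sample(
        scen_for(s, theta[[oc]], seed * 1000 + 100 + cell))
      f <- file.path(dir, sprintf("outcome_%d.tsv", cell))
      write_sumstats(sim$outcome, f)
      out_cfg[[oc]][[s]] <- list(path = f)
    }
  }
  list(seed = seed, out_dir = file.path(dir, "out"),
       ld_matrix = file.path(dir, "ld.tsv"),
       instruments = list(r2_threshold = 0.01, mode = mode),
       exposures = exposures, outcomes = out_cfg,
       base_dir = dir)
}
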