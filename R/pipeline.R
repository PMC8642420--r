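#' Read and validate a pipeline run configuration
#'
#' The configuration is a structured key/value text file in JSON (a strict
#' subset of YAML). Keys: `seed`, `out_dir`, `ld_matrix`,
#' `instruments: {r2_threshold, mode}`, `palindromic_maf`,
#' `meta: {het_alpha}`, `correction: {alpha, n_phenotypes}`,
#' `confounders: {<name>: path}`, `confounder_alpha`,
#' `exposures: {<stratum>: path}`, and
#' `outcomes: {<outcome>: {<stratum>: path or {path, scale, n, n_cases}}}`.
#' Stratum labels follow `"<population>:<sex>"`, e.g. `"EUR:all"`,
#' `"EUR:female"`, `"EAS:all"`. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path config file path, or a list with the same structure.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (is.character(path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
    base <- dirname(normalizePath(path))
  } else {
    cfg <- path
    base <- cfg$base_dir %||% "."
  }
  defaults <- list(
    seed = 1L,
    out_dir = "targetmr_out",
    instruments = list(r2_threshold = 0.01, mode = "lead_snp"),
    palindromic_maf = 0.42,
    meta = list(het_alpha = 0.05),
    correction = list(alpha = 0.05, n_phenotypes = 10),
    confounder_alpha = 5e-8
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$exposures) || is.null(cfg$outcomes)) {
    stop("config requires 'exposures' and 'outcomes'", call. = FALSE)
  }
  if (!cfg$instruments$mode %in%
      c("lead_snp", "independent", "all_correlated")) {
    stop("instruments.mode must be lead_snp, independent or all_correlated",
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  cfg$ld_matrix <- resolve(cfg$ld_matrix)
  cfg$exposures <- lapply(cfg$exposures, resolve)
  cfg$outcomes <- lapply(cfg$outcomes, function(strata) {
    lapply(strata, function(x) {
      if (is.character(x)) x <- list(path = x)
      x$path <- resolve(x$path)
      x
    })
  })
  if (!is.null(cfg$confounders)) cfg$confounders <- lapply(cfg$confounders, resolve)
  class(cfg) <- c("run_config", "list")
  cfg
}

split_stratum <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  list(population = parts[1],
       sex = if (length(parts) > 1) parts[2] else "all")
}

analyze_cell <- function(exposure, outcome, corr, cfg) {
  h <- harmonize(exposure, outcome, palindromic_maf = cfg$palindromic_maf)
  h <- outcome_to_log_or(h)
  kept <- h[!h$dropped, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all instruments dropped in harmonization")

  mode <- cfg$instruments$mode
  ld_h <- align_ld(corr, h)
  if (mode == "all_correlated") {
    est <- ivw_correlated(kept, ld_h)
    used <- kept
  } else {
    pruned <- ld_prune(kept, ld_h,
                       r2_threshold = cfg$instruments$r2_threshold,
                       top_1 = (mode == "lead_snp"))
    used <- pruned$records
    est <- ivw(used)
  }
  # sensitivity: every retained SNP with its correlation matrix
  sens <- if (nrow(kept) >= 2) ivw_correlated(kept, ld_h) else NULL
  list(
    estimate = to_per_sd_decrease(est),
    sensitivity = if (!is.null(sens)) to_per_sd_decrease(sens) else NULL,
    f_stat = f_statistic(used),
    n_harmonized = nrow(kept),
    n_dropped = sum(h$dropped),
    snp_ids = used$snp_id
  )
}

#' Run the full drug-target MR analysis grid
#'
#' For every outcome x stratum cell with input files available:
#' harmonize exposure and outcome summary statistics, convert
#' linear-probability outcome betas to log-OR, select instruments
#' (lead-SNP or LD-pruned main analysis; all-SNP correlated IVW
#' sensitivity analysis), estimate the causal effect, and re-express it
#' per SD decrease in the exposure. Afterwards: sex-difference tests
#' within each population, ethnic-difference tests between populations
#' (sex-combined strata), fixed/random-effects meta-analysis across
#' populations, Bonferroni annotation, and instrument diagnostics
#' (F-statistics, heterogeneity, confounder screen). Strata are
#' independent cells: a failure in one is recorded and never aborts the
#' others.
#'
#' @param config path to a config file or a config list
#'   (see [read_run_config()]).
#' @return list of class `targetmr_results`: `results`, `sensitivity`,
#'   `differences`, `meta`, `diagnostics`, `confounders` data.frames and a
#'   `log` character vector. When `out_dir` is set the tables are also
#'   written there as TSV plus `log.txt`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  log <- c(sprintf("seed: %d", cfg$seed),
           sprintf("instrument mode: %s", cfg$instruments$mode),
           sprintf("r2 threshold: %g", cfg$instruments$r2_threshold))
  corr <- if (!is.null(cfg$ld_matrix)) read_correlation_matrix(cfg$ld_matrix)
          else NULL

  exposures <- list()
  for (s in names(cfg$exposures)) {
    p <- cfg$exposures[[s]]
    if (!is.null(p) && file.exists(p)) {
      exposures[[s]] <- read_sumstats(p, scale = "sd")
    } else {
      log <- c(log, sprintf("exposure %s: skipped, missing input", s))
    }
  }

  estimates <- list()   # estimates[[outcome]][[stratum]]
  res_rows <- list(); sens_rows <- list(); diag_rows <- list()
  for (oc in names(cfg$outcomes)) {
    estimates[[oc]] <- list()
    for (s in names(cfg$outcomes[[oc]])) {
      spec <- cfg$outcomes[[oc]][[s]]
      cell <- sprintf("%s/%s", oc, s)
      if (is.null(spec$path) || !file.exists(spec$path)) {
        log <- c(log, sprintf("%s: skipped, missing input", cell))
        next
      }
      if (is.null(exposures[[s]])) {
        log <- c(log, sprintf("%s: skipped, no exposure for stratum", cell))
        next
      }
      ans <- tryCatch({
        outc <- read_sumstats(spec$path, scale = spec$scale %||% NULL)
        if (!is.null(spec$n_cases) && !is.null(spec$n)) {
          outc$n_cases <- spec$n_cases
          outc$n <- spec$n
          outc$n_controls <- spec$n - spec$n_cases
        }
        analyze_cell(exposures[[s]], outc, corr, cfg)
      }, error = function(e) e)
      if (inherits(ans, "error")) {
        log <- c(log, sprintf("%s: error, %s", cell, conditionMessage(ans)))
        next
      }
      est <- ans$estimate
      est$outcome <- oc; est$stratum <- s
      estimates[[oc]][[s]] <- est
      res_rows[[cell]] <- data.frame(
        outcome = oc, stratum = s, method = est$method,
        n_snps = est$n_snps, beta = est$beta, se = est$se,
        or = exp(est$beta), ci_low = exp(est$ci_low),
        ci_high = exp(est$ci_high), pval = est$pval,
        q_pval = est$q_pval, stringsAsFactors = FALSE)
      if (!is.null(ans$sensitivity)) {
        se2 <- ans$sensitivity
        sens_rows[[cell]] <- data.frame(
          outcome = oc, stratum = s, method = se2$method,
          n_snps = se2$n_snps, beta = se2$beta, se = se2$se,
          or = exp(se2$beta), ci_low = exp(se2$ci_low),
          ci_high = exp(se2$ci_high), pval = se2$pval,
          q_pval = se2$q_pval, stringsAsFactors = FALSE)
      }
      diag_rows[[cell]] <- data.frame(
        outcome = oc, stratum = s, f_statistic = ans$f_stat,
        n_harmonized = ans$n_harmonized, n_dropped = ans$n_dropped,
        snp_ids = paste(ans$snp_ids, collapse = ","),
        stringsAsFactors = FALSE)
      log <- c(log, sprintf("%s: %s with %d SNP(s)", cell, est$method,
                            est$n_snps))
    }
  }
  results <- do.call(rbind, unname(res_rows))
  if (!is.null(results)) {
    results$significance <- annotate_significance(
      results$pval, cfg$correction$alpha, cfg$correction$n_phenotypes)
  } else {
    results <- data.frame()
  }

  # difference tests: sex within population; population at sex = all
  diff_rows <- list()
  for (oc in names(estimates)) {
    es <- estimates[[oc]]
    if (length(es) < 2) next
    info <- lapply(names(es), split_stratum)
    pops <- vapply(info, `[[`, "", "population")
    sexes <- vapply(info, `[[`, "", "sex")
    for (p in unique(pops)) {
      im <- which(pops == p & sexes == "male")
      iw <- which(pops == p & sexes == "female")
      if (length(im) == 1 && length(iw) == 1) {
        dt <- difference_test(es[[im]], es[[iw]])
        diff_rows[[length(diff_rows) + 1L]] <- data.frame(
          outcome = oc, comparison = "sex",
          pair = sprintf("%s vs %s", names(es)[im], names(es)[iw]),
          delta = dt$delta, se_delta = dt$se_delta, z = dt$z,
          pval = dt$pval, stringsAsFactors = FALSE)
      }
    }
    ia <- which(sexes == "all")
    if (length(ia) >= 2) {
      cmb <- utils::combn(ia, 2)
      for (j in seq_len(ncol(cmb))) {
        dt <- difference_test(es[[cmb[1, j]]], es[[cmb[2, j]]])
        diff_rows[[length(diff_rows) + 1L]] <- data.frame(
          outcome = oc, comparison = "population",
          pair = sprintf("%s vs %s", names(es)[cmb[1, j]],
                         names(es)[cmb[2, j]]),
          delta = dt$delta, se_delta = dt$se_delta, z = dt$z,
          pval = dt$pval, stringsAsFactors = FALSE)
      }
    }
  }
  differences <- do.call(rbind, diff_rows) %||% data.frame()

  # cross-population meta-analysis per outcome x sex
  meta_rows <- list()
  for (oc in names(estimates)) {
    es <- estimates[[oc]]
    if (length(es) < 2) next
    sexes <- vapply(names(es), function(s) split_stratum(s)$sex, "")
    for (sx in unique(sexes)) {
      grp <- es[sexes == sx]
      if (length(grp) < 2) next
      mr <- meta_analyze(unname(grp), het_alpha = cfg$meta$het_alpha)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        outcome = oc, sex = sx, model = mr$model,
        beta = mr$pooled$beta, se = mr$pooled$se,
        or = exp(mr$pooled$beta), ci_low = exp(mr$pooled$ci_low),
        ci_high = exp(mr$pooled$ci_high), pval = mr$pooled$pval,
        q_stat = mr$q_stat, q_pval = mr$q_pval,
        inputs = paste(names(grp), collapse = ","),
        stringsAsFactors = FALSE)
      log <- c(log, sprintf("%s/meta[%s]: %s effects over %s", oc, sx,
                            mr$model, paste(names(grp), collapse = "+")))
    }
  }
  meta <- do.call(rbind, meta_rows) %||% data.frame()

  confounders <- data.frame()
  if (!is.null(cfg$confounders) && length(exposures) > 0) {
    cf_stats <- lapply(cfg$confounders, read_sumstats)
    all_snps <- unique(unlist(lapply(exposures, function(e) e$snp_id)))
    confounders <- confounder_screen(all_snps, cf_stats,
                                     alpha = cfg$confounder_alpha)
    n_fl <- sum(confounders$status == "flagged")
    log <- c(log, sprintf("confounder screen: %d flag(s)", n_fl))
  }

  out <- structure(list(
    results = results, sensitivity = do.call(rbind, unname(sens_rows)) %||%
      data.frame(),
    differences = differences, meta = meta,
    diagnostics = do.call(rbind, unname(diag_rows)) %||% data.frame(),
    confounders = confounders, log = log, config = cfg
  ), class = "targetmr_results")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (nrow(results) > 0) {
      write_results(results[, c("outcome", "stratum", "method", "n_snps",
                                "or", "ci_low", "ci_high", "pval",
                                "q_pval")],
                    file.path(cfg$out_dir, "results.tsv"))
    } else {
      write_results(list(), file.path(cfg$out_dir, "results.tsv"))
    }
    wt(out$sensitivity, "sensitivity.tsv")
    wt(differences, "differences.tsv")
    wt(meta, "meta.tsv")
    wt(out$diagnostics, "diagnostics.tsv")
    if (nrow(confounders) > 0) wt(confounders, "confounders.tsv")
    writeLines(log, file.path(cfg$out_dir, "log.txt"))
  }
  out
}

#' Render a results table as a fixed-width text forest table
#'
#' @param results a results data.frame from [run_pipeline()], a path to a
#'   `results.tsv`, or a `targetmr_results` object.
#' @return character vector of lines (also printed), grouped by outcome,
#'   one row per stratum with OR (95% CI), p-value, method and SNP count.
#' @export
render_forest <- function(results) {
  if (inherits(results, "targetmr_results")) results <- results$results
  if (is.character(results)) {
    results <- utils::read.delim(results, stringsAsFactors = FALSE)
    needed <- c("outcome", "stratum", "or", "ci_low", "ci_high", "pval")
    if (!all(needed %in% names(results))) {
      stop("malformed results table; need columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
  }
  hdr <- sprintf("%-18s %-12s %-22s %-8s %-14s %s",
                 "outcome", "stratum", "OR (95% CI)", "p", "method",
                 "n_snps")
  lines <- hdr
  if (nrow(results) > 0) {
    for (oc in unique(results$outcome)) {
      sub <- results[results$outcome == oc, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        or_ci <- sprintf("%5.2f (%5.2f, %5.2f)", sub$or[i], sub$ci_low[i],
                         sub$ci_high[i])
        lines <- c(lines, sprintf(
          "%-18s %-12s %-22s %-8s %-14s %d",
          substr(oc, 1, 18), substr(sub$stratum[i], 1, 12), or_ci,
          sprintf("p=%.3f", sub$pval[i]),
          sub$method[i] %||% "", sub$n_snps[i] %||% NA_integer_))
      }
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
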