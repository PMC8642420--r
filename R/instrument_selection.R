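#' LD-prune a candidate SNP set to approximate independence
#'
#' Greedy selection in the style of GWAS clumping: candidates are ranked by
#' ascending exposure p-value (ties broken by larger `|beta|`, then by
#' rsID), and a SNP is accepted iff its squared correlation with every
#' already-accepted SNP is below `r2_threshold`. The tie-break chain makes
#' the ranking total, so the selection is invariant to input row order.
#'
#' @param records association records (or a `harmonized` table, in which
#'   case `pval_exposure`/`beta_exposure` are used for ranking).
#' @param corr [ld_matrix()] covering every record.
#' @param r2_threshold squared-correlation ceiling, in (0,1). Default 0.01,
#'   the conventional independence threshold for cis instruments.
#' @param top_1 when TRUE return only the single best-ranked survivor
#'   (mode `"lead_snp"`).
#' @return list of class `pruned_set`: `snp_ids` (selected, in rank order),
#'   `mode` (`"independent"` or `"lead_snp"`), and `records` (the selected
#'   rows).
#' @export
ld_prune <- function(records, corr, r2_threshold = 0.01, top_1 = FALSE) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  is_harm <- inherits(records, "harmonized")
  pv <- if (is_harm) records$pval_exposure else records$pval
  bb <- if (is_harm) records$beta_exposure else records$beta
  ids <- records$snp_id
  missing <- setdiff(ids, rownames(corr))
  if (length(missing) > 0L) {
    stop("SNP(s) missing from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(pv))) {
    stop("exposure p-values required for LD pruning", call. = FALSE)
  }
  ord <- order(pv, -abs(bb), ids)
  accepted <- integer(0)
  r <- unclass(corr)
  for (i in ord) {
    if (length(accepted) == 0L ||
        all(r[ids[i], ids[accepted]]^2 < r2_threshold)) {
      accepted <- c(accepted, i)
    }
    if (top_1 && length(accepted) == 1L) break
  }
  sel <- records[accepted, , drop = FALSE]
  mode <- if (length(accepted) == 1L) "lead_snp" else "independent"
  structure(list(snp_ids = ids[accepted], mode = mode, records = sel),
            class = "pruned_set")
}

#' Instrument-strength F-statistic
#'
#' Approximated as the mean over instruments of the squared z-statistic of
#' the SNP-exposure association, `mean((beta/se)^2)`. Values above 10
#' conventionally indicate that weak-instrument bias is unlikely.
#'
#' @param records exposure-scale association records (or `harmonized`
#'   table, using the exposure columns).
#' @return the F-statistic (scalar).
#' @export
f_statistic <- function(records) {
  b <- if (inherits(records, "harmonized")) records$beta_exposure
       else records$beta
  s <- if (inherits(records, "harmonized")) records$se_exposure
       else records$se
  if (length(b) == 0L) stop("no records", call. = FALSE)
  if (any(s == 0)) stop("se must be nonzero", call. = FALSE)
  mean((b / s)^2)
}

#' Screen instruments against confounder GWAS
#'
#' Flags any instrument associated with a potential confounder (e.g.
#' socioeconomic position, current smoking, alcohol consumption) below a
#' genome-wide significance threshold. The screen is advisory: flagged
#' SNPs are reported, not removed, since the check is a diagnostic of the
#' independence assumption rather than a filter.
#'
#' @param snp_ids character vector of instrument rsIDs (an
#'   `instrument_set`, `pruned_set` or `harmonized` table is also
#'   accepted).
#' @param confounder_stats named list of association-record data.frames,
#'   one per confounder.
#' @param alpha flagging threshold. Default `5e-8` (genome-wide
#'   significance).
#' @return data.frame with one row per SNP x confounder: `snp_id`,
#'   `confounder`, `pval`, `status` in
#'   `{"ok", "flagged", "untested"}`.
#' @export
confounder_screen <- function(snp_ids, confounder_stats, alpha = 5e-8) {
  if (inherits(snp_ids, "instrument_set")) {
    snp_ids <- snp_ids$instruments$snp_id
  } else if (inherits(snp_ids, "pruned_set")) {
    snp_ids <- snp_ids$snp_ids
  } else if (is.data.frame(snp_ids)) {
    snp_ids <- snp_ids$snp_id
  }
  stopifnot(length(snp_ids) > 0, length(confounder_stats) > 0,
            !is.null(names(confounder_stats)))
  rows <- lapply(names(confounder_stats), function(cf) {
    st <- confounder_stats[[cf]]
    idx <- match(snp_ids, st$snp_id)
    p <- ifelse(is.na(idx), NA_real_, st$pval[idx])
    status <- ifelse(is.na(idx), "untested",
                     ifelse(!is.na(p) & p < alpha, "flagged", "ok"))
    data.frame(snp_id = snp_ids, confounder = cf, pval = p,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
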