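# Column alias table for summary-statistics dialects. Keys are lower-cased
# header names as found in the wild; values are canonical column names.
SUMSTATS_ALIASES <- c(
  snp = "snp_id", rsid = "snp_id", variant_id = "snp_id", snp_id = "snp_id",
  a1 = "effect_allele", ea = "effect_allele", effect_allele = "effect_allele",
  a2 = "other_allele", nea = "other_allele", oa = "other_allele",
  other_allele = "other_allele",
  b = "beta", beta = "beta",
  se = "se", standard_error = "se",
  p = "pval", pval = "pval", p_value = "pval",
  af = "eaf", eaf = "eaf", freq = "eaf",
  n = "n", n_cases = "n_cases", n_controls = "n_controls",
  scale = "scale"
)

VALID_ALLELES <- c("A", "C", "G", "T")
VALID_SCALES <- c("sd", "log_or", "linear")

#' Validate a table of per-SNP association records
#'
#' An association-record table is the atom of all I/O in this package: one
#' row per SNP carrying its association with a single trait. Required
#' columns are `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`;
#' optional columns are `eaf`, `pval`, `n`, `n_cases`, `n_controls`,
#' `scale`. The `scale` flag records the units of `beta`: `"sd"` for a
#' standardized continuous trait, `"log_or"` for a binary trait on the
#' log odds ratio scale, `"linear"` for a binary trait analyzed by linear
#' regression (linear-probability units).
#'
#' @param records data.frame of association records.
#' @param scale optional scale flag applied to all rows when the table has
#'   no `scale` column.
#' @return the validated data.frame (invisibly the same object), with
#'   canonical column order and a `scale` column always present.
#' @export
validate_sumstats <- function(records, scale = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary statistics missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"scale" %in% names(records)) {
    records$scale <- if (is.null(scale)) NA_character_ else scale
  }
  for (opt in c("eaf", "pval", "n", "n_cases", "n_controls")) {
    if (!opt %in% names(records)) records[[opt]] <- NA_real_
    records[[opt]] <- as.numeric(records[[opt]])
  }
  records$snp_id <- as.character(records$snp_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup) > 0L) {
    stop("duplicate snp_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_allele <- !(records$effect_allele %in% VALID_ALLELES) |
    !(records$other_allele %in% VALID_ALLELES) |
    records$effect_allele == records$other_allele
  if (any(bad_allele)) {
    stop("invalid alleles in rows: ",
         paste(which(bad_allele), collapse = ", "), call. = FALSE)
  }
  bad_num <- !is.finite(records$beta) | !is.finite(records$se)
  if (any(bad_num)) {
    stop("non-finite beta/se in rows: ",
         paste(which(bad_num), collapse = ", "), call. = FALSE)
  }
  if (any(records$se <= 0)) {
    stop("se must be > 0; offending rows: ",
         paste(which(records$se <= 0), collapse = ", "), call. = FALSE)
  }
  eaf_known <- !is.na(records$eaf)
  if (any(eaf_known & (records$eaf <= 0 | records$eaf >= 1))) {
    stop("eaf must lie in (0,1); offending rows: ",
         paste(which(eaf_known & (records$eaf <= 0 | records$eaf >= 1)),
               collapse = ", "), call. = FALSE)
  }
  p_known <- !is.na(records$pval)
  if (any(p_known & (records$pval <= 0 | records$pval > 1))) {
    stop("pval must lie in (0,1]; offending rows: ",
         paste(which(p_known & (records$pval <= 0 | records$pval > 1)),
               collapse = ", "), call. = FALSE)
  }
  bad_scale <- !is.na(records$scale) & !(records$scale %in% VALID_SCALES)
  if (any(bad_scale)) {
    stop("scale must be one of ", paste(VALID_SCALES, collapse = "/"),
         call. = FALSE)
  }
  lin <- !is.na(records$scale) & records$scale == "linear" &
    !is.na(records$n_cases) & !is.na(records$n_controls) & !is.na(records$n)
  if (any(lin & (records$n_cases + records$n_controls != records$n))) {
    stop("linear-scale rows require n_cases + n_controls == n; rows: ",
         paste(which(lin & (records$n_cases + records$n_controls != records$n)),
               collapse = ", "), call. = FALSE)
  }
  cols <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval", "n", "n_cases", "n_controls", "scale")
  out <- records[, cols]
  rownames(out) <- NULL
  out
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read GWAS summary statistics from delimited text
#'
#' Accepts tab- or comma-delimited files with a header. Column names are
#' mapped through a documented alias table (e.g. `SNP`/`rsid` ->
#' `snp_id`, `A1`/`ea` -> `effect_allele`, `A2`/`nea`/`oa` ->
#' `other_allele`). Row order is preserved.
#'
#' @param path file path.
#' @param scale scale flag (`"sd"`, `"log_or"` or `"linear"`) applied when
#'   the file carries no scale column.
#' @return validated association-record data.frame.
#' @export
read_sumstats <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = guess_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  mapped <- SUMSTATS_ALIASES[nm]
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  validate_sumstats(raw, scale = scale)
}

#' Write summary statistics as tab-delimited text
#'
#' Inverse of [read_sumstats()]: a written table re-reads field-for-field.
#'
#' @param records validated association-record data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(records, path) {
  records <- validate_sumstats(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a signed LD correlation matrix
#'
#' The matrix holds signed allele-dosage correlations r in \[-1, 1\] between
#' SNPs, with unit diagonal, aligned to the effect alleles of the records it
#' will be used with. Mild asymmetry (<= 1e-8) is repaired by averaging with
#' the transpose; an indefinite matrix whose smallest eigenvalue is only
#' marginally negative (> -1e-8, as arises from file round-tripping) is
#' repaired by clipping eigenvalues at zero and renormalizing the diagonal
#' to one. Anything worse is an error.
#'
#' @param r square numeric matrix.
#' @param snp_ids character vector of rsIDs, one per row/column.
#' @return matrix with class `ld_matrix` and `snp_ids` as dimnames.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(snp_ids) || length(snp_ids) != nrow(r)) {
    stop("snp_ids must match the matrix dimension", call. = FALSE)
  }
  asym <- max(abs(r - t(r)))
  if (asym > 1e-8) stop("LD matrix asymmetric beyond 1e-8", call. = FALSE)
  r <- (r + t(r)) / 2
  if (max(abs(r)) > 1 + 1e-8) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (max(abs(diag(r) - 1)) > 1e-8) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE)
  min_ev <- min(ev$values)
  if (min_ev < -1e-8) {
    stop("LD matrix is not positive semi-definite (min eigenvalue ",
         format(min_ev), ")", call. = FALSE)
  }
  if (min_ev < 0) {
    vals <- pmax(ev$values, 0)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
    diag(r) <- 1
  }
  dimnames(r) <- list(as.character(snp_ids), as.character(snp_ids))
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' Read a signed LD correlation matrix from delimited text
#'
#' Expects a square matrix with rsIDs as the first row and first column.
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_correlation_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = guess_delim(path),
                           row.names = 1L, check.names = FALSE)
  m <- as.matrix(raw)
  if (!identical(rownames(m), colnames(m))) {
    stop("rsID mismatch between LD matrix header row and first column",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  ld_matrix(m, rownames(m))
}

#' Write an LD correlation matrix as tab-delimited text
#' @param corr an [ld_matrix()].
#' @param path output path.
#' @export
write_correlation_matrix <- function(corr, path) {
  df <- data.frame(snp_id = rownames(corr), unclass(corr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome associations to a shared effect allele
#'
#' For each SNP present in both tables, the outcome association is expressed
#' on the exposure's effect allele: matching alleles are copied; swapped
#' alleles (effect <-> other) negate the outcome beta and complement its
#' frequency; a strand flip (A<->T, C<->G complement) is applied first when
#' it resolves the match. Palindromic SNPs (A/T or C/G), for which swap and
#' strand flip are indistinguishable, are frequency-aligned when the allele
#' frequency is informative and dropped otherwise (see `palindromic_maf`).
#' SNPs whose allele sets cannot be reconciled are kept in the output with a
#' `dropped_reason` rather than silently discarded.
#'
#' @param exposure,outcome validated association-record data.frames. The
#'   exposure is the instrumented trait in SD units; the outcome may be on
#'   the log-OR or linear scale.
#' @param palindromic_maf palindromic SNPs with `min(eaf, 1-eaf)` at or
#'   above this value (or missing eaf) are dropped as ambiguous; below it
#'   they are aligned by frequency. Default 0.42, the conservative standard
#'   for two-sample MR.
#' @return data.frame of class `harmonized` with one row per shared SNP:
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta_exposure`,
#'   `se_exposure`, `pval_exposure`, `beta_outcome`, `se_outcome`,
#'   `n_outcome`, `k_outcome` (case fraction when available),
#'   `scale_outcome`, `flipped`, `dropped`, `dropped_reason`.
#' @export
harmonize <- function(exposure, outcome, palindromic_maf = 0.42) {
  exposure <- validate_sumstats(exposure)
  outcome <- validate_sumstats(outcome)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) stop("no shared instruments", call. = FALSE)
  ex <- exposure[match(shared, exposure$snp_id), ]
  ot <- outcome[match(shared, outcome$snp_id), ]

  n <- length(shared)
  flipped <- logical(n)
  dropped <- logical(n)
  reason <- rep(NA_character_, n)
  beta_out <- ot$beta
  eaf_out <- ot$eaf

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ot$effect_allele[i]; oa_y <- ot$other_allele[i]
    if (is_palindromic(ea_x, oa_x)) {
      if (!is_palindromic(ea_y, oa_y) ||
          !setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        dropped[i] <- TRUE; reason[i] <- "allele mismatch"; next
      }
      fx <- ex$eaf[i]; fy <- ot$eaf[i]
      if (is.na(fx) || is.na(fy) ||
          min(fx, 1 - fx) >= palindromic_maf ||
          min(fy, 1 - fy) >= palindromic_maf) {
        dropped[i] <- TRUE
        reason[i] <- "palindromic, ambiguous frequency"
        next
      }
      # frequency alignment: minor/major orientation must agree
      if ((fx < 0.5) != (fy < 0.5)) {
        flipped[i] <- TRUE
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    direct <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!direct && !swapped) {
      ea_c <- unname(COMPLEMENT[ea_y]); oa_c <- unname(COMPLEMENT[oa_y])
      direct <- ea_c == ea_x && oa_c == oa_x
      swapped <- ea_c == oa_x && oa_c == ea_x
    }
    if (direct) next
    if (swapped) {
      flipped[i] <- TRUE
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      next
    }
    dropped[i] <- TRUE; reason[i] <- "allele mismatch"
  }

  k_out <- ifelse(!is.na(ot$n_cases) & !is.na(ot$n),
                  ot$n_cases / ot$n, NA_real_)
  out <- data.frame(
    snp_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf = ex$eaf,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pval_exposure = ex$pval,
    beta_outcome = beta_out,
    se_outcome = ot$se,
    n_outcome = ot$n,
    k_outcome = k_out,
    scale_outcome = ot$scale,
    flipped = flipped,
    dropped = dropped,
    dropped_reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized", "data.frame")
  out
}

#' Align a signed LD matrix to a harmonized instrument table
#'
#' LD correlations are defined on allele dosages, so when harmonization
#' flips the effect allele of SNP j, row and column j of r change sign.
#' Dropped SNPs are removed. The result is ordered as the retained
#' instruments.
#'
#' @param corr an [ld_matrix()] covering all harmonized SNPs.
#' @param harmonized output of [harmonize()].
#' @return an [ld_matrix()] restricted and sign-aligned to the retained
#'   instruments.
#' @export
align_ld <- function(corr, harmonized) {
  keep <- harmonized[!harmonized$dropped, , drop = FALSE]
  missing <- setdiff(keep$snp_id, rownames(corr))
  if (length(missing) > 0L) {
    stop("SNP(s) missing from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r <- unclass(corr)[keep$snp_id, keep$snp_id, drop = FALSE]
  s <- ifelse(keep$flipped, -1, 1)
  r <- r * tcrossprod(s)
  ld_matrix(r, keep$snp_id)
}

#' Write an MR results table as delimited text
#'
#' Renders estimates in the reporting layout used for forest-style result
#' tables: odds ratios and CI bounds to 2 decimals, p-values to 3 decimals.
#'
#' @param estimates list of [mr_estimate()] objects (carrying `outcome` and
#'   `stratum` labels) or a results data.frame from [run_pipeline()].
#' @param path output path.
#' @return the formatted data.frame, invisibly.
#' @export
write_results <- function(estimates, path) {
  if (is.data.frame(estimates)) {
    df <- estimates
  } else {
    df <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(
        outcome = e$outcome %||% NA_character_,
        stratum = e$stratum %||% NA_character_,
        method = e$method,
        n_snps = e$n_snps,
        or = exp(e$beta),
        ci_low = exp(e$ci_low),
        ci_high = exp(e$ci_high),
        pval = e$pval,
        q_pval = e$q_pval %||% NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  }
  if (is.null(df)) {
    df <- data.frame(outcome = character(), stratum = character(),
                     method = character(), n_snps = integer(),
                     or = numeric(), ci_low = numeric(), ci_high = numeric(),
                     pval = numeric(), q_pval = numeric())
  }
  fmt <- df
  for (col in c("or", "ci_low", "ci_high")) {
    fmt[[col]] <- sprintf("%.2f", df[[col]])
  }
  for (col in c("pval", "q_pval")) {
    fmt[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.3f", df[[col]]))
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fmt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
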