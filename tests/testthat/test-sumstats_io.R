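test_that("read_sumstats maps aliases, preserves order, validates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tstandard_error\tp_value\tn",
               "rs1\tA\tG\t0.30\t0.07\t0.010\t2.6e-12\t100000",
               "rs2\tC\tT\t0.10\t0.03\t0.012\t0.0124\t100000",
               "rs3\tG\tA\t0.45\t-0.02\t0.011\t0.0690\t100000"), tf)
  rec <- read_sumstats(tf, scale = "sd")
  expect_equal(rec$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(rec$effect_allele, c("A", "C", "G"))
  expect_equal(rec$beta, c(0.07, 0.03, -0.02))
  expect_equal(rec$se, c(0.010, 0.012, 0.011))
  expect_equal(rec$eaf, c(0.30, 0.10, 0.45))
  expect_equal(rec$scale, rep("sd", 3))

  # missing mandatory column named in the error
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,A1,b,se", "rs1,A,0.1,0.01"), tf2)
  expect_error(read_sumstats(tf2), "other_allele")
})

test_that("validation rejects bad rows with row-level messages", {
  rec <- make_records(2)
  rec$se[2] <- 0
  expect_error(validate_sumstats(rec), "se must be > 0.*2")
  rec <- make_records(2)
  rec$beta[1] <- NA
  expect_error(validate_sumstats(rec), "non-finite.*1")
  raw <- data.frame(snp_id = c("rs1", "rs1"), effect_allele = "A",
                    other_allele = "G", beta = 0.1, se = 0.01)
  expect_error(validate_sumstats(raw), "duplicate snp_id: rs1")
  raw2 <- data.frame(snp_id = "rs1", effect_allele = "A",
                     other_allele = "G", beta = 0.1, se = 0.01,
                     n = 100, n_cases = 10, n_controls = 80,
                     scale = "linear")
  expect_error(validate_sumstats(raw2), "n_cases \\+ n_controls")
})

test_that("sumstats round-trip through disk is the identity", {
  rec <- make_records(6, effect_allele = c("A", "C", "G", "T", "A", "C"),
                      other_allele = c("G", "T", "A", "C", "G", "T"),
                      eaf = c(0.39, 0.47, 0.35, 0.13, 0.42, 0.22),
                      beta = c(0.062, -0.035, 0.03, 0.028, -0.025, 0.02),
                      se = c(0.0024, 0.0025, 0.0026, 0.003, 0.0024, 0.005))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(rec, tf)
  back <- read_sumstats(tf)
  expect_equal(back, rec)
})

test_that("correlation matrix I/O enforces invariants and round-trips", {
  r <- matrix(c(1, 0.95, 0.95, 1), 2, dimnames = list(c("rs1", "rs2"),
                                                      c("rs1", "rs2")))
  m <- ld_matrix(r)
  expect_s3_class(m, "ld_matrix")
  expect_identical(unclass(m), r)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_matrix(m, tf)
  back <- read_correlation_matrix(tf)
  expect_equal(unclass(back), r)

  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "\\[-1, 1\\]")
  bad <- r; bad[1, 2] <- 0.2
  expect_error(ld_matrix(bad), "asymmetric")
  # genuinely indefinite matrix is refused
  ind <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  dimnames(ind) <- list(paste0("s", 1:3), paste0("s", 1:3))
  expect_error(ld_matrix(ind), "positive semi-definite")
})

test_that("PSD repair fixes rounding-level negative eigenvalues only", {
  # rank-deficient correlation (3 dosage vectors spanning 2 dimensions)
  v <- cbind(c(1, 0), c(0.6, 0.8), c(0.8, 0.6))
  r <- crossprod(v)                     # unit diagonal, min eigenvalue 0
  ev <- eigen(r, symmetric = TRUE)
  vals <- ev$values
  vals[3] <- -5e-9   # nudge the zero eigenvalue just below zero
  broken <- ev$vectors %*% (vals * t(ev$vectors))
  diag(broken) <- 1
  ids <- paste0("s", 1:3)
  dimnames(broken) <- list(ids, ids)
  repaired <- ld_matrix(broken)
  expect_gte(min(eigen(unclass(repaired), symmetric = TRUE)$values),
             -1e-12)
  expect_equal(diag(unclass(repaired)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(repaired), r, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("harmonize copies, flips, strand-complements and drops", {
  ex <- make_records(4, effect_allele = c("A", "A", "A", "A"),
                     other_allele = c("G", "G", "G", "G"),
                     beta = c(0.07, 0.07, 0.07, 0.07))
  ot <- make_records(4,
                     effect_allele = c("A", "G", "T", "A"),
                     other_allele = c("G", "A", "C", "C"),
                     beta = c(-0.02, 0.02, -0.02, 0.05),
                     eaf = c(0.3, 0.7, 0.3, 0.3))
  h <- harmonize(ex, ot)
  # direct match
  expect_equal(h$beta_outcome[1], -0.02)
  expect_false(h$flipped[1])
  # swapped alleles: beta negated, flagged
  expect_equal(h$beta_outcome[2], -0.02)
  expect_true(h$flipped[2])
  expect_equal(h$eaf[2], 0.3)
  # strand complement of direct (T/C -> A/G)
  expect_equal(h$beta_outcome[3], -0.02)
  expect_false(h$flipped[3])
  # unresolvable allele set
  expect_true(h$dropped[4])
  expect_equal(h$dropped_reason[4], "allele mismatch")
  # allele flip never changes |beta| or se
  expect_equal(abs(h$beta_outcome[1:3]), rep(0.02, 3))
  expect_equal(h$se_outcome, ot$se)
})

test_that("palindromic policy: drop when ambiguous, align by frequency", {
  pal <- function(eaf_x, eaf_y) {
    ex <- make_records(1, effect_allele = "A", other_allele = "T",
                       eaf = eaf_x, beta = 0.07)
    ot <- make_records(1, effect_allele = "A", other_allele = "T",
                       eaf = eaf_y, beta = 0.02)
    harmonize(ex, ot)
  }
  # enumerated policy table
  cases <- list(
    list(0.49, 0.49, TRUE, NA),       # ambiguous frequency -> drop
    list(NA, 0.30, TRUE, NA),         # missing frequency -> drop
    list(0.30, 0.30, FALSE, FALSE),   # aligned minor alleles -> keep
    list(0.30, 0.70, FALSE, TRUE),    # discordant orientation -> flip
    list(0.42, 0.30, TRUE, NA)        # at the 0.42 boundary -> drop
  )
  for (cs in cases) {
    h <- pal(cs[[1]], cs[[2]])
    expect_equal(h$dropped, cs[[3]])
    if (!cs[[3]]) expect_equal(h$flipped, cs[[4]])
  }
  h <- pal(0.49, 0.49)
  expect_equal(h$dropped_reason, "palindromic, ambiguous frequency")
  expect_error(harmonize(make_records(1), make_records(1, snp_id = "rsX")),
               "no shared instruments")
})

test_that("harmonization involution: pre-swapped outcome gives same betas", {
  ex <- make_records(3, beta = c(0.07, 0.05, 0.06))
  ot <- make_records(3, beta = c(-0.02, 0.01, 0.03))
  swapped <- ot
  swapped$effect_allele <- ot$other_allele
  swapped$other_allele <- ot$effect_allele
  swapped$beta <- -ot$beta
  swapped$eaf <- 1 - ot$eaf
  h1 <- harmonize(ex, ot)
  h2 <- harmonize(ex, swapped)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$se_outcome, h1$se_outcome)
  expect_true(all(h2$flipped))
})

test_that("align_ld negates rows/columns of flipped SNPs", {
  ex <- make_records(3, beta = c(0.07, 0.05, 0.06))
  ot <- make_records(3, beta = c(-0.02, 0.01, 0.03))
  ot$effect_allele[2] <- "G"; ot$other_allele[2] <- "A"
  h <- harmonize(ex, ot)
  corr <- make_ld_block(3, 0.6, snp_ids = h$snp_id)
  al <- align_ld(corr, h)
  expect_equal(al[1, 2], -0.6)
  expect_equal(al[2, 3], -0.6)
  expect_equal(al[1, 3], 0.36)
  expect_equal(diag(unclass(al)), rep(1, 3), ignore_attr = TRUE)
  expect_error(align_ld(make_ld_block(2, 0, snp_ids = c("rs1", "rs2")), h),
               "rs3")
})

test_that("write_results formats at reporting precision", {
  e <- mr_estimate(0.71784, 0.27453, method = "wald", n_snps = 1L,
                   outcome = "asthma", stratum = "EAS:all")
  tf <- withr::local_tempfile(fileext = ".tsv")
  fmt <- write_results(list(e), tf)
  expect_equal(fmt$or, "2.05")
  expect_equal(fmt$ci_low, "1.20")
  expect_equal(fmt$pval, "0.009")
  # upper bound from beta + 1.959964*se (printed sources may round
  # differently in the last digit)
  expect_equal(fmt$ci_high, sprintf("%.2f", exp(0.71784 + qnorm(0.975) *
                                                  0.27453)))
  on_disk <- read.delim(tf, colClasses = "character")
  expect_equal(on_disk$or, "2.05")

  # null effect: OR 1.00, CI symmetric on the log scale
  e0 <- mr_estimate(0, 0.1, method = "wald", n_snps = 1L)
  fmt0 <- write_results(list(e0), tf)
  expect_equal(fmt0$or, "1.00")
  expect_equal(as.numeric(fmt0$ci_low) * as.numeric(fmt0$ci_high), 1,
               tolerance = 0.02)

  # empty input -> header-only file
  write_results(list(), tf)
  expect_equal(length(readLines(tf)), 1L)
})
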