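test_that("wald ratio: point estimate, delta-method SE, null case", {
  h <- make_harmonized(1, 0.1, 0.5, 0.2)
  e <- wald_ratio(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  expect_equal(e$method, "wald")
  expect_equal(e$ci_low, 0.5 - qnorm(0.975) * 0.2)

  h0 <- make_harmonized(1, 0.1, 0, 0.2)
  e0 <- wald_ratio(h0)
  expect_equal(e0$beta, 0)
  expect_equal(e0$pval, 1)

  expect_error(wald_ratio(make_harmonized(0, 0.1, 0.1, 0.2)),
               "null instrument")
  # sign: flipping the exposure allele flips the ratio, not its |value|
  hneg <- make_harmonized(-1, 0.1, 0.5, 0.2)
  expect_equal(wald_ratio(hneg)$beta, -0.5)
  expect_equal(wald_ratio(hneg)$se, 0.2)
})

test_that("first-order wald SE matches parametric bootstrap within 2%", {
  # strong instrument: beta_gx/se_gx = 14, as for a cis lead SNP
  bx <- 0.07; sx <- 0.005; by <- 0.021; sy <- 0.012
  e <- wald_ratio(make_harmonized(bx, sx, by, sy))
  set.seed(20240901)
  n <- 1e5
  draws <- rnorm(n, by, sy) / rnorm(n, bx, sx)
  expect_equal(e$se, sd(draws), tolerance = 0.02)
})

test_that("ivw reduces to wald for one SNP and averages symmetric pairs", {
  h1 <- make_harmonized(0.07, 0.005, 0.021, 0.012)
  expect_equal(ivw(h1)[c("beta", "se", "pval")],
               wald_ratio(h1)[c("beta", "se", "pval")])
  # equal weights, ratios 0.4 and 0.6 -> 0.5
  h2 <- make_harmonized(c(1, 1), c(0.1, 0.1), c(0.4, 0.6), c(0.2, 0.2))
  expect_equal(ivw(h2)$beta, 0.5)
  expect_equal(ivw(h2)$method, "ivw_fixed")
})

test_that("ivw equals weighted least squares through the origin", {
  sc <- hmgcr_like_scenario(ld = 0, theta = 0.3, seed = 5)
  sim <- simulate_two_sample(sc)
  h <- harmonize(sim$exposure, sim$outcome)
  e <- ivw(h, random_effects_min_snps = 99L)  # fixed effects path
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
            weights = 1 / h$se_outcome^2)
  expect_equal(e$beta, unname(coef(fit)), tolerance = 1e-10)
  # fixed-effect SE is the model-based (sigma-free) WLS SE
  se_wls <- sqrt(1 / sum((h$beta_exposure / h$se_outcome)^2))
  expect_equal(e$se, se_wls, tolerance = 1e-12)
})

test_that("SNP-count rule selects fixed vs multiplicative random effects", {
  mk <- function(n, spread) {
    set.seed(99)
    make_harmonized(rep(1, n), rep(0.05, n),
                    0.3 + spread * seq(-1, 1, length.out = n),
                    rep(0.1, n))
  }
  expect_equal(ivw(mk(3, 0.5))$method, "ivw_fixed")
  e4 <- ivw(mk(4, 0.5))
  expect_equal(e4$method, "ivw_random")
  # overdispersion: se inflated by sqrt(Q/(n-2)) when Q/(n-2) > 1
  fixed_se <- 1 / sqrt(sum((1 / 0.1)^2 * rep(1, 4)))
  expect_equal(e4$se, fixed_se * sqrt(e4$q_stat / 2), tolerance = 1e-12)
  # homogeneous 4-SNP set: floor at 1 keeps the fixed-effects SE
  e4h <- ivw(mk(4, 0))
  expect_equal(e4h$method, "ivw_random")
  expect_equal(e4h$se, fixed_se, tolerance = 1e-12)
})

test_that("correlated IVW: identity correlation equals fixed IVW", {
  sc <- hmgcr_like_scenario(ld = 0, theta = 0.2, seed = 8)
  sim <- simulate_two_sample(sc)
  h <- harmonize(sim$exposure, sim$outcome)
  idm <- make_ld_block(6, 0, snp_ids = h$snp_id)
  ec <- ivw_correlated(h, idm)
  ef <- ivw(h, random_effects_min_snps = 99L)
  expect_equal(ec$beta, ef$beta, tolerance = 1e-10)
  expect_equal(ec$se, ef$se, tolerance = 1e-10)
})

test_that("correlated IVW matches the exact-arithmetic GLS oracle", {
  # 3-SNP instance solved in exact rational arithmetic (values frozen)
  h <- make_harmonized(c(0.062, 0.035, 0.030), rep(0.002, 3),
                       c(0.020, 0.013, 0.009), c(0.017, 0.016, 0.018))
  rho <- make_ld_block(3, 0.7, snp_ids = h$snp_id)
  e <- ivw_correlated(h, rho)
  expect_equal(e$beta, 0.314754950871724, tolerance = 1e-10)
  expect_equal(e$se, 0.271174521216400, tolerance = 1e-10)
})

test_that("correlated IVW refuses singular LD and honors ridge", {
  h <- make_harmonized(c(0.06, 0.06), c(0.002, 0.002),
                       c(0.02, 0.02), c(0.017, 0.017))
  r <- matrix(c(1, 1, 1, 1), 2, dimnames = list(h$snp_id, h$snp_id))
  dup <- ld_matrix(r)
  expect_error(ivw_correlated(h, dup), "singular")
  expect_s3_class(ivw_correlated(h, dup, ridge = 1e-4), "mr_estimate")
})

test_that("cochran_q: zero under agreement, hand arithmetic, errors", {
  h <- make_harmonized(c(1, 1, 1), c(0.1, 0.1, 0.1),
                       c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))
  q <- cochran_q(h)
  expect_equal(q$q_stat, 0)
  expect_equal(q$q_pval, 1)
  # theta = {0, 2}, unit weights: Q = 2, df = 1
  h2 <- make_harmonized(c(1, 1), c(0.1, 0.1), c(0, 2), c(1, 1))
  q2 <- cochran_q(h2)
  expect_equal(q2$q_stat, 2)
  expect_equal(q2$q_df, 1)
  expect_equal(q2$q_pval, pchisq(2, 1, lower.tail = FALSE))
  expect_error(cochran_q(make_harmonized(1, 0.1, 0.3, 0.1)),
               "at least 2")
})

test_that("estimates are equivariant under exposure rescaling", {
  sc <- hmgcr_like_scenario(ld = 0, theta = 0.25, seed = 13)
  sim <- simulate_two_sample(sc)
  h <- harmonize(sim$exposure, sim$outcome)
  base <- ivw(h)
  neg <- h; neg$beta_exposure <- -neg$beta_exposure
  expect_equal(ivw(neg)$beta, -base$beta)
  expect_equal(ivw(neg)$se, base$se)
  scaled <- h; scaled$beta_exposure <- 2 * scaled$beta_exposure
  expect_equal(ivw(scaled)$beta, base$beta / 2)
  # same equivariances for the correlated estimator
  rho <- make_ld_block(6, 0, snp_ids = h$snp_id)
  cb <- ivw_correlated(h, rho)$beta
  expect_equal(ivw_correlated(neg, rho)$beta, -cb)
  expect_equal(ivw_correlated(scaled, rho)$beta, cb / 2)
})
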