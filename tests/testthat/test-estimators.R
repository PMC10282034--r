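test_that("Wald ratios follow the first-order formulas and exclude zero gamma", {
  s <- make_hset(gamma = c(0.1, 0.2, 0, -0.1),
                 Gamma = c(0.05, 0, 0.3, 0.1),
                 se_Gamma = c(0.02, 0.02, 0.02, 0.01))
  wr <- wald_ratios(s)
  expect_equal(wr$ratio, c(0.5, 0, -1))
  expect_equal(wr$se, c(0.2, 0.1, 0.1))
  expect_equal(attr(wr, "excluded_zero_gamma"), "rs003")
})

test_that("IVW matches the closed-form example and the GLS oracle", {
  s <- make_hset(gamma = c(1, 2), Gamma = c(1, 4), se_Gamma = c(1, 1))
  f <- mr_ivw(s, "fe")
  expect_equal(f$beta, 9 / 5)
  expect_equal(f$se, 1 / sqrt(5))

  set.seed(101)
  for (i in 1:100) {
    J <- sample(2:8, 1)
    g <- rnorm(J); G <- rnorm(J); se <- runif(J, 0.1, 1)
    s <- make_hset(g, G, se)
    expect_equal(mr_ivw(s)$beta, oracle_ivw(g, G, se), tolerance = 1e-10)
  }
})

test_that("IVW MRE inflates but never deflates the FE standard error", {
  # collinear: shared ratio, sigma capped at 1 -> identical SEs
  s <- make_hset(gamma = c(1, 2, 3), Gamma = c(2, 4, 6),
                 se_Gamma = c(1, 1, 1))
  expect_equal(mr_ivw(s, "mre")$beta, 2)
  expect_equal(mr_ivw(s, "mre")$se, mr_ivw(s, "fe")$se)

  # heterogeneous: MRE se strictly larger
  s2 <- make_hset(gamma = c(1, 1, 1), Gamma = c(-3, 0, 5),
                  se_Gamma = c(0.1, 0.1, 0.1))
  expect_gt(mr_ivw(s2, "mre")$se, mr_ivw(s2, "fe")$se)
  expect_equal(mr_ivw(s2, "mre")$se,
               mr_ivw(s2, "fe")$se * mr_ivw(s2, "mre")$sigma_hat)

  # scaling all gamma by 2 halves the estimate
  s3 <- make_hset(gamma = c(1, 2) * 2, Gamma = c(1, 4), se_Gamma = c(1, 1))
  expect_equal(mr_ivw(s3)$beta, 9 / 10)

  expect_error(mr_ivw(s[1, , drop = FALSE]), "insufficient")
})

test_that("Cochran's Q matches the arithmetic oracle and is permutation invariant", {
  s <- make_hset(gamma = c(1, 1), Gamma = c(1, 3), se_Gamma = c(1, 1))
  got <- cochran_q(s, beta_hat = 2)
  expect_equal(got$q, 2)
  expect_equal(got$q_df, 1L)

  s2 <- make_hset(gamma = c(1, 2, 3), Gamma = c(2, 4, 6), se_Gamma = c(1, 1, 1))
  expect_equal(cochran_q(s2, 2)$q, 0)

  set.seed(5)
  g <- rnorm(6); G <- rnorm(6); se <- runif(6, 0.2, 1)
  q1 <- cochran_q(make_hset(g, G, se), 0.7)$q
  p <- sample(6)
  q2 <- cochran_q(make_hset(g[p], G[p], se[p]), 0.7)$q
  expect_equal(q1, q2)
  expect_equal(q1, oracle_q(g, G, se, 0.7), tolerance = 1e-12)
})

test_that("Egger matches OLS on the textbook fixture and the GLS oracle", {
  s <- make_hset(gamma = c(1, 2, 3), Gamma = c(3, 5, 7), se_Gamma = c(1, 1, 1))
  f <- mr_egger(s)
  expect_equal(f$beta, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)

  set.seed(202)
  for (i in 1:100) {
    J <- sample(3:8, 1)
    g <- rnorm(J); G <- rnorm(J); se <- runif(J, 0.1, 1)
    f <- mr_egger(make_hset(g, G, se))
    o <- oracle_egger(g, G, se)
    expect_equal(f$intercept, o[1], tolerance = 1e-10)
    expect_equal(f$beta, o[2], tolerance = 1e-10)
  }

  # affine property: adding c to every (oriented) outcome shifts the intercept
  g <- c(0.5, 1, 1.5, 2); G <- c(0.2, 0.7, 0.8, 1.4); se <- rep(0.3, 4)
  f0 <- mr_egger(make_hset(g, G, se))
  f1 <- mr_egger(make_hset(g, G + 0.25, se))
  expect_equal(f1$intercept, f0$intercept + 0.25, tolerance = 1e-10)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-10)

  expect_error(mr_egger(make_hset(c(1, 2), c(1, 2), c(1, 1))), "insufficient")
})

test_that("I2_GX is reported missing with a warning flag when degenerate", {
  # all gamma and se_gamma equal -> Q_GX = 0 -> undefined
  s <- make_hset(gamma = c(1, 1, 1), Gamma = c(1, 2, 3),
                 se_Gamma = c(1, 1, 1), se_gamma = c(0.1, 0.1, 0.1))
  f <- mr_egger(s)
  expect_true(is.na(f$i2_gx))
  expect_true(f$egger_nome_warning)

  # strong, spread instruments: I2_GX close to 1, no warning
  s2 <- make_hset(gamma = c(0.1, 0.2, 0.3, 0.4), Gamma = c(0.1, 0.2, 0.3, 0.4),
                  se_Gamma = rep(0.01, 4), se_gamma = rep(0.001, 4))
  f2 <- mr_egger(s2)
  expect_gt(f2$i2_gx, 0.9)
  expect_false(f2$egger_nome_warning)
})

test_that("weighted median interpolates the weighted empirical CDF", {
  # equal weights, odd n: plain sample median
  s <- make_hset(gamma = rep(1, 5), Gamma = c(1, 2, 3, 4, 5),
                 se_Gamma = rep(1, 5))
  expect_equal(mr_weighted_median(s, n_boot = 50)$beta, 3)

  # hand-computed interpolation: ratios {1,2,10}, weights {0.25,0.5,0.25}
  # -> s = {0.125, 0.5, 0.875}, estimate 2
  s2 <- make_hset(gamma = c(1, 1, 1), Gamma = c(1, 2, 10),
                  se_Gamma = c(1, 1 / sqrt(2), 1))
  expect_equal(mr_weighted_median(s2, n_boot = 50)$beta, 2)

  # bootstrap reproducible bit-for-bit under a fixed seed
  set.seed(1)
  g <- rnorm(6, 0.2, 0.02); G <- 0.5 * g + rnorm(6, 0, 0.01)
  s3 <- make_hset(g, G, rep(0.01, 6))
  f1 <- mr_weighted_median(s3, n_boot = 200, seed = 42)
  f2 <- mr_weighted_median(s3, n_boot = 200, seed = 42)
  expect_identical(f1$se, f2$se)
})

test_that("weighted mode finds the plurality ratio", {
  # all ratios identical
  s <- make_hset(gamma = c(1, 2, 4), Gamma = c(0.7, 1.4, 2.8),
                 se_Gamma = rep(0.5, 3))
  expect_equal(mr_weighted_mode(s, n_boot = 50)$beta, 0.7, tolerance = 1e-9)

  # 7 of 10 ratios cluster at 0.5, 3 at 3.0 -> estimate near 0.5
  set.seed(33)
  ratios <- c(rnorm(7, 0.5, 0.02), rnorm(3, 3, 0.02))
  g <- rep(1, 10)
  s2 <- make_hset(g, ratios, rep(0.1, 10))
  f <- mr_weighted_mode(s2, n_boot = 50)
  expect_lt(abs(f$beta - 0.5), f$bandwidth + 0.05)

  # invariant to SNV ordering
  p <- sample(10)
  s3 <- make_hset(g[p], ratios[p], rep(0.1, 10))
  expect_equal(mr_weighted_mode(s3, n_boot = 50)$beta, f$beta,
               tolerance = 1e-12)
})

test_that("every estimator is sign-equivariant in the outcome", {
  set.seed(55)
  g <- rnorm(8, 0.2, 0.05); G <- 0.4 * g + rnorm(8, 0, 0.005)
  se <- runif(8, 0.005, 0.02)
  s <- make_hset(g, G, se)
  sneg <- make_hset(g, -G, se)
  expect_equal(mr_ivw(sneg)$beta, -mr_ivw(s)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(sneg)$beta, -mr_egger(s)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(sneg, n_boot = 10)$beta,
               -mr_weighted_median(s, n_boot = 10)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_mode(sneg, n_boot = 10)$beta,
               -mr_weighted_mode(s, n_boot = 10)$beta, tolerance = 1e-9)
})

test_that("radial MR flags a planted pleiotropic outlier and respects alpha = 0", {
  set.seed(66)
  J <- 20
  g <- rnorm(J, 0.2, 0.03)
  G <- 0.5 * g + rnorm(J, 0, 0.004)
  avg <- mean(abs(0.5 * g))
  G[7] <- G[7] + 10 * avg  # planted outlier
  s <- make_hset(g, G, rep(0.004, J), se_gamma = rep(0.003, J))
  rad <- radial_outliers(s, alpha = 0.05 / J)
  expect_true("rs007" %in% rad$outliers)
  expect_true(rad$converged)
  expect_equal(radial_outliers(s, alpha = 0)$outliers, character(0))
})

test_that("leave-one-out produces one fit per omitted SNV and drives the flag", {
  set.seed(77)
  g <- rnorm(5, 0.3, 0.02); G <- 0.6 * g + rnorm(5, 0, 0.002)
  s <- make_hset(g, G, rep(0.002, 5))
  loo <- leave_one_out(s)
  expect_equal(nrow(loo), 5L)
  expect_equal(loo$omitted, s$snv_id)
  expect_true(attr(loo, "loo_all_nominal"))

  # one SNV carries all the signal: omitting it abolishes significance
  g2 <- c(1, 0.01, 0.011, 0.012)
  G2 <- c(0.8, 0, 0, 0)
  s2 <- make_hset(g2, G2, rep(0.05, 4))
  loo2 <- leave_one_out(s2)
  expect_false(attr(loo2, "loo_all_nominal"))
  expect_gte(loo2$pval[loo2$omitted == "rs001"], 0.05)
})

test_that("single-instrument fallback is a labelled Wald ratio", {
  s <- make_hset(0.2, 0.1, 0.01)
  f <- mr_wald_single(s)
  expect_equal(f$method, "wald_ratio")
  expect_equal(f$beta, 0.5)
  expect_equal(f$se, 0.05)
})
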