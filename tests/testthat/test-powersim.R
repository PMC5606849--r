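test_that("MVN estimation returns sample moments and rank information", {
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Tot.TMD", 1:16)
  fc <- feature_curve(cohort, "Tot.TMD", 1:16)
  X <- as.matrix(fc[paste0("v", 1:16)])
  expect_equal(m$mu, colMeans(X))
  expect_equal(m$cov, cov(X))
  expect_equal(m$sigma^2, diag(cov(X)))
  # 16 fish give a covariance of rank n - 1 = 15 over k = 16 vertebrae
  expect_equal(m$rank, 15)
  expect_true(m$rank_deficient)
  m8 <- estimate_mvn(cohort, "Tot.TMD", 1:8)
  expect_false(m8$rank_deficient)
  # two identical fish: zero covariance
  X2 <- rbind(1:5, 1:5)
  m2 <- estimate_mvn(X2)
  expect_true(all(m2$sigma == 0))
  # n = 3 fish, k = 16: rank at most 2, flagged
  X3 <- matrix(rnorm(3 * 16), 3, 16)
  m3 <- estimate_mvn(X3)
  expect_lte(m3$rank, 2)
  expect_true(m3$rank_deficient)
  expect_error(estimate_mvn(matrix(1, 1, 4)), "at least 2")
})

test_that("MVN moments are recovered from a large simulated cohort", {
  set.seed(71)
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Cent.Vol", 1:8)
  draws <- simulate_cohort(m, NULL, 10000)
  expect_lt(max(abs(colMeans(draws) / m$mu - 1)), 0.02)
  expect_lt(max(abs(diag(cov(draws)) / m$sigma^2 - 1)), 0.1)
})

test_that("effect patterns shift the simulated means as designed", {
  set.seed(72)
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Tot.TMD", 1:16)
  se <- m$sigma / sqrt(1e5)
  # d = 0 reproduces the WT distribution
  d0 <- simulate_cohort(m, effect_pattern(0, "uniform", 16), 1e5)
  expect_true(all(abs(colMeans(d0) - m$mu) < 3 * se))
  # uniform d = 4
  d4 <- simulate_cohort(m, effect_pattern(4, "uniform", 16), 1e5)
  expect_true(all(abs(colMeans(d4) - (m$mu + 4 * m$sigma)) < 3 * se))
  # ramp endpoints: no shift at vertebra 1, full shift at vertebra 16
  pr <- effect_pattern(4, "ramp", 16)
  expect_equal(pr$d_i[1], 0)
  expect_equal(pr$d_i[16], 4)
  dr <- simulate_cohort(m, pr, 1e5)
  expect_lt(abs(mean(dr[, 1]) - m$mu[1]), 3 * se[1])
  expect_lt(abs(mean(dr[, 16]) - (m$mu[16] + 4 * m$sigma[16])), 3 * se[16])
})

test_that("rank-deficient covariances sample on their support", {
  X3 <- matrix(rnorm(3 * 16, 100, 5), 3, 16)
  m3 <- estimate_mvn(X3)
  set.seed(73)
  draws <- simulate_cohort(m3, NULL, 500)
  sv <- svd(sweep(draws, 2, colMeans(draws)))$d
  expect_lt(sv[3] / sv[1], 1e-6)          # all draws lie in a rank-2 slab
})

test_that("power analysis is reproducible and calibrated under the null", {
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Tot.TMD", 1:16)
  a <- run_power_analysis(m, effect_pattern(0, "uniform", 16), n = 3,
                          alpha = 0.05, n_sims = 400, seed = 9)
  b <- run_power_analysis(m, effect_pattern(0, "uniform", 16), n = 3,
                          alpha = 0.05, n_sims = 400, seed = 9)
  expect_identical(a, b)                  # bit-reproducible given the seed
  # with d = 0, sensitivity is a rejection rate under the null: near alpha
  ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / 400)
  for (s in a$sensitivity) {
    expect_gte(s, 0)
    expect_lte(s, ci[2])
  }
})

test_that("a huge effect saturates sensitivity for every procedure", {
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Tot.TMD", 1:16)
  pr <- run_power_analysis(m, effect_pattern(10, "uniform", 16), n = 5,
                           alpha = 0.05, n_sims = 200, seed = 10)
  expect_true(all(pr$sensitivity > 0.99))
})

test_that("sensitivity grows with effect size and sample size", {
  cohort <- wt_cohort16()
  m <- estimate_mvn(cohort, "Tot.TMD", 1:16)
  sens_d <- vapply(c(0.5, 2, 4), function(d)
    run_power_analysis(m, effect_pattern(d, "uniform", 16), n = 3,
                       alpha = 0.05, n_sims = 300, seed = 11,
                       procedures = "global")$sensitivity, 0.0)
  expect_true(all(diff(sens_d) > -0.05))  # monotone within MC error
  sens_n <- vapply(c(2, 4, 8), function(n)
    run_power_analysis(m, effect_pattern(1.5, "uniform", 16), n = n,
                       alpha = 0.05, n_sims = 300, seed = 12,
                       procedures = "global")$sensitivity, 0.0)
  expect_true(all(diff(sens_n) > -0.05))
})

test_that("the FDR estimate follows the two-urn formula", {
  expect_equal(estimate_fdr(1, 0.05), 0.05 / 1.05)
  expect_equal(estimate_fdr(0.05, 0.05), 0.5)
  expect_equal(estimate_fdr(0.96, 0.05), 0.05 / (0.05 + 0.96))
  expect_equal(estimate_fdr(0, 0.05), 1)
  # the workflow's headline operating point lands near 5%
  expect_equal(round(100 * estimate_fdr(0.96, 0.05), 1), 5.0, tolerance = 0.2)
})

test_that("royston screening flags non-normal features only", {
  set.seed(74)
  cohort <- simulate_phenome_cohort(16, seed = 75)
  # corrupt one feature into a strongly skewed distribution
  for (i in seq_along(cohort))
    cohort[[i]]$Cent.Le <- exp(rnorm(nrow(cohort[[i]]), 0, 1.5))
  scr <- screen_features_royston(cohort, c("Tot.TMD", "Cent.Le"), 1:16)
  expect_false(scr$excluded[scr$feature == "Tot.TMD"])
  expect_true(scr$excluded[scr$feature == "Cent.Le"])
})
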