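test_that("the exact permutation p-value matches brute-force enumeration", {
  # k = 1, three fish per group, clearly separated covariate values:
  # only the observed assignment and its mirror reach the observed
  # statistic, so p = 2/20 over the 20 label assignments
  d <- data.frame(group = rep(c("wt", "mut"), each = 3),
                  v1 = c(1, 2, 3, 7, 8, 9))
  gt_perm <- global_test(d, method = "permutation")
  expect_equal(gt_perm$n_permutations, 20L)
  expect_equal(gt_perm$p, 2 / 20)
  gt_asym <- global_test(d)
  expect_lt(gt_asym$p, 0.05)
})

test_that("asymptotic p-values are uniform under the multivariate null", {
  set.seed(41)
  k <- 8
  S <- 0.5 + 0.5 * diag(k)
  A <- chol(S)
  ps <- replicate(1000, {
    X <- matrix(rnorm(20 * k), 20, k) %*% A
    vertebrome:::.gt_pvalue(X, rep(0:1, each = 10))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the global test is invariant to scaling, shifts and label swaps", {
  set.seed(42)
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  matrix(rnorm(8 * 5), 8, 5))
  p0 <- global_test(d)$p
  d_scaled <- d; d_scaled[, -1] <- d[, -1] * 3.7
  expect_equal(global_test(d_scaled)$p, p0, tolerance = 1e-8)
  d_shift <- d; d_shift[, -1] <- d[, -1] + 100
  expect_equal(global_test(d_shift)$p, p0, tolerance = 1e-8)
  d_swap <- d; d_swap$group <- rev(d$group)
  expect_equal(global_test(d_swap)$p, p0, tolerance = 1e-8)
})

test_that("degenerate global-test inputs are rejected", {
  d <- data.frame(group = rep("a", 4), v1 = rnorm(4))
  expect_error(global_test(d), "two levels")
  d2 <- data.frame(group = rep(c("a", "b"), 2))
  expect_error(global_test(d2), "covariates")
})

test_that("component statistics sum to the global statistic", {
  set.seed(43)
  d <- data.frame(group = rep(c("a", "b"), each = 5),
                  matrix(rnorm(10 * 6), 10, 6))
  gt <- global_test(d)
  expect_equal(sum(gt$per_vertebra$statistic), gt$statistic,
               tolerance = 1e-10)
  # identical covariate copies have identical component statistics
  d2 <- d; for (j in 2:7) d2[[j]] <- d$X1
  gt2 <- global_test(d2)
  expect_true(all(abs(gt2$per_vertebra$statistic -
                        gt2$per_vertebra$statistic[1]) < 1e-12))
})

test_that("covariate components localize an injected anterior effect", {
  set.seed(44)
  k <- 16
  hits <- 0; flagged_total <- 0
  for (r in 1:60) {
    wt <- matrix(rnorm(8 * k, 100, 5), 8, k)
    mut <- matrix(rnorm(8 * k, 100, 5), 8, k)
    mut[, 1:5] <- mut[, 1:5] + 3 * 5      # d = 3 at vertebrae 1-5
    d <- data.frame(group = rep(c("wt", "mut"), each = 8),
                    rbind(wt, mut))
    names(d)[-1] <- paste0("v", 1:k)
    got <- covariate_components(global_test(d), alpha = 0.05)
    hits <- hits + (length(intersect(got, 1:5)) >= 3)
    flagged_total <- flagged_total + length(setdiff(got, 1:5))
  }
  expect_gt(hits, 45)                      # majority localization
  # false flags among null vertebrae stay near alpha
  expect_lt(flagged_total / (60 * 11), 0.15)
})

test_that("standard scores self-normalize the control cohort", {
  cohort <- simulate_phenome_cohort(5, seed = 45)
  scores <- lapply(cohort, standard_scores, controls = cohort,
                   vertebrae = 1:16)
  pooled <- unlist(lapply(scores, function(s) s$Cent.TMD))
  expect_equal(mean(pooled), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(pooled^2)), 1, tolerance = 1e-10)
  # value at control mean scores 0; one SD above scores 1
  ph <- cohort[[1]]
  ctrl_vals <- unlist(lapply(cohort, function(p) p$Cent.TMD[1:16]))
  mu <- mean(ctrl_vals); sdv <- sqrt(mean((ctrl_vals - mu)^2))
  ph$Cent.TMD[] <- mu
  expect_equal(standard_scores(ph, cohort, 1:16)$Cent.TMD[1], 0)
  ph$Cent.TMD[] <- mu + sdv
  expect_equal(standard_scores(ph, cohort, 1:16)$Cent.TMD[1], 1)
})

test_that("barcodes are invariant to a common affine rescaling", {
  cohort <- simulate_phenome_cohort(5, seed = 46)
  ph <- cohort[[1]]
  s0 <- standard_scores(ph, cohort, 1:16)
  rescale <- function(p) { p$Neur.Vol <- p$Neur.Vol * 3 + 17; p }
  s1 <- standard_scores(rescale(ph), lapply(cohort, rescale), 1:16)
  expect_equal(s1$Neur.Vol, s0$Neur.Vol, tolerance = 1e-10)
})

test_that("zero control SD flags scores as undefined", {
  cohort <- simulate_phenome_cohort(3, seed = 47)
  for (i in seq_along(cohort)) cohort[[i]]$Cent.Le[] <- 500
  expect_warning(s <- standard_scores(cohort[[1]], cohort, 1:16),
                 "zero control SD")
  expect_true(all(is.na(s$Cent.Le)))
})

test_that("correlation profiles honour duplicates, sign and independence", {
  set.seed(48)
  cohort <- simulate_phenome_cohort(20, seed = 48)
  # exact duplicate and exact negation both give |r| = 1
  for (i in seq_along(cohort)) {
    cohort[[i]]$Neur.SA <- cohort[[i]]$Cent.Vol * 2
    cohort[[i]]$Haem.SA <- -cohort[[i]]$Cent.Vol
  }
  cp <- correlation_profile(cohort, 1:4)
  m <- cp$matrix
  expect_true(isSymmetric(unname(m)))
  expect_true(all(abs(diag(m) - 1) < 1e-12))
  nm <- colnames(m)
  expect_equal(m["Cent.Vol_2", "Neur.SA_2"], 1, tolerance = 1e-12)
  expect_equal(m["Cent.Vol_3", "Haem.SA_3"], 1, tolerance = 1e-12)
})

test_that("independent columns give a small median absolute correlation", {
  set.seed(49)
  M <- matrix(rnorm(200 * 30), 200, 30)
  cc <- abs(cor(M))
  expect_lt(median(cc[upper.tri(cc)]), 0.1)
})

test_that("royston reduces to Shapiro-Wilk for one variable", {
  set.seed(50)
  x <- rnorm(40)
  rt <- royston_test(matrix(x, ncol = 1))
  expect_equal(rt$p.value, shapiro.test(x)$p.value, tolerance = 1e-6)
})

test_that("royston holds its size under MVN and rejects log-normal data", {
  set.seed(51)
  k <- 8
  S <- 0.4 + 0.6 * diag(k)
  A <- chol(S)
  rej <- mean(replicate(300, {
    royston_test(matrix(rnorm(50 * k), 50, k) %*% A)$p.value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
  power <- mean(replicate(100, {
    royston_test(exp(matrix(rnorm(50 * 4, 0, 1.2), 50, 4)))$p.value < 0.05
  }))
  expect_gt(power, 0.9)
})

test_that("royston demands more observations than variables", {
  expect_error(royston_test(matrix(rnorm(5 * 6), 5, 6)), "subsets")
  expect_error(royston_test(matrix(rnorm(3), 3, 1)), "at least 4")
})
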