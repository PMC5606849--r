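test_that("TMC is the unit-converted volume-density product", {
  expect_equal(derive_tmc(1e12, 500), 500)   # 1 cm^3 at 500 mgHA/cm^3
  expect_equal(derive_tmc(0, 700), 0)
  expect_warning(derive_tmc(10, -5), "negative")
  # phantom element: designed volume x uniform density, exact
  ph <- noiseless_phantom()
  tr <- ph$truth[1, ]
  expect_equal(derive_tmc(tr$Cent.Vol, tr$Cent.TMD),
               tr$Cent.Vol * 1e-12 * tr$Cent.TMD)
})

test_that("power-law fits recover coefficients exactly on noiseless data", {
  x <- 18:32
  m <- fit_power_law(x, 2 * x^3)
  expect_equal(m$a, 2, tolerance = 1e-10)
  expect_equal(m$b, 3, tolerance = 1e-10)
  expect_equal(fit_power_law(x, rep(7, length(x)))$b, 0, tolerance = 1e-10)
  expect_equal(fit_power_law(x, 5 * x)$b, 1, tolerance = 1e-10)
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(1, 2, 3), c(1, -2, 3)), "fish")
})

test_that("the slope estimate is unbiased under log-normal noise", {
  set.seed(61)
  x <- runif(16, 18, 32)
  bhat <- replicate(1000, fit_power_law(x, 2 * x^3 * exp(rnorm(16, 0, 0.1)))$b)
  se <- sd(bhat) / sqrt(1000)
  expect_lt(abs(mean(bhat) - 3), 4 * se)
})

test_that("fitted exponents are stable across subsamples of 10+ fish", {
  set.seed(62)
  x <- seq(18, 32, length.out = 16)
  y <- 0.5 * x^2.7 * exp(rnorm(16, 0, 0.05))
  bs <- replicate(50, {
    ix <- sample(16, 10)
    fit_power_law(x[ix], y[ix])$b
  })
  expect_lt((max(bs) - min(bs)) / mean(bs), 0.1)
})

test_that("normalization follows y * (x_ref/x)^b and collapses cohorts", {
  expect_equal(allometric_normalize(5, 2, 4, 3), 40)
  expect_equal(allometric_normalize(9, 7, 7, 2.3), 9)   # x_ref = x
  # a cohort generated exactly from y = a x^b collapses to CV = 0
  x <- seq(18, 30, length.out = 10)
  y <- 3 * x^2.5
  ystar <- allometric_normalize(y, x, 24, 2.5)
  expect_equal(coefficient_of_variation(ystar), 0, tolerance = 1e-12)
  expect_true(all(abs(ystar - 3 * 24^2.5) < 1e-9))
})

test_that("phenome normalization is exact where structure is power-law", {
  cohort <- simulate_phenome_cohort(8, seed = 63)
  models <- fit_allometry(cohort)
  ph <- cohort[[1]]
  x <- attr(ph, "standard_length")
  # normalizing to the fish's own length is the identity
  same <- normalize_phenome(ph, models, x)
  for (m in c("Cent.Vol", "Cent.TMD", "Neur.Th", "Cent.Le"))
    expect_equal(same[[m]], ph[[m]], tolerance = 1e-10)
  # round trip: normalize to x_ref, then back to x
  there <- normalize_phenome(ph, models, 25)
  back <- normalize_phenome(there, models, x)
  for (m in c("Cent.Vol", "Cent.TMD", "Neur.Th", "Cent.Le", "Cent.TMD.sd"))
    expect_equal(back[[m]], ph[[m]], tolerance = 1e-8)
})

test_that("normalized TMD comes from the TMC/Vol two-step", {
  cohort <- simulate_phenome_cohort(8, seed = 64)
  models <- fit_allometry(cohort)
  ph <- cohort[[2]]
  x <- attr(ph, "standard_length")
  np <- normalize_phenome(ph, models, 24)
  b_tmc <- models$b[models$feature == "Cent.TMC"]
  b_vol <- models$b[models$feature == "Cent.Vol"]
  expect_equal(np$Cent.TMD, ph$Cent.TMD * (24 / x)^(b_tmc - b_vol),
               tolerance = 1e-10)
})

test_that("isometric growth leaves TMD unchanged by normalization", {
  # uniform-density cohort grown exactly isometrically: Vol ~ L^3,
  # TMD constant, so TMC ~ L^3 and the exponents cancel
  x <- seq(18, 30, length.out = 8)
  cohort <- lapply(seq_along(x), function(i) {
    tb <- tibble::tibble(vertebra = 1:16,
                         Cent.Vol = 2e7 * (x[i] / 20)^3,
                         Cent.TMD = 500)
    vertebrome:::new_phenome(tb, standard_length = x[i])
  })
  models <- fit_allometry(cohort, features = c("Cent.Vol", "Cent.TMC"))
  np <- normalize_phenome(suppressWarnings(cohort[[1]]), models, 24)
  expect_equal(np$Cent.TMD, cohort[[1]]$Cent.TMD, tolerance = 1e-8)
})

test_that("normalization to the cohort mean shrinks the CV of scaled features", {
  cohort <- simulate_phenome_cohort(10, sl_mean = 24, sl_sd = 3, seed = 65)
  models <- fit_allometry(cohort)
  x_ref <- mean(vapply(cohort, function(p) attr(p, "standard_length"), 0.0))
  raw <- vapply(cohort, function(p) mean(p$Cent.Vol[1:16]), 0.0)
  nrm <- vapply(cohort, function(p)
    mean(normalize_phenome(p, models, x_ref)$Cent.Vol[1:16]), 0.0)
  expect_lt(coefficient_of_variation(nrm), coefficient_of_variation(raw))
})

test_that("CV follows its definition", {
  expect_equal(coefficient_of_variation(c(4, 4, 4)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)   # psd 1, mean 2
  v <- c(2, 5, 9)
  expect_equal(coefficient_of_variation(v * 13), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("allometric model tables round-trip as text", {
  cohort <- simulate_phenome_cohort(6, seed = 66)
  models <- fit_allometry(cohort, features = c("Cent.Vol", "Cent.Le"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_allometry(models, f)
  back <- read_allometry(f)
  expect_equal(back$b, models$b, tolerance = 1e-10)
  expect_equal(back$feature, models$feature)
})
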