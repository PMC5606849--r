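# Monte-Carlo engine: multivariate-normal models of vertebral feature
# curves, simulated WT/mutant cohorts under uniform or ramped effect
# patterns, and sensitivity/specificity/power estimation for three test
# procedures (global test, single-vertebra t-test, vertebra-averaged
# t-test).

#' Estimate a multivariate-normal model of one feature curve
#'
#' Sample mean vector and sample covariance (denominator n - 1) of a
#' feature across fish, one variable per vertebra. Rank deficiency
#' (n <= k) is allowed and recorded.
#'
#' @param cohort List of `phenome` objects (>= 2 fish) or a numeric
#'   matrix (fish x vertebrae).
#' @param feature Measure short name (ignored for the matrix interface).
#' @param vertebrae Vertebra window (k variables).
#' @return `mvn_model`: `mu`, `sigma`, `cov`, `k`, `n`, `feature`,
#'   `rank`, `rank_deficient`.
#' @export
estimate_mvn <- function(cohort, feature = NULL, vertebrae = 1:16) {
  X <- if (is.matrix(cohort)) cohort else {
    fc <- feature_curve(cohort, feature, vertebrae)
    as.matrix(fc[paste0("v", vertebrae)])
  }
  if (nrow(X) < 2) abort("need at least 2 fish")
  if (anyNA(X)) abort("missing values in the vertebra range")
  S <- cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  rk <- sum(ev > max(ev) * 1e-10)
  structure(list(mu = colMeans(X), sigma = sqrt(diag(S)), cov = S,
                 k = ncol(X), n = nrow(X), feature = feature,
                 rank = rk, rank_deficient = rk < ncol(X)),
            class = "mvn_model")
}

#' @export
print.mvn_model <- function(x, ...) {
  cat(sprintf("<mvn_model> %s: k = %d vertebrae from n = %d fish%s\n",
              x$feature %||% "feature", x$k, x$n,
              if (x$rank_deficient) sprintf(" (rank %d, deficient)", x$rank)
              else ""))
  invisible(x)
}

#' Per-vertebra effect pattern
#'
#' Mutant mean shifts in units of the WT per-vertebra SD: uniform
#' (`d_i = d`) or a linear anterior-to-posterior ramp
#' (`d_i = ((i - 1) / (k - 1)) * d`, so `d_1 = 0` and `d_k = d`).
#'
#' @param d Characteristic effect size (>= 0).
#' @param shape `"uniform"` or `"ramp"`.
#' @param k Number of vertebrae.
#' @return `effect_pattern`: `d`, `shape`, `d_i` (length k).
#' @export
effect_pattern <- function(d, shape = c("uniform", "ramp"), k = 16) {
  shape <- match.arg(shape)
  if (d < 0) abort("`d` must be >= 0")
  d_i <- switch(shape, uniform = rep(d, k),
                ramp = (seq_len(k) - 1) / (k - 1) * d)
  structure(list(d = d, shape = shape, d_i = d_i, k = k),
            class = "effect_pattern")
}

# square root factor of a (possibly rank-deficient) covariance by
# eigen-decomposition; negative eigenvalues clipped at zero
.cov_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  n_clip <- sum(lam < 0)
  lam[lam < 0] <- 0
  attr_out <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  attr(attr_out, "n_clipped") <- n_clip
  attr_out
}

#' Simulate a cohort from an MVN model with an effect pattern
#'
#' Draws `n` fish from `MVN(mu + d_i * sigma_i, cov)`. `d = 0` (or a NULL
#' pattern) reproduces the WT distribution; covariances are assumed equal
#' in the WT and mutant distributions. Rank-deficient covariances are
#' sampled through the eigen-decomposition with negative eigenvalues
#' clipped at 0.
#'
#' @param model An `mvn_model`.
#' @param pattern An [effect_pattern()] or `NULL` for no shift.
#' @param n Number of fish.
#' @return n x k numeric matrix.
#' @export
simulate_cohort <- function(model, pattern = NULL, n = 3) {
  stopifnot(inherits(model, "mvn_model"), n >= 1)
  k <- model$k
  shift <- if (is.null(pattern)) rep(0, k) else {
    stopifnot(inherits(pattern, "effect_pattern"))
    if (pattern$k != k) abort("pattern k does not match the model")
    pattern$d_i * model$sigma
  }
  A <- .cov_factor(model$cov)
  Z <- matrix(rnorm(n * k), n, k)
  sweep(Z %*% t(A), 2, model$mu + shift, `+`)
}

# Welch two-sample p-value (two-tailed, unequal variances)
.welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  se2 <- va + vb
  if (se2 == 0) return(1)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  2 * pt(-abs(t), df)
}

#' Monte-Carlo sensitivity and specificity of the three test procedures
#'
#' For each replicate a WT and a mutant cohort are drawn for sensitivity
#' (fraction of replicates with p < alpha) and two WT cohorts for
#' specificity (1 minus that fraction), for: (a) the global test over the
#' full vertebra window, (b) a two-tailed Welch t-test of one vertebra
#' (`t_single`, vertebra 2 by default), and (c) a Welch t-test of the
#' per-fish mean across the window (`t_mean`).
#'
#' @param model An `mvn_model` (the WT distribution).
#' @param pattern An [effect_pattern()] describing the mutant shift.
#' @param n Fish per group.
#' @param alpha Significance level in (0, 1).
#' @param n_sims Number of Monte-Carlo replicates (>= 100; the workflow
#'   default is 10,000).
#' @param procedures Subset of `c("global", "t_single", "t_mean")`.
#' @param t_vertebra Vertebra used by `t_single` (index within the
#'   window).
#' @param mutant_model Optional separate `mvn_model` for the mutant group
#'   (its own means and covariances); `pattern` is ignored when supplied.
#' @param seed RNG seed recorded in the result.
#' @return `power_result` tibble: one row per procedure with
#'   `sensitivity`, `specificity`, and the design columns.
#' @export
run_power_analysis <- function(model, pattern = effect_pattern(4, "uniform",
                                                               model$k),
                               n = 3, alpha = 0.05, n_sims = 10000,
                               procedures = c("global", "t_single",
                                              "t_mean"),
                               t_vertebra = 2, mutant_model = NULL,
                               seed = NULL) {
  stopifnot(inherits(model, "mvn_model"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (n_sims < 100) abort("`n_sims` must be >= 100")
  procedures <- match.arg(procedures, several.ok = TRUE)
  if (n < 2 && any(procedures != "global"))
    abort("t-tests need at least 2 fish per group")
  if (!is.null(seed)) set.seed(seed)
  k <- model$k
  y <- rep(c(0, 1), each = n)
  rej_sens <- rej_spec <- setNames(numeric(length(procedures)), procedures)
  mut_draw <- function() {
    if (is.null(mutant_model)) simulate_cohort(model, pattern, n)
    else simulate_cohort(mutant_model, NULL, n)
  }
  one <- function(a, b) {
    X <- rbind(a, b)
    out <- numeric(0)
    for (pr in procedures) {
      p <- switch(pr,
        global = .gt_pvalue(X, y),
        t_single = .welch_p(a[, t_vertebra], b[, t_vertebra]),
        t_mean = .welch_p(rowMeans(a), rowMeans(b)))
      out[pr] <- p
    }
    out
  }
  for (i in seq_len(n_sims)) {
    wt1 <- simulate_cohort(model, NULL, n)
    mu1 <- mut_draw()
    rej_sens <- rej_sens + (one(wt1, mu1) < alpha)
    wt2 <- simulate_cohort(model, NULL, n)
    wt3 <- simulate_cohort(model, NULL, n)
    rej_spec <- rej_spec + (one(wt2, wt3) < alpha)
  }
  out <- tibble::tibble(
    procedure = procedures,
    n = n, alpha = alpha,
    d = if (is.null(mutant_model)) pattern$d else NA_real_,
    shape = if (is.null(mutant_model)) pattern$shape else "empirical",
    sensitivity = unname(rej_sens[procedures]) / n_sims,
    specificity = 1 - unname(rej_spec[procedures]) / n_sims,
    n_sims = n_sims, seed = seed %||% NA_integer_)
  class(out) <- c("power_result", class(out))
  out
}

#' False discovery rate under equal null and alternative prevalence
#'
#' The two-urn estimate `FDR = alpha / (alpha + sensitivity)`: with equal
#' numbers of null and alternative comparisons, false positives arrive at
#' rate alpha and true positives at the test's sensitivity.
#'
#' @param sensitivity Test sensitivity in (0, 1\].
#' @param alpha Significance level.
#' @return Estimated FDR (1 when sensitivity is 0).
#' @export
estimate_fdr <- function(sensitivity, alpha = 0.05) {
  ifelse(sensitivity <= 0, 1, alpha / (alpha + sensitivity))
}
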