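# Statistical workflow: global score test on vertebral patterns, skeletal
# barcodes, pairwise-correlation profiling, Royston MVN screening.

# ---- quadratic-form tail probability ------------------------------------

# P(sum_j lambda_j * chisq_1 >= 0) by Imhof's integral; normal
# approximation as a fallback when numerical inversion fails.
.imhof_p0 <- function(lambda) {
  lambda <- lambda[abs(lambda) > 1e-12 * max(abs(lambda), 1e-300)]
  if (length(lambda) == 0) return(NA_real_)
  if (all(lambda > 0)) return(1)
  if (all(lambda < 0)) return(0)
  # P(sum lambda_j z_j^2 >= 0) is invariant to a positive rescaling of the
  # weights; normalizing keeps the integrand's scale at O(1) in u
  lambda <- lambda / max(abs(lambda))
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u)))
    lr <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    out <- ifelse(u == 0, sum(lambda) / 2, sin(th) / (u * exp(lr)))
    out
  }
  p <- tryCatch({
    v <- integrate(integrand, 0, Inf, subdivisions = 500L,
                   rel.tol = 1e-8, abs.tol = 1e-10, stop.on.error = FALSE)
    0.5 + v$value / pi
  }, error = function(e) NA_real_)
  if (is.na(p) || p < -1e-3 || p > 1 + 1e-3) {
    # two-moment fallback
    m <- sum(lambda); s <- sqrt(2 * sum(lambda^2))
    p <- pnorm(0, mean = m, sd = s, lower.tail = FALSE)
  }
  min(max(p, 0), 1)
}

# asymptotic p-value of the ratio statistic s = (yc' Xc Xc' yc)/(yc' yc)
# for column-centred Xc: P(W' Xc Xc' W / W' H W >= s), W ~ N(0, I_n)
.gt_ratio_p <- function(Xc, s) {
  n <- nrow(Xc)
  H <- diag(n) - 1 / n
  M <- tcrossprod(Xc) - s * H
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  .imhof_p0(lam)
}

.gt_statistic <- function(Xc, y) {
  yc <- y - mean(y)
  drop(crossprod(crossprod(Xc, yc))) / drop(crossprod(yc))
}

# fast internal path used by the Monte-Carlo engine: asymptotic p only
.gt_pvalue <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  .gt_ratio_p(Xc, .gt_statistic(Xc, y))
}

#' Extract one feature as a fish-by-vertebra curve
#'
#' @param cohort List of `phenome` objects (see [read_phenome_dir()],
#'   [assemble_phenome()], [simulate_phenome_cohort()]).
#' @param feature Measure short name, e.g. `"Cent.TMD"`.
#' @param vertebrae Vertebra window (default the 16 anterior-most).
#' @return Tibble with `fish`, `group`, and one column `v<i>` per
#'   vertebra.
#' @export
feature_curve <- function(cohort, feature, vertebrae = 1:16) {
  rows <- purrr::imap(cohort, function(ph, id) {
    v <- ph[[feature]][match(vertebrae, ph$vertebra)]
    out <- tibble::as_tibble(setNames(as.list(v), paste0("v", vertebrae)))
    dplyr::bind_cols(tibble::tibble(fish = as.character(id),
                                    group = attr(ph, "group")), out)
  })
  dplyr::bind_rows(rows)
}

#' Global test for a difference in vertebral patterns between two groups
#'
#' Goeman-style score test: the binary group indicator is the response and
#' the per-vertebra values are the covariates. The statistic is the
#' centred-response quadratic form through the covariate Gram matrix,
#' scaled by the response sum of squares (so it is invariant to scaling of
#' either response or covariates); its null distribution is the
#' corresponding mixture of chi-squares, with the p-value obtained by
#' numerical inversion (Imhof), or optionally by permutation of group
#' labels (exact enumeration when the number of distinct assignments is at
#' most `max_permutations`). Covariates are centred but not standardized,
#' so covariance-driven weighting is preserved.
#'
#' @param data Data frame with a `group` column (exactly two levels) and
#'   covariate columns, e.g. from [feature_curve()]; non-covariate columns
#'   `fish`/`group` are dropped automatically. Alternatively a numeric
#'   matrix plus `group` vector.
#' @param group Group labels (needed only for the matrix interface).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_permutations Monte-Carlo permutations when exact enumeration is
#'   infeasible.
#' @param max_permutations Enumeration limit for the exact permutation
#'   p-value.
#' @return An object of class `global_test_result`: `statistic`, `p`,
#'   per-vertebra component statistics/p-values, and bookkeeping. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
global_test <- function(data, group = NULL,
                        method = c("asymptotic", "permutation"),
                        n_permutations = 10000, max_permutations = 20000) {
  method <- match.arg(method)
  if (is.data.frame(data)) {
    if (is.null(group)) group <- data$group
    X <- as.matrix(data[setdiff(names(data), c("fish", "group"))])
  } else {
    X <- as.matrix(data)
  }
  if (is.null(group)) abort("`group` is required")
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("`group` must have exactly two levels")
  if (any(table(g) == 0)) abort("both groups must be non-empty")
  if (ncol(X) == 0) abort("no covariates")
  if (anyNA(X)) abort("missing values in the analyzed vertebra range")
  y <- as.numeric(g == levels(g)[2])
  if (var(y) == 0) abort("constant response")
  n <- nrow(X); k <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  s_obs <- .gt_statistic(Xc, y)

  comp <- tibble::tibble(
    vertebra = colnames(X) %||% paste0("v", seq_len(k)),
    statistic = vapply(seq_len(k), function(j)
      .gt_statistic(Xc[, j, drop = FALSE], y), 0.0),
    p = vapply(seq_len(k), function(j)
      .gt_ratio_p(Xc[, j, drop = FALSE],
                  .gt_statistic(Xc[, j, drop = FALSE], y)), 0.0))

  if (method == "asymptotic") {
    p <- .gt_ratio_p(Xc, s_obs)
    n_perm <- NA_integer_
  } else {
    n1 <- sum(y == 1)
    n_assign <- choose(n, n1)
    if (n_assign <= max_permutations) {
      sets <- utils::combn(n, n1)
      stats <- apply(sets, 2, function(ix) {
        yy <- numeric(n); yy[ix] <- 1
        .gt_statistic(Xc, yy)
      })
      p <- mean(stats >= s_obs - 1e-12)
      n_perm <- as.integer(n_assign)
    } else {
      stats <- replicate(n_permutations, .gt_statistic(Xc, sample(y)))
      p <- (sum(stats >= s_obs - 1e-12) + 1) / (n_permutations + 1)
      n_perm <- as.integer(n_permutations)
    }
  }
  structure(list(statistic = s_obs, p = p, per_vertebra = comp,
                 method = method, n_permutations = n_perm,
                 n = n, k = k, groups = levels(g),
                 group_sizes = as.integer(table(g))),
            class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf("Global test: %d vs %d subjects, %d covariates\n",
              x$group_sizes[1], x$group_sizes[2], x$k))
  cat(sprintf("  statistic = %.4g, p = %.4g (%s)\n", x$statistic, x$p,
              x$method))
  invisible(x)
}

#' @export
tidy.global_test_result <- function(x, ...) x$per_vertebra

#' @export
glance.global_test_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p, n = x$n,
                 k = x$k, method = x$method)
}

#' Vertebrae significantly associated with group
#'
#' Per-vertebra component p-values of a fitted global test, unadjusted
#' (vertebral clusters are reported descriptively, not as confirmatory
#' tests).
#'
#' @param result A `global_test_result`.
#' @param alpha Component-level significance threshold.
#' @return Integer (or character) vector of vertebrae with component
#'   `p < alpha`.
#' @export
covariate_components <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "global_test_result"))
  v <- result$per_vertebra$vertebra[result$per_vertebra$p < alpha]
  iv <- suppressWarnings(as.integer(sub("^v", "", v)))
  if (!anyNA(iv)) iv else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- skeletal barcodes ---------------------------------------------------

#' Skeletal barcode: standard scores against a control population
#'
#' For every measure, the score of a value is its difference from the
#' measure's mean across all vertebrae and all fish of the control
#' population, divided by the corresponding pooled standard deviation
#' (population SD). Control fish scored against their own cohort therefore
#' pool to mean 0, SD 1 per measure.
#'
#' @param phenome A `phenome` to score.
#' @param controls List of control `phenome` objects.
#' @param vertebrae Vertebra window used for pooling and scoring.
#' @return A `barcode` tibble: `vertebra` plus one standard-score column
#'   per measure. Measures with zero control SD are flagged `NA` with a
#'   warning.
#' @export
standard_scores <- function(phenome, controls, vertebrae = NULL) {
  if (length(controls) == 0) abort("control population is empty")
  measures <- intersect(names(measure_names()), names(phenome))
  if (is.null(vertebrae)) vertebrae <- phenome$vertebra
  pool <- function(m) unlist(lapply(controls, function(ph)
    ph[[m]][ph$vertebra %in% vertebrae]))
  out <- tibble::tibble(vertebra = phenome$vertebra[
    phenome$vertebra %in% vertebrae])
  for (m in measures) {
    ctrl <- pool(m)
    mu <- mean(ctrl, na.rm = TRUE)
    sdv <- .psd(ctrl[!is.na(ctrl)])
    vals <- phenome[[m]][phenome$vertebra %in% vertebrae]
    if (!is.finite(sdv) || sdv == 0) {
      warn(sprintf("zero control SD for %s: scores undefined", m))
      out[[m]] <- NA_real_
    } else {
      out[[m]] <- (vals - mu) / sdv
    }
  }
  class(out) <- c("barcode", class(out))
  out
}

# ---- correlation profiling ----------------------------------------------

#' Pairwise correlation profile of all measurements
#'
#' Every combination of vertebra and measure becomes one measurement, a
#' vector across fish; absolute Pearson correlations are computed for
#' every pair with per-pair exclusion of fish carrying missing values.
#' The matrix is ordered by hierarchical clustering (average linkage on
#' 1 - |rho|) for display, and the median off-diagonal |rho| is reported.
#'
#' @param cohort List of `phenome` objects (n >= 3 fish).
#' @param vertebrae Vertebra range entering the profile.
#' @param min_fish Measurements with fewer non-missing fish are dropped
#'   with a warning.
#' @return `correlation_profile` object: `matrix` (clustered order),
#'   `median_abs_r`, `n_measurements`, `order`.
#' @export
correlation_profile <- function(cohort, vertebrae = 1:24, min_fish = 3) {
  if (length(cohort) < 3) abort("need at least 3 fish")
  measures <- intersect(names(measure_names()), names(cohort[[1]]))
  cols <- list()
  for (m in measures)
    for (v in vertebrae)
      cols[[paste0(m, "_", v)]] <- vapply(cohort, function(ph) {
        val <- ph[[m]][match(v, ph$vertebra)]
        if (length(val) == 0) NA_real_ else val
      }, 0.0)
  M <- do.call(cbind, cols)
  n_ok <- colSums(!is.na(M))
  drop <- n_ok < min_fish
  if (any(drop)) {
    warn(sprintf("%d measurements with < %d non-missing fish dropped",
                 sum(drop), min_fish))
    M <- M[, !drop, drop = FALSE]
  }
  cc <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  ac <- abs(cc)
  hc <- hclust(as.dist(1 - ac), method = "average")
  ord <- hc$order
  med <- median(ac[upper.tri(ac)])
  structure(list(matrix = ac[ord, ord], median_abs_r = med,
                 n_measurements = ncol(ac), order = ord),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf(
    "<correlation_profile> %d measurements, median |r| = %.3f\n",
    x$n_measurements, x$median_abs_r))
  invisible(x)
}

# ---- Royston multivariate normality -------------------------------------

# Royston's normalizing transformation of the Shapiro-Wilk W
.royston_z <- function(W, n) {
  if (n >= 4 && n <= 11) {
    x <- n
    g <- -2.273 + 0.459 * x
    m <- 0.5440 - 0.39978 * x + 0.025054 * x^2 - 0.0006714 * x^3
    s <- exp(1.3822 - 0.77857 * x + 0.062767 * x^2 - 0.0020322 * x^3)
    (-log(g - log(1 - W)) - m) / s
  } else {
    x <- log(n)
    m <- -1.5861 - 0.31082 * x - 0.083751 * x^2 + 0.0038915 * x^3
    s <- exp(-0.4803 - 0.082676 * x + 0.0030302 * x^2)
    (log(1 - W) - m) / s
  }
}

#' Royston's H test for multivariate normality
#'
#' Combines per-variable Shapiro-Wilk statistics, transformed to
#' equivalent chi-squares, with an equivalent-degrees-of-freedom correction
#' for the correlation between variables. Requires more observations than
#' variables; when a feature has too many vertebrae for the sample, test
#' subsets of vertebrae instead.
#'
#' @param data Numeric matrix or data frame, n observations x k variables
#'   (n > k, n >= 4).
#' @return Tibble with `H`, `df` (equivalent degrees of freedom) and
#'   `p.value`.
#' @export
royston_test <- function(data) {
  X <- as.matrix(data)
  n <- nrow(X); k <- ncol(X)
  if (n < 4) abort("need at least 4 observations")
  if (n <= k)
    abort(paste("more variables than observations:",
                "test subsets of vertebrae so that k < n"))
  z <- vapply(seq_len(k), function(j)
    .royston_z(shapiro.test(X[, j])$statistic, n), 0.0)
  R <- qnorm(pnorm(-z) / 2)^2
  if (k == 1) {
    H <- R; e <- 1
  } else {
    u <- 0.715
    v <- 0.21364 + 0.015124 * log(n)^2 - 0.0018034 * log(n)^3
    l <- 5
    C <- cor(X)
    cc <- C[upper.tri(C)]
    NC <- (cc^l) * (1 - (u * (1 - cc)^u) / v)
    cbar <- sum(NC, na.rm = TRUE) * 2 / (k * (k - 1))
    cbar <- min(max(cbar, 0), 1)
    e <- k / (1 + (k - 1) * cbar)
    H <- e * sum(R) / k
  }
  tibble::tibble(H = unname(H), df = e,
                 p.value = pchisq(unname(H), df = e, lower.tail = FALSE))
}

#' Screen features for multivariate normality
#'
#' Splits the vertebra window into two interleaved subsets (odd and even
#' vertebrae) so that the number of variables stays below the sample size,
#' runs [royston_test()] on each subset of each feature, and flags
#' features whose p-value falls below `alpha` in either subset. Flagged
#' features are excluded from Monte-Carlo simulation by default.
#'
#' @param cohort List of `phenome` objects.
#' @param features Measure names to screen.
#' @param vertebrae Vertebra window.
#' @param alpha Significance level for flagging.
#' @return Tibble: `feature`, `p_odd`, `p_even`, `excluded`.
#' @export
screen_features_royston <- function(cohort, features, vertebrae = 1:16,
                                    alpha = 0.05) {
  odd <- vertebrae[seq_along(vertebrae) %% 2 == 1]
  even <- vertebrae[seq_along(vertebrae) %% 2 == 0]
  rows <- purrr::map(features, function(f) {
    mat <- function(vv) {
      fc <- feature_curve(cohort, f, vv)
      as.matrix(fc[paste0("v", vv)])
    }
    p1 <- royston_test(mat(odd))$p.value
    p2 <- royston_test(mat(even))$p.value
    tibble::tibble(feature = f, p_odd = p1, p_even = p2,
                   excluded = p1 < alpha | p2 < alpha)
  })
  dplyr::bind_rows(rows)
}
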