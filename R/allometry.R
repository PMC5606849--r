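# Allometric growth models: power-law fits per feature, normalization of
# phenomes to a reference standard length, TMC and the two-step TMD
# normalization.

#' Tissue mineral content from volume and TMD
#'
#' TMC (mgHA) is the product of element volume and mean TMD, with the
#' micrometre-to-centimetre unit conversion (1 µm³ = 1e-12 cm³). TMC is
#' mass-like, so its isometric scaling exponent (3) is directly
#' interpretable, unlike TMD's.
#'
#' @param vol Volume in µm³.
#' @param tmd Mean tissue mineral density in mgHA/cm³ (negative values are
#'   flagged with a warning).
#' @return TMC in mgHA.
#' @export
derive_tmc <- function(vol, tmd) {
  if (any(vol < 0, na.rm = TRUE)) abort("volumes must be >= 0")
  if (any(tmd < 0, na.rm = TRUE)) warn("negative TMD values in TMC")
  vol * 1e-12 * tmd
}

#' Fit a power-law growth model y = a * x^b
#'
#' Ordinary least squares on log(y) ~ log(x): `a = exp(intercept)`,
#' `b = slope`. Exact on noiseless power-law data; with multiplicative
#' log-normal noise the slope estimate is unbiased.
#'
#' @param x Standard lengths, mm (> 0).
#' @param y Feature values (> 0), same length.
#' @param feature Optional feature name recorded in the model.
#' @return `allometric_model`: `a`, `b`, `r_squared`, `n`, `feature`,
#'   `b_isometric` (3 for Vol/TMC, 1 for Th/Le, 2 for SA, NA otherwise).
#'   Has [tidy()] and [glance()] methods.
#' @export
fit_power_law <- function(x, y, feature = NA_character_) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 fish")
  if (any(x <= 0) || any(y <= 0))
    abort(sprintf("non-positive values for fish %s",
                  paste(which(x <= 0 | y <= 0), collapse = ", ")))
  fit <- lm(log(y) ~ log(x))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(feature = feature, a = unname(exp(coef(fit)[1])),
                 b = unname(coef(fit)[2]), r_squared = r2, n = length(x),
                 b_isometric = .isometric_exponent(feature)),
            class = "allometric_model")
}

.isometric_exponent <- function(feature) {
  if (is.na(feature)) return(NA_real_)
  q <- sub("^(Tot|Cent|Neur|Haem)\\.", "", feature)
  switch(q, Vol = 3, TMC = 3, SA = 2, Th = 1, Le = 1, NA_real_)
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s: y = %.4g * x^%.4g (R2 = %.3f, n = %d)\n",
              x$feature, x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.allometric_model <- function(x, ...) {
  tibble::tibble(feature = x$feature, a = x$a, b = x$b,
                 b_isometric = x$b_isometric)
}

#' @export
glance.allometric_model <- function(x, ...) {
  tibble::tibble(feature = x$feature, r.squared = x$r_squared, n = x$n)
}

#' Fit allometric models for many features of a control cohort
#'
#' Fits one power law per feature against the fish standard lengths
#' stored in the phenomes, using per-fish feature values at one vertebra
#' or averaged over a window. TMC features (`<El>.TMC`) are derived from
#' the Vol and TMD columns on the fly.
#'
#' @param cohort List of `phenome` objects with `standard_length`
#'   attributes (mm).
#' @param features Feature names; `<El>.TMC` allowed.
#' @param vertebrae Vertebra window averaged per fish before fitting.
#' @return Tibble of models: feature, a, b, n, r_squared, b_isometric.
#' @export
fit_allometry <- function(cohort,
                          features = c("Cent.Vol", "Neur.Vol", "Haem.Vol",
                                       "Cent.TMC", "Neur.TMC", "Haem.TMC",
                                       "Cent.Th", "Neur.Th", "Haem.Th",
                                       "Cent.SA", "Neur.SA", "Haem.SA",
                                       "Cent.Le", "Tot.Vol", "Tot.TMC",
                                       "Tot.Th", "Tot.SA"),
                          vertebrae = 1:16) {
  sl <- vapply(cohort, function(ph) as.numeric(attr(ph, "standard_length")),
               0.0)
  if (anyNA(sl)) abort("every phenome needs a standard_length attribute")
  rows <- purrr::map(features, function(f) {
    y <- vapply(cohort, function(ph) {
      v <- .feature_values(ph, f)
      mean(v[ph$vertebra %in% vertebrae], na.rm = TRUE)
    }, 0.0)
    m <- fit_power_law(sl, y, feature = f)
    tibble::tibble(feature = f, a = m$a, b = m$b, n = m$n,
                   r_squared = m$r_squared, b_isometric = m$b_isometric)
  })
  dplyr::bind_rows(rows)
}

.feature_values <- function(ph, feature) {
  if (grepl("\\.TMC$", feature)) {
    el <- sub("\\.TMC$", "", feature)
    derive_tmc(ph[[paste0(el, ".Vol")]], ph[[paste0(el, ".TMD")]])
  } else {
    ph[[feature]]
  }
}

#' Normalize a value to a reference standard length
#'
#' `y* = y * (x_ref / x)^b`: the fitted allometric trajectory is used to
#' slide a measurement from a fish of length `x` to the value expected at
#' length `x_ref`.
#'
#' @param y Feature value(s).
#' @param x Fish standard length, mm.
#' @param x_ref Reference standard length, mm.
#' @param b Scaling exponent for the feature.
#' @return Normalized value(s).
#' @export
allometric_normalize <- function(y, x, x_ref, b) {
  if (any(x <= 0) || any(x_ref <= 0)) abort("lengths must be > 0")
  y * (x_ref / x)^b
}

#' Normalize a whole phenome to a reference length
#'
#' Vol, SA, Th and Le columns are normalized with their fitted exponents.
#' TMD is never normalized directly: TMC and Vol are normalized
#' independently and normalized TMD is recomputed as TMC*/Vol* (with the
#' cm³/µm³ unit conversion). SD-type columns are scaled with their parent
#' feature's exponent, which preserves the element's coefficient of
#' variation. Features without a model pass through unchanged with a
#' warning. Intended for control (WT) fish only; mutants, whose allometry
#' may differ, are left on their raw scale.
#'
#' @param phenome A `phenome` with a `standard_length` attribute.
#' @param models Model tibble from [fit_allometry()].
#' @param x_ref Reference standard length, mm (e.g. the mutant group's
#'   mean).
#' @return The normalized `phenome`.
#' @export
normalize_phenome <- function(phenome, models, x_ref) {
  if (x_ref <= 0) abort("`x_ref` must be > 0")
  x <- as.numeric(attr(phenome, "standard_length"))
  if (is.na(x)) abort("phenome lacks a standard_length attribute")
  b_of <- function(f) {
    i <- match(f, models$feature)
    if (is.na(i)) NA_real_ else models$b[i]
  }
  out <- phenome
  for (el in c("Tot", "Cent", "Neur", "Haem")) {
    bv <- b_of(paste0(el, ".Vol")); bt <- b_of(paste0(el, ".TMC"))
    vol_col <- paste0(el, ".Vol"); tmd_col <- paste0(el, ".TMD")
    has_tmd_path <- !is.na(bv) && !is.na(bt) &&
      all(c(vol_col, tmd_col) %in% names(phenome))
    # direct features with their own exponents
    for (q in c("Vol", "SA", "Th", "Le")) {
      col <- paste0(el, ".", q)
      if (!col %in% names(phenome)) next
      b <- b_of(col)
      if (is.na(b)) {
        warn(sprintf("no allometric model for %s: passed through", col))
        next
      }
      out[[col]] <- allometric_normalize(phenome[[col]], x, x_ref, b)
    }
    # two-step TMD: normalized TMC / normalized Vol
    if (has_tmd_path) {
      tmc <- derive_tmc(phenome[[vol_col]], phenome[[tmd_col]])
      tmc_n <- allometric_normalize(tmc, x, x_ref, bt)
      vol_n <- allometric_normalize(phenome[[vol_col]], x, x_ref, bv)
      out[[tmd_col]] <- tmc_n / (vol_n * 1e-12)
      sd_col <- paste0(el, ".TMD.sd")
      if (sd_col %in% names(phenome))
        out[[sd_col]] <- phenome[[sd_col]] * (x_ref / x)^(bt - bv)
    } else if (tmd_col %in% names(phenome)) {
      warn(sprintf("no TMC/Vol models for %s: TMD passed through", el))
    }
    th_sd <- paste0(el, ".Th.sd")
    if (th_sd %in% names(phenome) && !is.na(b_of(paste0(el, ".Th"))))
      out[[th_sd]] <- allometric_normalize(phenome[[th_sd]], x, x_ref,
                                           b_of(paste0(el, ".Th")))
  }
  attr(out, "standard_length") <- x_ref
  attr(out, "normalized_from") <- x
  out
}

#' Coefficient of variation
#'
#' Population SD divided by the mean.
#'
#' @param values Numeric vector with nonzero mean.
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) abort("zero mean: CV undefined")
  .psd(values) / m
}

#' Read / write allometric model tables
#'
#' Tab-separated text: feature, a, b, n, r_squared.
#'
#' @param models Model tibble from [fit_allometry()].
#' @param file Path.
#' @export
write_allometry <- function(models, file) {
  utils::write.table(as.data.frame(models), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_allometry
#' @export
read_allometry <- function(file) {
  tibble::as_tibble(utils::read.table(file, header = TRUE, sep = "\t"))
}
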