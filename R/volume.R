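#' Scanner calibration parameters
#'
#' Maps raw microCT intensities to tissue mineral density (TMD) via
#' `mgHA/cm^3 = (x / divisor) * slope + intercept`. Defaults are the
#' published calibration of the vivaCT40 scans this workflow was developed
#' on; they should be replaced with the calibration of the scanner actually
#' used.
#'
#' @param slope Calibration slope, mgHA/cm^3 per normalized intensity unit.
#' @param intercept Calibration intercept, mgHA/cm^3.
#' @param divisor Dimensionless intensity normalization constant.
#' @return An object of class `ct_calibration`.
#' @export
#' @examples
#' cal <- ct_calibration()
#' calibrate_intensity(4096, cal)
ct_calibration <- function(slope = 281.706, intercept = -195.402,
                           divisor = 4096) {
  stopifnot(is.numeric(slope), is.numeric(intercept), is.numeric(divisor))
  if (divisor <= 0) abort("`divisor` must be > 0")
  if (slope == 0) abort("`slope` must be nonzero")
  structure(list(slope = slope, intercept = intercept, divisor = divisor),
            class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf("<ct_calibration> mgHA/cm^3 = (x/%g) * %g + %g\n",
              x$divisor, x$slope, x$intercept))
  invisible(x)
}

#' Convert raw intensities to tissue mineral density
#'
#' Vectorized over scalars, vectors and 3D grids. Negative outputs are not
#' clamped; TMD statistics are only ever computed over above-threshold
#' voxels, where values are positive in practice.
#'
#' @param x Raw intensity value(s), `x >= 0`.
#' @param cal A [ct_calibration()].
#' @return Mineral density in mgHA/cm^3, same shape as `x`.
#' @export
calibrate_intensity <- function(x, cal = ct_calibration()) {
  stopifnot(inherits(cal, "ct_calibration"))
  if (any(x < 0, na.rm = TRUE)) abort("raw intensities must be >= 0")
  (x / cal$divisor) * cal$slope + cal$intercept
}

#' Calibrated microCT volume
#'
#' A 3D grid of raw integer intensities together with its isotropic voxel
#' size and intensity calibration. By convention grid axis 1 is
#' dorsoventral (dorsal at index 1), axis 2 mediolateral, and axis 3
#' anteroposterior (anterior at slice 1); this can be overridden through
#' `axis_labels`.
#'
#' @param intensities 3D numeric array of raw values (>= 0).
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param calibration A [ct_calibration()].
#' @param axis_labels Character vector of length 3 naming the anatomical
#'   axis of each grid axis; exactly one must be `"anteroposterior"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, voxel_size,
                      calibration = ct_calibration(),
                      axis_labels = c("dorsoventral", "mediolateral",
                                      "anteroposterior")) {
  if (length(dim(intensities)) != 3L) abort("`intensities` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    abort("`voxel_size` must be a single positive number (micrometres)")
  if (any(intensities < 0, na.rm = TRUE)) abort("intensities must be >= 0")
  if (sum(axis_labels == "anteroposterior") != 1L)
    abort("exactly one axis must be labeled \"anteroposterior\"")
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 calibration = calibration, axis_labels = axis_labels),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size,
              paste(substr(x$axis_labels, 1, 2), collapse = " x ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$intensities)

ap_axis <- function(vol) which(vol$axis_labels == "anteroposterior")

#' Rotate a volume about the anteroposterior axis
#'
#' In-plane rotation of every transverse slice, used to orient specimens
#' upright before segmentation. Interpolation is bilinear within each slice
#' (trilinear in effect, since the rotation has no anteroposterior
#' component); voxels sampled from outside the grid are filled with 0.
#'
#' @param vol A [ct_volume()].
#' @param angle Rotation angle in degrees (counter-clockwise in the
#'   transverse plane).
#' @return A [ct_volume()] of the same shape.
#' @export
reorient <- function(vol, angle) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(angle)) abort("`angle` must be finite")
  if (angle %% 360 == 0) return(vol)
  a <- ap_axis(vol)
  perm <- c(setdiff(1:3, a), a)            # AP last, rotate in-plane
  x <- aperm(vol$intensities, perm)
  d <- dim(x)
  n1 <- d[1]; n2 <- d[2]
  th <- angle * pi / 180
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  # inverse map: sample the source at the back-rotated coordinate
  di <- g$i - c1; dj <- g$j - c2
  si <- cos(th) * di + sin(th) * dj + c1
  sj <- -sin(th) * di + cos(th) * dj + c2
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  samp <- function(slice, ii, jj) {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    v <- numeric(length(ii))
    v[ok] <- slice[cbind(ii[ok], jj[ok])]
    v
  }
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    slice <- x[, , k]
    out[, , k] <- (1 - fi) * (1 - fj) * samp(slice, i0, j0) +
      fi * (1 - fj) * samp(slice, i0 + 1L, j0) +
      (1 - fi) * fj * samp(slice, i0, j0 + 1L) +
      fi * fj * samp(slice, i0 + 1L, j0 + 1L)
  }
  out[out < 0] <- 0
  out <- aperm(out, order(perm))
  ct_volume(out, vol$voxel_size, vol$calibration, vol$axis_labels)
}

#' Intensity projection of a volume
#'
#' @param vol A [ct_volume()] or 3D array.
#' @param mode `"max"` or `"mean"`.
#' @param axis Grid axis to project along (1, 2 or 3).
#' @return A 2D matrix of projected intensities.
#' @export
project <- function(vol, mode = c("max", "mean"), axis = 3) {
  mode <- match.arg(mode)
  x <- if (inherits(vol, "ct_volume")) vol$intensities else vol
  if (length(dim(x)) != 3L) abort("need a 3D volume")
  if (!axis %in% 1:3) abort("`axis` must be 1, 2 or 3")
  f <- if (mode == "max") max else mean
  apply(x, setdiff(1:3, axis), f)
}
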