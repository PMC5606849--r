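# Minimal DICOM slice reader/writer (explicit VR little endian).
# Covers the tags a microCT series needs: rows/columns, pixel spacing,
# slice thickness, image position (used to order slices on read), and
# unsigned 16-bit pixel data. No compression, no implicit VR.

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
.dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                    endian = "little")

.dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  hdr <- c(.dcm_uint16(group), .dcm_uint16(elem), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(hdr, as.raw(c(0, 0)), .dcm_uint32(length(value_raw)), value_raw)
  } else {
    c(hdr, .dcm_uint16(length(value_raw)), value_raw)
  }
}

.dcm_str <- function(group, elem, vr, s) .dcm_element(group, elem, vr,
                                                      charToRaw(s))
.dcm_us <- function(group, elem, x) .dcm_element(group, elem, "US",
                                                 .dcm_uint16(x))

.dcm_ds <- function(x) paste(vapply(x, function(v)
  format(v, digits = 10, scientific = FALSE, trim = TRUE), ""),
  collapse = "\\")

.dcm_write_slice <- function(file, pixels, voxel_mm, slice_index, z_mm) {
  # pixels: matrix rows x cols (dorsoventral x mediolateral)
  stopifnot(is.matrix(pixels))
  v <- as.integer(round(t(pixels)))       # DICOM pixel order is row-major
  if (any(v < 0 | v > 65535)) abort("pixel values must be in [0, 65535]")
  v[v > 32767L] <- v[v > 32767L] - 65536L # two's complement for writeBin
  px <- writeBin(v, raw(), size = 2, endian = "little")

  meta <- c(
    .dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_str(0x0002, 0x0003, "UI", sprintf("1.2.826.0.1.3680043.9.0.%d",
                                           slice_index)),
    .dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  body <- c(
    .dcm_str(0x0008, 0x0060, "CS", "CT"),
    .dcm_str(0x0018, 0x0050, "DS", .dcm_ds(voxel_mm)),
    .dcm_str(0x0020, 0x0013, "IS", as.character(slice_index)),
    .dcm_str(0x0020, 0x0032, "DS", .dcm_ds(c(0, 0, z_mm))),
    .dcm_str(0x0020, 0x0037, "DS", .dcm_ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_us(0x0028, 0x0002, 1),
    .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_us(0x0028, 0x0010, nrow(pixels)),
    .dcm_us(0x0028, 0x0011, ncol(pixels)),
    .dcm_str(0x0028, 0x0030, "DS", .dcm_ds(c(voxel_mm, voxel_mm))),
    .dcm_us(0x0028, 0x0100, 16),
    .dcm_us(0x0028, 0x0101, 16),
    .dcm_us(0x0028, 0x0102, 15),
    .dcm_us(0x0028, 0x0103, 0),
    .dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.dcm_element(0x0002, 0x0000, "UL", .dcm_uint32(length(meta))), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(file)
}

.dcm_read_slice <- function(file) {
  buf <- readBin(file, raw(), n = file.info(file)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    abort(sprintf("%s is not a DICOM file", file))
  pos <- 133L
  n <- length(buf)
  u16 <- function(p) readBin(buf[p:(p + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(buf[p:(p + 3)], "integer", size = 4,
                             endian = "little")
  out <- list()
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L); vpos <- pos + 8L
    }
    val <- if (len > 0) buf[vpos:(vpos + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr, value = val)
    pos <- vpos + len
  }
  str_of <- function(key) {
    v <- out[[key]]
    if (is.null(v)) return(NULL)
    trimws(rawToChar(v$value))
  }
  ds_of <- function(key) {
    s <- str_of(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_of <- function(key) {
    v <- out[[key]]
    if (is.null(v)) return(NULL)
    readBin(v$value, "integer", size = 2, endian = "little", signed = FALSE)
  }
  rows <- us_of("00280010"); cols <- us_of("00280011")
  if (is.null(rows) || is.null(cols))
    abort(sprintf("%s: missing Rows/Columns", file))
  px_raw <- out[["7FE00010"]]
  if (is.null(px_raw)) abort(sprintf("%s: missing PixelData", file))
  px <- readBin(px_raw$value, "integer", n = rows * cols, size = 2,
                endian = "little", signed = FALSE)
  list(pixels = t(matrix(px, nrow = cols, ncol = rows)),  # row-major on disk
       spacing = ds_of("00280030"),
       thickness = ds_of("00180050"),
       position = ds_of("00200032"),
       instance = as.integer(str_of("00200013")))
}

#' Write a volume as a DICOM series
#'
#' One file per transverse slice, explicit VR little endian, with standard
#' pixel-spacing, slice-thickness and image-position tags. Intensities are
#' stored as unsigned 16-bit integers, so raw values must lie in
#' \[0, 65535\].
#'
#' @param vol A [ct_volume()] (anteroposterior axis = grid axis 3).
#' @param path Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dicom <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (ap_axis(vol) != 3L)
    abort("write_dicom expects the anteroposterior axis on grid axis 3")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$intensities)
  mm <- vol$voxel_size / 1000
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    files[k] <- file.path(path, sprintf("slice_%04d.dcm", k))
    .dcm_write_slice(files[k], vol$intensities[, , k], mm, k, (k - 1) * mm)
  }
  invisible(files)
}

#' Read a DICOM series into a calibrated volume
#'
#' Slices are stacked in order of their image-position tag along the slice
#' normal (file order on disk is irrelevant). Voxel size is taken from the
#' pixel-spacing and inter-slice spacing tags and must be isotropic within
#' 1%. Intensity calibration is *not* read from DICOM rescale tags: the
#' density mapping addresses raw values, so calibration comes from
#' `calibration`.
#'
#' @param path Directory containing one DICOM file per slice.
#' @param calibration A [ct_calibration()].
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path, calibration = ct_calibration()) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort(sprintf("no DICOM files found in %s", path))
  slices <- lapply(files, .dcm_read_slice)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("inconsistent slice dimensions across series")
  sp <- vapply(slices, function(s) s$spacing[1], numeric(1))
  sp2 <- vapply(slices, function(s) s$spacing[2], numeric(1))
  if (max(abs(sp - sp[1])) > 1e-9 || max(abs(sp2 - sp2[1])) > 1e-9)
    abort("inconsistent pixel spacing across series")
  if (abs(sp[1] - sp2[1]) / sp[1] > 0.01)
    abort(sprintf("anisotropic in-plane spacing: %g vs %g mm", sp[1], sp2[1]))
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (max(abs(dz - dz[1])) > 1e-6 * max(abs(dz[1]), 1e-12))
      abort("non-uniform slice spacing")
    if (abs(dz[1] - sp[1]) / sp[1] > 0.01)
      abort(sprintf("anisotropic spacing: in-plane %g mm, slice %g mm",
                    sp[1], dz[1]))
  }
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  ct_volume(arr, voxel_size = sp[1] * 1000, calibration = calibration)
}
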