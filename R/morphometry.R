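# Per-vertebra morphometry: local thickness, element measures, centrum
# length, and phenome assembly/IO.

# population SD (intra-specimen variation is over the voxels of one
# element, a complete population, not a sample)
.psd <- function(x) sqrt(mean((x - mean(x))^2))

#' The 25 per-vertebra measures and their long file-dialect names
#'
#' @return Named character vector mapping short names (`Cent.TMD`, ...) to
#'   the long column names used in phenome text files
#'   (`CentrumTMDs`, ...).
#' @export
measure_names <- function() {
  el <- c(Tot = "Vertebral", Cent = "Centrum", Haem = "Haemal",
          Neur = "Neural")
  qt <- c(Vol = "Volumes", SA = "SAs", TMD = "TMDs", TMD.sd = "ISs",
          Th = "MTs", Th.sd = "TSs")
  out <- character(0)
  for (q in names(qt))
    for (e in names(el))
      out[paste(e, q, sep = ".")] <- paste0(el[e], qt[q])
  out["Cent.Le"] <- "CentrumLength"
  out
}

#' Model-independent local thickness
#'
#' Per-voxel thickness is the diameter of the largest sphere that fits
#' entirely inside the structure and contains the voxel
#' (distance-transform, distance-ridge, sphere-propagation construction).
#'
#' @param mask Logical 3D array (non-empty).
#' @param voxel_size Voxel edge length in micrometres.
#' @return Numeric 3D array of thickness in micrometres (0 outside the
#'   mask).
#' @export
local_thickness <- function(mask, voxel_size = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) abort("empty mask")
  .local_thickness_cpp(mask, dim(mask)) * voxel_size
}

.surface_voxels <- function(mask) {
  d <- dim(mask)
  # pad with background so volume-boundary voxels count as surface
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  nb_all <- p[i - 1, j, k] & p[i + 1, j, k] &
    p[i, j - 1, k] & p[i, j + 1, k] &
    p[i, j, k - 1] & p[i, j, k + 1]
  mask & !nb_all
}

#' Measure one skeletal element
#'
#' Volume is voxel count times voxel volume; surface area counts foreground
#' voxels with at least one face-adjacent background neighbour (the
#' perimeter-voxel estimator; biased relative to meshed surfaces, so do not
#' compare across estimators). Thickness statistics come from
#' [local_thickness()]; TMD statistics from the calibrated intensities over
#' the mask. SDs are population SDs over the element's voxels.
#'
#' @param mask Logical 3D array.
#' @param vol A [ct_volume()] of the same shape.
#' @param thickness Optional precomputed local-thickness map (micrometres)
#'   for the structure `mask` belongs to.
#' @return One-row tibble: `Vol` (µm³), `SA` (µm²), `Th`, `Th.sd` (µm),
#'   `TMD`, `TMD.sd` (mgHA/cm³). All `NA` (with a warning) when the mask is
#'   empty.
#' @export
measure_element <- function(mask, vol, thickness = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!identical(dim(mask), dim(vol$intensities)))
    abort("mask and volume shapes differ")
  vs <- vol$voxel_size
  n <- sum(mask)
  if (n == 0) {
    warn("empty element mask: measures reported as missing")
    return(tibble::tibble(Vol = NA_real_, SA = NA_real_, Th = NA_real_,
                          Th.sd = NA_real_, TMD = NA_real_,
                          TMD.sd = NA_real_))
  }
  if (is.null(thickness)) thickness <- local_thickness(mask, vs)
  th <- thickness[mask]
  dens <- calibrate_intensity(vol$intensities[mask], vol$calibration)
  tibble::tibble(
    Vol = n * vs^3,
    SA = sum(.surface_voxels(mask)) * vs^2,
    Th = mean(th), Th.sd = .psd(th),
    TMD = mean(dens), TMD.sd = .psd(dens))
}

#' Centrum length from boundary seed lines
#'
#' Anteroposterior distance between the midpoints of a vertebra's anterior
#' and posterior boundary lines, in micrometres.
#'
#' @param anterior,posterior One-row [seed_lines()] slices.
#' @param voxel_size Voxel edge length, micrometres.
#' @return Length in micrometres (0 with a warning if the boundaries
#'   coincide).
#' @export
centrum_length <- function(anterior, posterior, voxel_size) {
  za <- (anterior$z1 + anterior$z2) / 2
  zp <- (posterior$z1 + posterior$z2) / 2
  le <- abs(zp - za) * voxel_size
  if (le == 0) warn("coincident boundaries: centrum length 0")
  le
}

#' Assemble the per-vertebra phenome of one fish
#'
#' Splits every labeled vertebra into elements, measures each element and
#' the whole vertebra (the `Tot.*` measures are computed on the union mask,
#' not averaged from elements), and adds centrum length. Missing element
#' masks yield missing fields.
#'
#' @param vmap A `vertebra_map` from [separate_vertebrae()].
#' @param vol The [ct_volume()] the map was derived from.
#' @param buffer Centrum dilation buffer passed to [segment_elements()].
#' @param standard_length Fish standard length, mm (stored as an
#'   attribute).
#' @param fish_id,group Optional metadata attributes.
#' @return A `phenome`: tibble with one row per vertebra, a `vertebra`
#'   column and the 25 measure columns (short names).
#' @export
assemble_phenome <- function(vmap, vol, buffer = 5, standard_length = NA,
                             fish_id = NA_character_, group = NA_character_) {
  stopifnot(inherits(vmap, "vertebra_map"), inherits(vol, "ct_volume"))
  seeds <- vmap$seeds
  rows <- vector("list", vmap$n_vertebrae)
  for (v in seq_len(vmap$n_vertebrae)) {
    vert <- vmap$labels == v
    ant <- seeds[v, ]; post <- seeds[v + 1, ]
    if (!any(vert)) {
      warn(sprintf("vertebra %d has no voxels; row reported missing", v))
      rows[[v]] <- tibble::tibble(vertebra = v)
      next
    }
    el <- segment_elements(vert, ant, post, buffer = buffer)
    th_all <- local_thickness(vert, vol$voxel_size)
    one <- function(mask) measure_element(mask, vol, thickness = th_all)
    m <- list(Cent = one(el$cent), Neur = one(el$neur), Haem = one(el$haem),
              Tot = one(vert))
    row <- tibble::tibble(vertebra = v)
    for (e in names(m))
      for (q in names(m[[e]]))
        row[[paste(e, q, sep = ".")]] <- m[[e]][[q]]
    row$Cent.Le <- centrum_length(ant, post, vol$voxel_size)
    rows[[v]] <- row
  }
  ph <- dplyr::bind_rows(rows)
  ph <- ph[, c("vertebra", names(measure_names())[
    names(measure_names()) %in% names(ph)])]
  new_phenome(ph, standard_length = standard_length, fish_id = fish_id,
              group = group, voxel_size = vol$voxel_size)
}

new_phenome <- function(tb, standard_length = NA, fish_id = NA_character_,
                        group = NA_character_, voxel_size = NA_real_) {
  attr(tb, "standard_length") <- standard_length
  attr(tb, "fish_id") <- fish_id
  attr(tb, "group") <- group
  attr(tb, "voxel_size") <- voxel_size
  class(tb) <- unique(c("phenome", class(tb)))
  tb
}

#' Read / write phenome tables
#'
#' Phenome files are plain tab-separated text, one row per vertebra, one
#' column per measure, with the long column names of [measure_names()]
#' (`VertebralVolumes`, `CentrumTMDs`, ...). Short-named files are also
#' accepted on read.
#'
#' @param file Path to a phenome text file.
#' @param standard_length,fish_id,group Metadata attached as attributes.
#' @return [read_phenome()]: a `phenome` tibble with short measure names.
#' @export
read_phenome <- function(file, standard_length = NA,
                         fish_id = basename(file), group = NA_character_) {
  tb <- tibble::as_tibble(utils::read.table(file, header = TRUE, sep = "\t",
                                            check.names = FALSE))
  mn <- measure_names()
  long_to_short <- setNames(names(mn), mn)
  hits <- names(tb) %in% mn
  names(tb)[hits] <- long_to_short[names(tb)[hits]]
  if (!"vertebra" %in% names(tb)) tb$vertebra <- seq_len(nrow(tb))
  tb <- tb[, c("vertebra", intersect(names(mn), names(tb)))]
  new_phenome(tb, standard_length = standard_length, fish_id = fish_id,
              group = group)
}

#' @rdname read_phenome
#' @param phenome A `phenome` tibble.
#' @export
write_phenome <- function(phenome, file) {
  mn <- measure_names()
  tb <- as.data.frame(phenome)[, intersect(names(mn), names(phenome))]
  names(tb) <- mn[names(tb)]
  utils::write.table(tb, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read every phenome file in a directory as a cohort
#'
#' @param dir Directory of phenome text files (`*.txt` or `*.tsv`).
#' @param lengths Optional named vector or two-column data frame
#'   (file, standard_length) of standard lengths in mm.
#' @param group Group label applied to every fish.
#' @return A list of `phenome` objects, named by file.
#' @export
read_phenome_dir <- function(dir, lengths = NULL, group = NA_character_) {
  files <- list.files(dir, pattern = "\\.(txt|tsv)$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no phenome files in %s", dir))
  if (is.data.frame(lengths))
    lengths <- setNames(lengths[[2]], lengths[[1]])
  out <- lapply(files, function(f) {
    sl <- if (!is.null(lengths)) unname(lengths[basename(f)]) else NA
    read_phenome(f, standard_length = sl, group = group)
  })
  names(out) <- basename(files)
  out
}
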