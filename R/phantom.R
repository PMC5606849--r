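# Synthetic spine phantoms: a column of mineralized centra with neural and
# haemal processes, with known geometry, intensities and noise, plus
# ground-truth label maps, element masks, analytic measures and ideal seed
# lines. Everything segmentation and morphometry claim is testable against
# these without scan data.

#' Specification of a spine phantom
#'
#' Centra are hollow hourglass cylinders along the anteroposterior axis
#' (outer radius largest at the endplates, `waist` fraction at
#' mid-length); the neural process is a dorsal sagittal blade, the haemal
#' process a ventral blade that is longer on anterior vertebrae (rib
#' emulation), so the anterior/posterior haemal-volume contrast of real
#' fish is present. All lengths are voxels unless noted.
#'
#' @param n_vertebrae Number of vertebrae.
#' @param centrum_radius Outer endplate radius.
#' @param centrum_wall Shell wall thickness.
#' @param centrum_length Centrum length along the column.
#' @param waist Mid-length radius as a fraction of the endplate radius.
#' @param gap Intervertebral gap.
#' @param arch_width Mediolateral thickness of the neural/haemal blades.
#' @param neur_extent Dorsal blade length.
#' @param haem_extent_ant,haem_extent_post Ventral blade lengths for
#'   anterior (rib-bearing) and posterior vertebrae.
#' @param rib_until Last rib-bearing vertebra.
#' @param seed_inset Dorsoventral inset of the ventral seed endpoint into
#'   the centrum silhouette, voxels (the centrum buffer restores the
#'   margin, as it does for hand-drawn boundary ROIs).
#' @param intensity_cent,intensity_arch Mean raw intensities.
#' @param noise_sd Additive Gaussian noise SD (raw units).
#' @param voxel_size Voxel edge, micrometres.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_vertebrae = 4, centrum_radius = 10,
                         centrum_wall = 4, centrum_length = 24,
                         waist = 0.7, gap = 4, arch_width = 5,
                         neur_extent = 14, haem_extent_ant = 16,
                         haem_extent_post = 7, rib_until = 2,
                         seed_inset = 5,
                         intensity_cent = 13000, intensity_arch = 11500,
                         noise_sd = 150, voxel_size = 21, seed = 1) {
  if (centrum_wall < 1) abort("wall thickness must be >= 1 voxel")
  if (gap < 0) abort("gap must be >= 0")
  as.list(environment()) |> structure(class = "phantom_spec")
}

#' Generate a spine phantom with ground truth
#'
#' Deterministic given `spec$seed`. Returns the noisy calibrated volume
#' together with truth: the vertebra label map, per-vertebra element
#' masks, an analytic measure table (volumes by voxel count — the
#' definition of the volume measure — wall/blade thicknesses and centrum
#' pitch in micrometres, plus the noiseless TMD), and ideal seed lines at
#' the intervertebral gap centres.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `spine_phantom`: `volume` ([ct_volume()]),
#'   `labels`, `elements` (list of `element_masks`), `truth` (tibble),
#'   `seeds` ([seed_lines()]), `spec`.
#' @export
generate_spine_phantom <- function(spec = phantom_spec()) {
  s <- spec
  if (s$gap < 1) abort("phantom not separable: gap < 1 voxel")
  n1 <- 2 * s$centrum_radius + s$neur_extent +
    max(s$haem_extent_ant, s$haem_extent_post) + 8
  n2 <- 2 * s$centrum_radius + 8
  pitch <- s$centrum_length + s$gap
  n3 <- s$n_vertebrae * pitch + s$gap
  c_dv <- 4 + s$neur_extent + s$centrum_radius
  R <- s$centrum_radius
  c_ml <- ceiling(n2 / 2)
  rmat <- sqrt(outer((seq_len(n1) - c_dv)^2, (seq_len(n2) - c_ml)^2, `+`))
  half_w <- (s$arch_width - 1) / 2
  ml_blade <- abs(seq_len(n2) - c_ml) <= half_w

  labels <- array(0L, c(n1, n2, n3))
  elements <- vector("list", s$n_vertebrae)
  truth_rows <- list()
  for (v in seq_len(s$n_vertebrae)) {
    z0 <- s$gap + (v - 1) * pitch + 1
    z1 <- z0 + s$centrum_length - 1
    cent <- neur <- haem <- array(FALSE, c(n1, n2, n3))
    h_ext <- if (v <= s$rib_until) s$haem_extent_ant else s$haem_extent_post
    for (z in z0:z1) {
      zc <- (z0 + z1) / 2
      frac <- if (z1 > z0) abs(z - zc) / ((z1 - z0) / 2) else 1
      Rz <- s$centrum_radius * (s$waist + (1 - s$waist) * min(frac, 1))
      cent[, , z] <- rmat <= Rz & rmat > Rz - s$centrum_wall
      if (z > z0 && z < z1) {           # blades inset from the endplates
        dvs_n <- (c_dv - R - s$neur_extent):(c_dv - R - 1)
        dvs_n <- dvs_n[dvs_n >= 1]
        neur[dvs_n, ml_blade, z] <- TRUE
        dvs_h <- (c_dv + R + 1):(c_dv + R + h_ext)
        dvs_h <- dvs_h[dvs_h <= n1]
        haem[dvs_h, ml_blade, z] <- TRUE
      }
    }
    labels[cent | neur | haem] <- v
    elements[[v]] <- structure(list(neur = neur, cent = cent, haem = haem),
                               class = "element_masks")
    vs <- s$voxel_size
    truth_rows[[v]] <- tibble::tibble(
      vertebra = v,
      Cent.Vol = sum(cent) * vs^3, Neur.Vol = sum(neur) * vs^3,
      Haem.Vol = sum(haem) * vs^3,
      Cent.Th = s$centrum_wall * vs, Neur.Th = s$arch_width * vs,
      Haem.Th = s$arch_width * vs,
      Cent.Le = pitch * vs,
      Cent.TMD = calibrate_intensity(s$intensity_cent),
      Neur.TMD = calibrate_intensity(s$intensity_arch),
      Haem.TMD = calibrate_intensity(s$intensity_arch))
  }

  set.seed(s$seed)
  inten <- array(0, c(n1, n2, n3))
  for (v in seq_len(s$n_vertebrae)) {
    inten[elements[[v]]$cent] <- s$intensity_cent
    inten[elements[[v]]$neur | elements[[v]]$haem] <- s$intensity_arch
  }
  if (s$noise_sd > 0)
    inten <- inten + rnorm(length(inten), 0, s$noise_sd)
  inten <- round(pmax(inten, 0))

  # ideal seed lines at the gap centres, mid-sagittal: dorsal endpoint at
  # the centrum crest, ventral endpoint inset into the silhouette (the
  # centrum buffer restores the ventral margin, as for hand-drawn ROIs)
  bz <- vapply(0:s$n_vertebrae, function(b)
    b * pitch + (s$gap + 1) / 2, 0.0)
  nb <- length(bz)
  seeds <- seed_lines(x1 = rep(c_dv - R, nb), y1 = rep(c_ml, nb),
                      z1 = bz, x2 = rep(c_dv + R - s$seed_inset, nb),
                      y2 = rep(c_ml, nb), z2 = bz,
                      boundary = 0:s$n_vertebrae)
  structure(list(
    volume = ct_volume(inten, s$voxel_size),
    labels = labels, elements = elements,
    truth = dplyr::bind_rows(truth_rows), seeds = seeds, spec = s),
    class = "spine_phantom")
}

#' @export
print.spine_phantom <- function(x, ...) {
  d <- dim(x$volume$intensities)
  cat(sprintf("<spine_phantom> %d vertebrae in a %d x %d x %d grid\n",
              x$spec$n_vertebrae, d[1], d[2], d[3]))
  invisible(x)
}

#' Simulated user seed lines for a phantom
#'
#' One line per intervertebral gap, at the gap centre, with endpoints
#' perturbed by uniform integer jitter (emulating hand-drawn boundary
#' ROIs). A jittered line whose anteroposterior coordinates leave its gap
#' is resampled up to 10 times before erroring.
#'
#' @param phantom A `spine_phantom`.
#' @param jitter Maximum absolute perturbation, voxels.
#' @param seed Optional RNG seed.
#' @return A [seed_lines()] tibble.
#' @export
generate_seed_lines <- function(phantom, jitter = 0, seed = NULL) {
  stopifnot(inherits(phantom, "spine_phantom"), jitter >= 0)
  if (!is.null(seed)) set.seed(seed)
  s <- phantom$spec
  base <- phantom$seeds
  if (jitter == 0) return(base)
  pitch <- s$centrum_length + s$gap
  out <- base
  for (i in seq_len(nrow(base))) {
    b <- base$boundary[i]
    gap_lo <- b * pitch + 1
    gap_hi <- b * pitch + s$gap
    for (try in 1:10) {
      jz1 <- base$z1[i] + sample(-jitter:jitter, 1)
      jz2 <- base$z2[i] + sample(-jitter:jitter, 1)
      jx1 <- base$x1[i] + sample(-jitter:jitter, 1)
      jx2 <- base$x2[i] + sample(-jitter:jitter, 1)
      ok <- jz1 >= gap_lo && jz1 <= gap_hi && jz2 >= gap_lo &&
        jz2 <= gap_hi && jx1 >= 1 && jx2 <= dim(phantom$labels)[1]
      if (ok) break
      if (try == 10) abort(sprintf(
        "could not place a jittered seed inside gap %d", b))
    }
    out$z1[i] <- jz1; out$z2[i] <- jz2
    out$x1[i] <- jx1; out$x2[i] <- jx2
  }
  out
}

#' Write a phantom to disk (DICOM series plus truth sidecars)
#'
#' @param phantom A `spine_phantom`.
#' @param path Output directory.
#' @return Invisibly, `path`. The DICOM series round-trips bit-exactly
#'   through [read_dicom_series()]; `truth.tsv` and `seeds.tsv` hold the
#'   analytic measure table and the ideal seed lines.
#' @export
write_phantom <- function(phantom, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_dicom(phantom$volume, file.path(path, "dicom"))
  utils::write.table(as.data.frame(phantom$truth),
                     file.path(path, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_seed_lines(phantom$seeds, file.path(path, "seeds.tsv"))
  invisible(path)
}
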