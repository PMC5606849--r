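# Vertebral segmentation: IsoData thresholding, separation-plane growing
# over connected components, component reassignment, and element masks.
#
# Coordinate convention (see ct_volume): axis 1 = dorsoveneral index "x"
# (dorsal at 1), axis 2 = mediolateral "y", axis 3 = anteroposterior "z"
# (anterior at slice 1). Seed lines are drawn in the sagittal (x, z) plane
# and extruded across the full mediolateral extent.

#' IsoData automatic threshold
#'
#' Iterative intermeans: starting from the midrange, the threshold is moved
#' to the mean of the below- and above-threshold class means until it
#' reaches the fixed point `T = (mean(x < T) + mean(x >= T)) / 2`. Values
#' are binned into `n_bins` equal-width bins first.
#'
#' @param x Numeric vector of intensities (a sample or a full volume).
#' @param n_bins Number of histogram bins.
#' @return The threshold, on the scale of `x`.
#' @export
isodata_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("empty histogram")
  rng <- range(x)
  if (rng[1] == rng[2]) abort("degenerate histogram: all values equal")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  thr <- mean(rng)
  for (iter in 1:1000) {
    lo <- mids < thr
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) {
      # walk into the occupied side and continue
      thr <- if (n_lo == 0) min(mids[counts > 0][-1], na.rm = TRUE) else
        max(mids[counts > 0][-sum(counts > 0)], na.rm = TRUE)
      next
    }
    m_lo <- sum(counts[lo] * mids[lo]) / n_lo
    m_hi <- sum(counts[!lo] * mids[!lo]) / n_hi
    new_thr <- (m_lo + m_hi) / 2
    if (abs(new_thr - thr) < (rng[2] - rng[1]) / (2 * n_bins)) {
      thr <- new_thr
      break
    }
    thr <- new_thr
  }
  thr
}

#' Semi-automatic threshold from a fish outline
#'
#' Voxels outside the user-drawn outline (a 2D mask on a maximum-intensity
#' projection, extruded along the projection axis) are zeroed; IsoData runs
#' on the histogram of the remaining nonzero voxels, and the result is
#' multiplied by a correction factor (0.73 in the workflow this package
#' implements, chosen against user-defined thresholds).
#'
#' @param vol A [ct_volume()].
#' @param outline Logical matrix matching the projection of `vol` along
#'   `axis`; `NULL` keeps every voxel.
#' @param correction Positive multiplicative correction factor.
#' @param axis Projection axis the outline was drawn on (default 2,
#'   the mediolateral axis, i.e. a lateral view).
#' @param n_bins Histogram bins for IsoData.
#' @return The corrected threshold (raw intensity units).
#' @export
compute_threshold <- function(vol, outline = NULL, correction = 0.73,
                              axis = 2, n_bins = 256) {
  stopifnot(inherits(vol, "ct_volume"))
  if (correction <= 0) abort("`correction` must be > 0")
  x <- vol$intensities
  if (!is.null(outline)) {
    if (!any(outline)) abort("empty outline")
    pd <- dim(x)[setdiff(1:3, axis)]
    if (!all(dim(outline) == pd))
      abort("outline does not match the projection dimensions")
    keep <- array(FALSE, dim(x))
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    for (k in seq_len(dim(x)[axis])) {
      if (axis == 1) keep[k, , ] <- outline
      else if (axis == 2) keep[, k, ] <- outline
      else keep[, , k] <- outline
    }
    x <- x * keep
  }
  vals <- x[x > 0]
  if (length(vals) == 0) abort("no nonzero voxels inside the outline")
  isodata_threshold(vals, n_bins = n_bins) * correction
}

#' Binarize a volume at a threshold
#'
#' Foreground is `intensity >= threshold` (inclusive).
#'
#' @param vol A [ct_volume()] or 3D array.
#' @param threshold Finite threshold, raw intensity units.
#' @return Logical 3D array.
#' @export
binarize <- function(vol, threshold) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  x <- if (inherits(vol, "ct_volume")) vol$intensities else vol
  x >= threshold
}

#' Label connected foreground components
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners; default).
#' @return Integer 3D array, 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .label_components_cpp(mask, dim(mask), as.integer(connectivity))
}

# --- seed lines -----------------------------------------------------------

#' Seed lines marking intervertebral boundaries
#'
#' A tibble with one row per boundary: `boundary` (0 = boundary anterior to
#' vertebra 1) and the two 3D endpoints in voxel coordinates, dorsal
#' (`x1,y1,z1`) then ventral (`x2,y2,z2`). x = dorsoventral, y =
#' mediolateral, z = anteroposterior grid index.
#'
#' @param x1,y1,z1,x2,y2,z2 Endpoint coordinates (vectors, one per line).
#' @param boundary Boundary indices; defaults to `0:(n-1)` after sorting by
#'   anteroposterior midpoint.
#' @return A `tbl_df` of class `seed_lines`.
#' @export
seed_lines <- function(x1, y1, z1, x2, y2, z2, boundary = NULL) {
  tb <- tibble::tibble(x1 = x1, y1 = y1, z1 = z1,
                       x2 = x2, y2 = y2, z2 = z2)
  if (any(tb$x1 == tb$x2 & tb$y1 == tb$y2 & tb$z1 == tb$z2))
    abort("seed line endpoints must be distinct")
  tb <- tb[order((tb$z1 + tb$z2) / 2), ]
  tb$boundary <- if (is.null(boundary)) seq_len(nrow(tb)) - 1L else
    sort(boundary)
  tb <- tb[, c("boundary", "x1", "y1", "z1", "x2", "y2", "z2")]
  class(tb) <- c("seed_lines", class(tb))
  tb
}

#' Read / write seed lines as tab-separated text
#'
#' @param file Path to a TSV with columns
#'   `boundary, x1, y1, z1, x2, y2, z2`.
#' @return [read_seed_lines()]: a [seed_lines()] tibble.
#' @export
read_seed_lines <- function(file) {
  tb <- utils::read.table(file, header = TRUE, sep = "\t")
  seed_lines(tb$x1, tb$y1, tb$z1, tb$x2, tb$y2, tb$z2, boundary = tb$boundary)
}

#' @rdname read_seed_lines
#' @param seeds A [seed_lines()] tibble.
#' @export
write_seed_lines <- function(seeds, file) {
  utils::write.table(as.data.frame(seeds), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Rasterize the (extended) seed segment in the sagittal plane and extrude
# mediolaterally. Returns a logical plane mask. The rasterization is
# 8-connected-thick so that a 26-connected path cannot slip through a
# diagonal.
.plane_mask <- function(dims, p1, p2, extend = 0) {
  dirv <- c(p2[1] - p1[1], p2[3] - p1[3])
  len <- sqrt(sum(dirv^2))
  if (len == 0) abort("degenerate seed segment")
  u <- dirv / len
  a <- c(p1[1], p1[3]) - extend * u
  b <- c(p2[1], p2[3]) + extend * u
  nstep <- max(2, ceiling(4 * (len + 2 * extend)))
  t <- seq(0, 1, length.out = nstep)
  xs <- a[1] + t * (b[1] - a[1])
  zs <- a[2] + t * (b[2] - a[2])
  cx <- round(xs); cz <- round(zs)
  cells <- unique(cbind(cx, cz))
  # fill diagonal steps with both adjacent corners
  if (nrow(cells) > 1) {
    d <- diff(cells)
    diag_steps <- which(d[, 1] != 0 & d[, 2] != 0)
    if (length(diag_steps)) {
      extra <- rbind(cbind(cells[diag_steps, 1], cells[diag_steps + 1, 2]),
                     cbind(cells[diag_steps + 1, 1], cells[diag_steps, 2]))
      cells <- unique(rbind(cells, extra))
    }
  }
  keep <- cells[, 1] >= 1 & cells[, 1] <= dims[1] &
    cells[, 2] >= 1 & cells[, 2] <= dims[3]
  cells <- cells[keep, , drop = FALSE]
  plane <- array(FALSE, dims)
  for (i in seq_len(nrow(cells)))
    plane[cells[i, 1], , cells[i, 2]] <- TRUE
  plane
}

# Signed anteroposterior offset of voxels from the infinite line through a
# seed segment (sagittal plane). Positive = posterior side.
.signed_side <- function(coords, p1, p2) {
  # coords: matrix with columns x (dv), z (ap)
  dx <- p2[1] - p1[1]; dz <- p2[3] - p1[3]
  len <- sqrt(dx^2 + dz^2)
  # normal with positive anteroposterior component
  nx <- -dz / len; nz <- dx / len
  if (nz < 0) { nx <- -nx; nz <- -nz }
  if (nz == 0) abort("seed line parallel to the anteroposterior axis")
  (coords[, 1] - p1[1]) * nx + (coords[, 2] - p1[3]) * nz
}

#' Separate touching vertebrae from seed lines
#'
#' For each seed line, the plane it defines (the segment extruded across the
#' mediolateral axis) zeroes foreground voxels; connected components of the
#' cut volume are computed and component labels are tallied on the two
#' anteroposterior sides of the plane within a local window. If the
#' components holding the plurality of votes on the two sides are distinct
#' the boundary is accepted; otherwise both endpoints are stepped outward
#' along the segment's own direction and the test repeats. Voxels between
#' consecutive accepted boundaries receive consecutive labels, assigned per
#' connected component by plurality so no component ever carries two labels.
#'
#' @param mask Logical 3D foreground array (already thresholded).
#' @param seeds A [seed_lines()] tibble, at least 2 rows, ordered along the
#'   anteroposterior axis. For n vertebrae there are n+1 boundaries.
#' @param step Endpoint extension per iteration, voxels.
#' @param window Half-width of the plurality-vote window on each
#'   anteroposterior side of the plane, voxels.
#' @param connectivity Foreground connectivity (26 default).
#' @param vote `"voxel"` (default) tallies voxel counts per component;
#'   `"component"` tallies distinct components.
#' @return A `vertebra_map`: list with `labels` (integer 3D array),
#'   `n_vertebrae`, and the accepted (possibly extended) `seeds`.
#' @export
separate_vertebrae <- function(mask, seeds, step = 2, window = 10,
                               connectivity = 26,
                               vote = c("voxel", "component")) {
  vote <- match.arg(vote)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!inherits(seeds, "seed_lines") || nrow(seeds) < 2)
    abort("need a seed_lines tibble with >= 2 boundaries")
  dims <- dim(mask)
  fg <- which(mask)
  fg_coord <- arrayInd(fg, dims)

  planes <- vector("list", nrow(seeds))
  extents <- numeric(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    p1 <- c(seeds$x1[s], seeds$y1[s], seeds$z1[s])
    p2 <- c(seeds$x2[s], seeds$y2[s], seeds$z2[s])
    u2 <- c(p2[1] - p1[1], p2[3] - p1[3])
    u2 <- u2 / sqrt(sum(u2^2))
    ext <- 0
    repeat {
      plane <- .plane_mask(dims, p1, p2, extend = ext)
      cut <- mask & !plane
      labs <- label_components(cut, connectivity)
      side <- .signed_side(fg_coord[, c(1, 3)], p1, p2)
      in_win <- abs(side) <= window & cut[fg]
      lab_win <- labs[fg][in_win]
      side_win <- side[in_win]
      ok <- lab_win > 0
      lab_win <- lab_win[ok]; side_win <- side_win[ok]
      plur <- function(lv) {
        if (length(lv) == 0) return(NA_integer_)
        tb <- if (vote == "voxel") table(lv) else table(unique(lv))
        top <- tb[tb == max(tb)]
        if (length(top) > 1) return(NA_integer_)  # tie: not separated
        as.integer(names(top))
      }
      p_ant <- plur(lab_win[side_win < 0])
      p_post <- plur(lab_win[side_win > 0])
      separated <- !is.na(p_ant) && !is.na(p_post) && p_ant != p_post
      # a side with no foreground in the window counts as separated
      if (length(lab_win[side_win < 0]) == 0 ||
          length(lab_win[side_win > 0]) == 0) separated <- TRUE
      if (separated) break
      ext <- ext + step
      out_of <- function(q) q[1] < 1 || q[1] > dims[1] ||
        q[2] < 1 || q[2] > dims[3]
      if (out_of(c(p1[1], p1[3]) - ext * u2) &&
          out_of(c(p2[1], p2[3]) + ext * u2))
        abort(sprintf(
          "seed %d: separation line reached the volume boundary without separating",
          seeds$boundary[s]))
    }
    planes[[s]] <- plane
    extents[s] <- ext
  }
  for (i in seq_len(length(planes) - 1))
    for (j in (i + 1):length(planes))
      if (any(planes[[i]] & planes[[j]] & mask))
        abort(sprintf("separation planes of boundaries %d and %d overlap",
                      seeds$boundary[i], seeds$boundary[j]))

  all_planes <- Reduce(`|`, planes)
  cut <- mask & !all_planes
  labs <- label_components(cut, connectivity)
  n_comp <- max(labs)
  fg2 <- which(cut)
  co <- arrayInd(fg2, dims)
  comp <- labs[fg2]
  # vertebra bin = number of boundary planes anterior to the voxel
  nb <- nrow(seeds)
  bin <- integer(length(fg2))
  for (s in seq_len(nb)) {
    p1 <- c(seeds$x1[s], seeds$y1[s], seeds$z1[s])
    p2 <- c(seeds$x2[s], seeds$y2[s], seeds$z2[s])
    bin <- bin + (.signed_side(co[, c(1, 3)], p1, p2) > 0)
  }
  bin[bin < 1 | bin > nb - 1] <- 0L  # outside the seeded window
  # plurality vote per component
  comp_lab <- integer(n_comp)
  votes <- dplyr::count(tibble::tibble(comp = comp, bin = as.integer(bin)),
                        .data$comp, .data$bin)
  votes <- dplyr::slice_max(dplyr::group_by(votes, .data$comp), .data$n,
                            n = 1, with_ties = FALSE)
  comp_lab[votes$comp] <- votes$bin
  out <- array(0L, dims)
  out[fg2] <- comp_lab[comp]
  new_vertebra_map(out, n_vertebrae = nb - 1L, seeds = seeds,
                   extents = extents)
}

new_vertebra_map <- function(labels, n_vertebrae, seeds = NULL,
                             extents = NULL) {
  structure(list(labels = labels, n_vertebrae = as.integer(n_vertebrae),
                 seeds = seeds, extents = extents),
            class = "vertebra_map")
}

#' @export
print.vertebra_map <- function(x, ...) {
  cat(sprintf("<vertebra_map> %d vertebrae, %s labeled voxels\n",
              x$n_vertebrae, format(sum(x$labels > 0), big.mark = ",")))
  invisible(x)
}

#' Sever a connection with a manual cut
#'
#' Zeroes the voxels of the plane defined by a cut segment (extruded
#' mediolaterally), e.g. to detach ribs from fin rays. Idempotent.
#'
#' @param mask Logical 3D array.
#' @param p1,p2 Cut segment endpoints, voxel coordinates `c(x, y, z)`.
#' @return The cut mask.
#' @export
apply_cut <- function(mask, p1, p2) {
  dims <- dim(mask)
  if (any(p1 < 1) || any(p2 < 1) || any(p1 > dims) || any(p2 > dims))
    abort("cut endpoints must lie inside the volume")
  mask & !.plane_mask(dims, p1, p2)
}

#' Reassign connected components to vertebrae
#'
#' @param vmap A `vertebra_map`.
#' @param reassignments Data frame with columns `component` (connected
#'   component id as produced by [label_components()] on the labeled
#'   foreground) and `vertebra` (target label).
#' @param connectivity Connectivity used to identify components.
#' @return The updated `vertebra_map`.
#' @export
assign_components <- function(vmap, reassignments, connectivity = 26) {
  stopifnot(inherits(vmap, "vertebra_map"))
  if (nrow(reassignments) == 0) return(vmap)
  comp <- label_components(vmap$labels > 0, connectivity)
  n_comp <- max(comp)
  labels <- vmap$labels
  for (r in seq_len(nrow(reassignments))) {
    ci <- reassignments$component[r]
    if (ci < 1 || ci > n_comp)
      abort(sprintf("component %s does not exist", ci))
    labels[comp == ci] <- as.integer(reassignments$vertebra[r])
  }
  # invariant: no component carries two labels
  comp2 <- label_components(labels > 0, connectivity)
  fg <- which(labels > 0)
  tab <- tapply(labels[fg], comp2[fg], function(v) length(unique(v)))
  if (any(tab > 1))
    abort("reassignment would give one connected component two labels")
  new_vertebra_map(labels, vmap$n_vertebrae, vmap$seeds, vmap$extents)
}

#' Split one vertebra into neural arch, centrum and haemal arch/rib masks
#'
#' The neural arch is the region dorsal to the line through the two dorsal
#' endpoints of the vertebra's anterior and posterior boundary lines. The
#' centrum is the region inside the quadrilateral spanned by all four
#' endpoints, dilated isotropically by `buffer` voxels, minus the neural
#' arch. The haemal arch/ribs are what remains. The three masks partition
#' the vertebra exactly.
#'
#' @param vertebra Logical 3D array: the voxels of one vertebra.
#' @param anterior,posterior One-row [seed_lines()] slices (or lists with
#'   `x1,y1,z1,x2,y2,z2`) for the vertebra's two boundaries.
#' @param buffer Isotropic dilation of the centrum quadrilateral, voxels.
#' @return List of class `element_masks` with logical arrays `neur`,
#'   `cent`, `haem`.
#' @export
segment_elements <- function(vertebra, anterior, posterior, buffer = 5) {
  stopifnot(is.logical(vertebra), length(dim(vertebra)) == 3L, buffer >= 0)
  dims <- dim(vertebra)
  pts <- function(b) list(d = if (b$x1 <= b$x2) c(b$x1, b$z1) else c(b$x2, b$z2),
                          v = if (b$x1 <= b$x2) c(b$x2, b$z2) else c(b$x1, b$z1))
  a <- pts(anterior); p <- pts(posterior)
  quad <- rbind(a$d, p$d, p$v, a$v)  # (dv, ap), clockwise-ish
  # collinearity check via the shoelace area
  area <- 0.5 * abs(sum(quad[, 1] * quad[c(2, 3, 4, 1), 2] -
                        quad[c(2, 3, 4, 1), 1] * quad[, 2]))
  if (area < 1e-6) abort("degenerate centrum quadrilateral (collinear points)")

  fg <- which(vertebra)
  if (length(fg) == 0)
    return(structure(list(neur = vertebra, cent = vertebra, haem = vertebra),
                     class = "element_masks"))
  co <- arrayInd(fg, dims)

  # neural arch: dorsal to the line through the two dorsal endpoints
  dz <- p$d[2] - a$d[2]
  if (abs(dz) < 1e-9) abort("dorsal endpoints share an anteroposterior slice")
  dv_line <- a$d[1] + (co[, 3] - a$d[2]) * (p$d[1] - a$d[1]) / dz
  is_neur <- co[, 1] < dv_line

  # centrum: inside the buffered quadrilateral prism (2D test in (dv, ap))
  quad_mask <- matrix(FALSE, dims[1], dims[3])
  gx <- rep(seq_len(dims[1]), dims[3])
  gz <- rep(seq_len(dims[3]), each = dims[1])
  inside <- rep(TRUE, length(gx))
  for (e in 1:4) {
    q1 <- quad[e, ]; q2 <- quad[(e %% 4) + 1, ]
    cr <- (q2[1] - q1[1]) * (gz - q1[2]) - (q2[2] - q1[2]) * (gx - q1[1])
    # orientation: centroid must be on the kept side
    ctr <- colMeans(quad)
    cr0 <- (q2[1] - q1[1]) * (ctr[2] - q1[2]) - (q2[2] - q1[2]) * (ctr[1] - q1[1])
    inside <- inside & (cr * sign(cr0) >= 0)
  }
  quad_mask[cbind(gx, gz)] <- inside
  if (buffer > 0) {
    d2 <- .edt3_sq_cpp(array(!quad_mask, c(dims[1], dims[3], 1L)),
                       c(dims[1], dims[3], 1L), FALSE)
    quad_mask <- matrix(d2[, , 1] <= buffer^2, dims[1], dims[3])
  }
  in_quad <- quad_mask[cbind(co[, 1], co[, 3])]
  is_cent <- in_quad & !is_neur

  neur <- cent <- haem <- array(FALSE, dims)
  neur[fg[is_neur]] <- TRUE
  cent[fg[is_cent]] <- TRUE
  haem[fg[!is_neur & !is_cent]] <- TRUE
  structure(list(neur = neur, cent = cent, haem = haem),
            class = "element_masks")
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Overlap agreement in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
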