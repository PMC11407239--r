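#' Cylindrical imaging domain
#'
#' Defines the vessel as a right circular cylinder, axis along z, base at
#' z = 0. All lengths are millimetres. This is the geometry every other
#' module (gridding, optode placement, forward modelling) refers to.
#'
#' @param radius Cylinder radius (mm), > 0.
#' @param height Cylinder height (mm), > 0.
#' @return An object of class `cyl_domain` with fields `radius` and `height`.
#' @examples
#' dom <- cyl_domain(radius = 65, height = 150)  # a 13 cm x 15 cm vessel
#' @export
cyl_domain <- function(radius, height) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (radius <= 0 || height <= 0)
    stop("cylinder radius and height must be positive")
  structure(list(radius = radius, height = height), class = "cyl_domain")
}

#' @export
print.cyl_domain <- function(x, ...) {
  cat(sprintf("Cylindrical domain: radius %.3g mm, height %.3g mm\n",
              x$radius, x$height))
  invisible(x)
}

#' Regular voxel grid over a cylindrical domain
#'
#' The grid spans the cylinder's bounding box (diameter x diameter x height).
#' Voxel `(i, j, k)` (0-based) has its center at
#' `origin + (i + 0.5) * spacing`, with the origin at the lower corner
#' `(-radius, -radius, 0)`. The mask marks voxels whose centers lie inside
#' the cylinder; centers exactly on the surface are included (`<=` test).
#'
#' @param domain A [cyl_domain()].
#' @param dims Integer triple `(nx, ny, nz)`, all positive.
#' @return An object of class `voxel_grid`: `dims`, `spacing` (mm),
#'   `origin` (mm), `mask` (logical array of dim `dims`), `domain`.
#' @examples
#' g <- build_voxel_grid(cyl_domain(65, 150), c(48, 48, 56))
#' g$spacing  # c(2.708, 2.708, 2.679) mm
#' @export
build_voxel_grid <- function(domain, dims) {
  stopifnot(inherits(domain, "cyl_domain"))
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L))
    stop("dims must be a triple of positive integers")
  extent <- c(2 * domain$radius, 2 * domain$radius, domain$height)
  spacing <- extent / dims
  origin <- c(-domain$radius, -domain$radius, 0)
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  r2 <- outer(cx^2, cy^2, `+`)
  in_circle <- r2 <= domain$radius^2
  in_z <- cz >= 0 & cz <= domain$height
  mask <- array(FALSE, dims)
  for (k in seq_len(dims[3])) if (in_z[k]) mask[, , k] <- in_circle
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 mask = mask, domain = domain),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %dx%dx%d, spacing (%.3f, %.3f, %.3f) mm, %d masked voxels\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$mask)))
  invisible(x)
}

#' Voxel volume of a grid (mm^3)
#' @param grid A [build_voxel_grid()] grid.
#' @return Scalar voxel volume, the product of the spacings.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel center coordinates
#'
#' @param grid A `voxel_grid`.
#' @param idx Optional vector of linear voxel indices (1-based, x fastest);
#'   default all voxels.
#' @return Matrix `length(idx) x 3` of center coordinates (mm).
#' @export
voxel_centers <- function(grid, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prod(grid$dims))
  sub <- arrayInd(idx, grid$dims)
  sweep(sub - 0.5, 2, grid$spacing, `*`) +
    matrix(grid$origin, nrow(sub), 3, byrow = TRUE)
}

#' Locate the voxel containing a point
#' @param grid A `voxel_grid`.
#' @param point Length-3 coordinate (mm).
#' @return Linear voxel index, or `NA` if outside the grid box.
#' @export
voxel_at <- function(grid, point) {
  ijk <- floor((point - grid$origin) / grid$spacing) + 1
  if (any(ijk < 1) || any(ijk > grid$dims)) return(NA_integer_)
  as.integer(ijk[1] + (ijk[2] - 1) * grid$dims[1] +
               (ijk[3] - 1) * grid$dims[1] * grid$dims[2])
}

ring_positions <- function(domain, rings, per_ring, phase = 0) {
  dz <- domain$height / rings
  z <- (seq_len(rings) - 0.5) * dz
  ang <- 2 * pi * (seq_len(per_ring) - 1) / per_ring + phase
  data.frame(
    x = rep(domain$radius * cos(ang), times = rings),
    y = rep(domain$radius * sin(ang), times = rings),
    z = rep(z, each = per_ring)
  )
}

#' Place sources and detectors on the lateral surface
#'
#' Optodes are arranged in equally spaced rings: within a ring, positions are
#' equally spaced in angle; rings are equally spaced in z with half-spacing
#' margins from the top and bottom edges. By default the detector rings are
#' rotated by half an angular step relative to the source rings so that the
#' two sets interleave.
#'
#' @param domain A [cyl_domain()].
#' @param n_sources,n_detectors Total optode counts; each must equal
#'   `rings * per_ring` of its pattern.
#' @param source_pattern,detector_pattern Integer pairs `c(rings, per_ring)`.
#' @param detector_phase Angular offset (radians) of the detector rings;
#'   default half a detector angular step.
#' @return An object of class `optode_layout`: data.frames `sources` and
#'   `detectors` (columns `x`, `y`, `z` in mm) and an empty `channels` table
#'   (populated by [form_channels()]).
#' @examples
#' dom <- cyl_domain(65, 150)
#' lay <- place_optodes(dom, 64, 56, c(8, 8), c(7, 8))
#' @export
place_optodes <- function(domain, n_sources, n_detectors,
                          source_pattern = c(8L, 8L),
                          detector_pattern = c(7L, 8L),
                          detector_phase = NULL) {
  stopifnot(inherits(domain, "cyl_domain"))
  source_pattern <- as.integer(source_pattern)
  detector_pattern <- as.integer(detector_pattern)
  if (prod(source_pattern) != n_sources)
    stop("n_sources does not factorize as rings x per-ring of source_pattern")
  if (prod(detector_pattern) != n_detectors)
    stop("n_detectors does not factorize as rings x per-ring of detector_pattern")
  if (is.null(detector_phase)) detector_phase <- pi / detector_pattern[2]
  src <- ring_positions(domain, source_pattern[1], source_pattern[2], 0)
  det <- ring_positions(domain, detector_pattern[1], detector_pattern[2],
                        detector_phase)
  structure(list(sources = src, detectors = det,
                 channels = data.frame(source = integer(0),
                                       detector = integer(0),
                                       separation_mm = numeric(0)),
                 domain = domain),
            class = "optode_layout")
}

#' @export
print.optode_layout <- function(x, ...) {
  cat(sprintf("Optode layout: %d sources, %d detectors, %d channels\n",
              nrow(x$sources), nrow(x$detectors), nrow(x$channels)))
  invisible(x)
}

#' Form source-detector channels by maximum separation
#'
#' Keeps every (source, detector) pair whose Euclidean separation is strictly
#' below `max_separation` (the printed convention "separation of less than
#' 7 cm" for the dense simulated layout).
#'
#' @param layout An `optode_layout`.
#' @param max_separation Maximum separation (mm), strict upper bound.
#' @return The layout with its `channels` table populated
#'   (`source`, `detector`, `separation_mm`).
#' @export
form_channels <- function(layout, max_separation) {
  stopifnot(inherits(layout, "optode_layout"),
            is.numeric(max_separation), length(max_separation) == 1L)
  S <- as.matrix(layout$sources[, c("x", "y", "z")])
  D <- as.matrix(layout$detectors[, c("x", "y", "z")])
  ns <- nrow(S); nd <- nrow(D)
  # full pairwise distance matrix (sources x detectors)
  d2 <- outer(rowSums(S^2), rowSums(D^2), `+`) - 2 * S %*% t(D)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  keep <- which(dist < max_separation, arr.ind = TRUE)
  ch <- data.frame(source = keep[, 1], detector = keep[, 2],
                   separation_mm = dist[keep])
  ch <- ch[order(ch$source, ch$detector), , drop = FALSE]
  rownames(ch) <- NULL
  layout$channels <- ch
  layout
}

#' Rotate an optode layout about the cylinder axis
#'
#' Utility (used e.g. in symmetry checks): rigidly rotates all optode
#' positions by `angle` radians about z.
#' @param layout An `optode_layout`.
#' @param angle Rotation angle (radians).
#' @return The rotated layout (channels, if formed, are kept: separations are
#'   rotation invariant).
#' @export
rotate_layout <- function(layout, angle) {
  rot <- function(df) {
    x <- df$x * cos(angle) - df$y * sin(angle)
    y <- df$x * sin(angle) + df$y * cos(angle)
    df$x <- x; df$y <- y
    df
  }
  layout$sources <- rot(layout$sources)
  layout$detectors <- rot(layout$detectors)
  layout
}

#' Wrap a square grid of positions onto the lateral surface
#'
#' Reproduces a printed measurement layout: a `pitch x pitch` square lattice
#' wrapped onto the side of the cylinder. Angular columns are placed at
#' arc-length multiples of the pitch (their count is
#' `floor(circumference / pitch)`), and rows at `z = pitch/2, 3*pitch/2, ...`
#' while `z <= height - pitch/2` (half-pitch margins at both ends).
#'
#' @param domain A [cyl_domain()].
#' @param pitch Grid pitch (mm), `0 < pitch <= circumference`.
#' @return data.frame with columns `x`, `y`, `z` (mm), `col` (angular column,
#'   1-based), `row` (z row, 1-based).
#' @export
wrap_grid_on_surface <- function(domain, pitch) {
  stopifnot(inherits(domain, "cyl_domain"))
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("pitch must be a positive scalar")
  circ <- 2 * pi * domain$radius
  if (pitch > circ) stop("pitch exceeds the cylinder circumference")
  ncol_ <- floor(circ / pitch)
  ang <- (seq_len(ncol_) - 1) * pitch / domain$radius
  if (pitch / 2 > domain$height - pitch / 2) {
    z <- numeric(0)
  } else {
    z <- seq(pitch / 2, domain$height - pitch / 2 + 1e-12, by = pitch)
    z <- z[z <= domain$height - pitch / 2 + 1e-9]
  }
  out <- expand.grid(col = seq_len(ncol_), row = seq_along(z))
  out$x <- domain$radius * cos(ang[out$col])
  out$y <- domain$radius * sin(ang[out$col])
  out$z <- z[out$row]
  out[, c("x", "y", "z", "col", "row")]
}

#' Write / read optode layouts as CSV
#'
#' Layout CSV columns: `kind` ("source"/"detector"), `index`, `x_mm`, `y_mm`,
#' `z_mm`. Channel CSV columns: `source_index`, `detector_index`,
#' `separation_mm`.
#' @param layout An `optode_layout`.
#' @param path,channels_path File paths; `channels_path = NULL` skips channels.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path, channels_path = NULL) {
  s <- layout$sources; d <- layout$detectors
  tab <- rbind(
    data.frame(kind = "source", index = seq_len(nrow(s)),
               x_mm = s$x, y_mm = s$y, z_mm = s$z),
    data.frame(kind = "detector", index = seq_len(nrow(d)),
               x_mm = d$x, y_mm = d$y, z_mm = d$z))
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(channels_path) && nrow(layout$channels) > 0) {
    ch <- layout$channels
    utils::write.csv(data.frame(source_index = ch$source,
                                detector_index = ch$detector,
                                separation_mm = ch$separation_mm),
                     channels_path, row.names = FALSE)
  }
  invisible(path)
}
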