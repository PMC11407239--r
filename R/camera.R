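# polynomial design matrix in two variables up to total degree d
poly2d_design <- function(u, v, degree) {
  cols <- list()
  for (p in 0:degree) for (q in 0:(degree - p)) cols[[length(cols) + 1]] <- u^p * v^q
  do.call(cbind, cols)
}

n_poly2d <- function(degree) (degree + 1) * (degree + 2) / 2

#' Fit the unwrapping transform from control points
#'
#' Least-squares polynomial 2D transforms in both directions between camera
#' pixel coordinates and the idealized rectilinear grid (the printed
#' calibration sheet has a 1 cm physical pitch). The forward map takes
#' pixels to grid coordinates; the inverse map takes grid coordinates to
#' pixels. Round-trip residuals on the control points are reported and must
#' stay below 0.5 px.
#'
#' @param pixel Matrix (n x 2) of control-point pixel coordinates.
#' @param grid_xy Matrix (n x 2) of the corresponding rectilinear
#'   coordinates (e.g. cm or mm units of the physical grid).
#' @param degree Polynomial total degree (default 3).
#' @return Object of class `calibration_map`: coefficient matrices
#'   `fwd_coef`, `inv_coef` (terms x 2), `degree`, `rms_roundtrip_px`.
#' @export
fit_unwrap_transform <- function(pixel, grid_xy, degree = 3) {
  pixel <- as.matrix(pixel); grid_xy <- as.matrix(grid_xy)
  stopifnot(ncol(pixel) == 2, ncol(grid_xy) == 2,
            nrow(pixel) == nrow(grid_xy))
  nterm <- n_poly2d(degree)
  if (nrow(pixel) < nterm)
    stop(sprintf("need at least %d control points for degree %d", nterm, degree))
  Xf <- poly2d_design(pixel[, 1], pixel[, 2], degree)
  Xi <- poly2d_design(grid_xy[, 1], grid_xy[, 2], degree)
  if (qr(Xf)$rank < nterm || qr(Xi)$rank < nterm)
    stop("control points are rank deficient for the requested degree")
  fwd <- qr.solve(Xf, grid_xy)
  inv <- qr.solve(Xi, pixel)
  # round trip: pixel -> grid -> pixel
  g <- Xf %*% fwd
  p_back <- poly2d_design(g[, 1], g[, 2], degree) %*% inv
  rms <- sqrt(mean(rowSums((p_back - pixel)^2)))
  structure(list(fwd_coef = fwd, inv_coef = inv, degree = degree,
                 rms_roundtrip_px = rms),
            class = "calibration_map")
}

#' Apply a calibration map
#' @param map A `calibration_map`.
#' @param xy Matrix (n x 2) of coordinates.
#' @param direction `"forward"` (pixel to grid) or `"inverse"` (grid to
#'   pixel).
#' @return Matrix (n x 2) of transformed coordinates.
#' @export
apply_transform <- function(map, xy, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  xy <- matrix(as.numeric(xy), ncol = 2)
  cf <- if (direction == "forward") map$fwd_coef else map$inv_coef
  poly2d_design(xy[, 1], xy[, 2], map$degree) %*% cf
}

# bilinear sampling of an image at fractional pixel coordinates; points
# outside return NA
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  # snap coordinates a rounding error outside the raster back onto it
  x <- ifelse(abs(x - 1) < 1e-6, 1, ifelse(abs(x - nr) < 1e-6, nr, x))
  y <- ifelse(abs(y - 1) < 1e-6, 1, ifelse(abs(y - nc) < 1e-6, nc, y))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 <= nr - 1 & y0 >= 1 & y0 <= nc - 1
  # clamp exact upper edge
  edge <- x >= 1 & x <= nr & y >= 1 & y <= nc & !ok
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i <- x0[ok]; j <- y0[ok]; a <- fx[ok]; b <- fy[ok]
    out[ok] <- img[cbind(i, j)] * (1 - a) * (1 - b) +
      img[cbind(i + 1, j)] * a * (1 - b) +
      img[cbind(i, j + 1)] * (1 - a) * b +
      img[cbind(i + 1, j + 1)] * a * b
  }
  if (any(edge)) {
    i <- pmin(pmax(round(x[edge]), 1), nr)
    j <- pmin(pmax(round(y[edge]), 1), nc)
    out[edge] <- img[cbind(i, j)]
  }
  out
}

#' Unwrap one cylindrical section
#'
#' Builds a dense rectilinear grid at the target pitch over the given grid
#' extent, maps each grid point back into the camera image with the inverse
#' transform, and samples the image bilinearly. Grid points mapping outside
#' the image are set to `NA` and masked.
#'
#' @param image Numeric matrix (rows = image x/pixel rows, cols = y).
#' @param map A [fit_unwrap_transform()] `calibration_map`.
#' @param grid_range List with `u` and `v` ranges (in rectilinear units) to
#'   cover.
#' @param pitch Target pitch in rectilinear units per output pixel.
#' @return Object of class `unwrapped_image`: `values` matrix, `u`, `v`
#'   axes, `pitch`, `valid` mask, `sections` provenance (single section id).
#' @export
unwrap_section <- function(image, map, grid_range, pitch) {
  u <- seq(grid_range$u[1], grid_range$u[2], by = pitch)
  v <- seq(grid_range$v[1], grid_range$v[2], by = pitch)
  pts <- as.matrix(expand.grid(u = u, v = v))
  px <- apply_transform(map, pts, "inverse")
  vals <- bilinear_sample(image, px[, 1], px[, 2])
  m <- matrix(vals, length(u), length(v))
  structure(list(values = m, u = u, v = v, pitch = pitch,
                 valid = !is.na(m), sections = 1L),
            class = "unwrapped_image")
}

#' Stitch unwrapped sections side by side
#'
#' Horizontally concatenates the sections (matching row extents and pitch)
#' in the given order, retaining per-column section provenance.
#'
#' @param sections List of `unwrapped_image`s (or plain matrices).
#' @param order Integer permutation giving the left-to-right order
#'   (default as supplied).
#' @return An `unwrapped_image` whose `sections` vector labels each column
#'   with its source section.
#' @export
stitch_sections <- function(sections, order = seq_along(sections)) {
  mats <- lapply(sections, function(s)
    if (inherits(s, "unwrapped_image")) s$values else s)
  pitches <- vapply(sections, function(s)
    if (inherits(s, "unwrapped_image")) s$pitch else NA_real_, numeric(1))
  if (any(!is.na(pitches)) &&
      any(abs(stats::na.omit(pitches) - stats::na.omit(pitches)[1]) >
          1e-9 * stats::na.omit(pitches)[1]))
    stop("sections have mismatched pitch")
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1) stop("sections have mismatched vertical extents")
  mats <- mats[order]
  out <- do.call(cbind, mats)
  prov <- rep(order, vapply(mats, ncol, integer(1)))
  structure(list(values = out, u = seq_len(nrow(out)), v = seq_len(ncol(out)),
                 pitch = if (all(is.na(pitches))) 1 else stats::na.omit(pitches)[1],
                 valid = !is.na(out), sections = prov),
            class = "unwrapped_image")
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

dilate_mask <- function(mask, radius) {
  offs <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (nrow(idx) == 0) return(out)
  for (k in seq_len(nrow(offs))) {
    i <- idx[, 1] + offs$dx[k]; j <- idx[, 2] + offs$dy[k]
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out[cbind(i[ok], j[ok])] <- TRUE
  }
  out
}

# harmonic (Laplace) fill of masked pixels with Dirichlet data from the
# unmasked neighbors; parameter-free and smooth
harmonic_fill <- function(img, mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  row_of <- matrix(0L, nr, nc)
  row_of[idx] <- seq_along(idx)
  sub <- arrayInd(idx, c(nr, nc))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(length(idx))
  diag_v <- numeric(length(idx))
  for (k in 1:4) {
    di <- c(1L, -1L, 0L, 0L)[k]; dj <- c(0L, 0L, 1L, -1L)[k]
    i2 <- sub[, 1] + di; j2 <- sub[, 2] + dj
    inb <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    lin2 <- idx + di + dj * nr
    r2 <- integer(length(idx)); r2[inb] <- row_of[lin2[inb]]
    interior <- inb & r2 > 0L
    boundary <- inb & r2 == 0L
    diag_v <- diag_v + as.numeric(inb)
    ii <- c(ii, which(interior)); jj <- c(jj, r2[interior])
    xx <- c(xx, rep(-1, sum(interior)))
    b[boundary] <- b[boundary] + img[lin2[boundary]]
  }
  n <- length(idx)
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, pmax(diag_v, 1)), dims = c(n, n))
  img[idx] <- as.numeric(Matrix::solve(A, b))
  img
}

#' Remove saturated spots
#'
#' Detects pixels at or above the saturation threshold, dilates the
#' detected set with a disk (default radius 5 px), and replaces the region
#' by harmonic interpolation from the surrounding pixels (the smooth,
#' parameter-free Laplace fill).
#'
#' @param image Numeric matrix.
#' @param threshold Saturation threshold: the raster's full-scale value
#'   (e.g. 255 for 8-bit images; defaults to the image maximum). A threshold
#'   above every pixel simply returns the image unchanged.
#' @param dilate_radius Disk radius in pixels (default 5).
#' @return The image with spots filled; attribute `spot_mask` records the
#'   filled region.
#' @export
remove_spots <- function(image, threshold = max(image), dilate_radius = 5) {
  sat <- image >= threshold
  if (all(sat)) stop("entire image saturated: nothing to interpolate from")
  if (!any(sat)) {
    attr(image, "spot_mask") <- sat
    return(image)
  }
  mask <- dilate_mask(sat, dilate_radius)
  if (all(mask)) stop("dilated saturation mask covers the whole image")
  out <- harmonic_fill(image, mask)
  attr(out, "spot_mask") <- mask
  out
}

#' Median smoothing with reflective padding
#'
#' Per-pixel median over a `window x window` neighborhood; edges use
#' reflective padding.
#'
#' @param image Numeric matrix at least `window` in both extents.
#' @param window Odd window size (default 7).
#' @return Smoothed matrix of the same size.
#' @export
median_smooth <- function(image, window = 7) {
  stopifnot(window %% 2 == 1, nrow(image) >= window, ncol(image) >= window)
  half <- (window - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  refl <- function(i, n) {           # reflective index (no edge repeat)
    i <- abs(i - 1) + 1
    k <- (i - 1) %% (2 * (n - 1))
    ifelse(k < n, k + 1, 2 * n - 1 - k)
  }
  ri <- refl(seq(1 - half, nr + half), nr)
  ci <- refl(seq(1 - half, nc + half), nc)
  pad <- image[ri, ci, drop = FALSE]
  stack <- matrix(NA_real_, nr * nc, window^2)
  k <- 0
  for (dj in 0:(window - 1)) for (di in 0:(window - 1)) {
    k <- k + 1
    stack[, k] <- as.vector(pad[di + seq_len(nr), dj + seq_len(nc)])
  }
  matrix(apply(stack, 1, stats::median), nr, nc)
}

#' Sample measurement amplitudes from an unwrapped image
#'
#' Each measurement position maps to a pixel of the unwrapped raster; the
#' amplitude is the median of the 3x3 pixel block centered there. Blocks
#' are truncated at the image border (documented truncation rule).
#'
#' @param unwrapped An `unwrapped_image` or numeric matrix.
#' @param pixels Matrix (n x 2) of mapped pixel coordinates (row, col);
#'   rounded to the nearest pixel.
#' @return Numeric vector of amplitudes.
#' @export
sample_measurements <- function(unwrapped, pixels) {
  img <- if (inherits(unwrapped, "unwrapped_image")) unwrapped$values else unwrapped
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  nr <- nrow(img); nc <- ncol(img)
  vapply(seq_len(nrow(pixels)), function(k) {
    i <- round(pixels[k, 1]); j <- round(pixels[k, 2])
    if (i < 1 || i > nr || j < 1 || j > nc)
      stop("measurement position maps outside the raster")
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    stats::median(img[ii, jj])
  }, numeric(1))
}

#' Deterministic synthetic three-view camera fixture
#'
#' Generates a known smooth panorama (sum of Gaussian blobs on a gentle
#' ramp), splits it into three sections, warps each with a known mild
#' quadratic map, plants saturated spots, and returns everything needed to
#' exercise the full preprocessing chain against ground truth.
#'
#' @param seed Integer seed.
#' @param width,height Panorama size in pixels (default 96 x 48).
#' @param n_spots Saturated spots to plant (default 3).
#' @return List: `raw` (list of 3 warped section images), `maps` (list of 3
#'   true `calibration_map`s fitted on dense control points), `control`
#'   (per-section control-point pairs), `truth` (the clean panorama matrix),
#'   `spots` (planted spot centers per section), `sections` (column ranges
#'   of the panorama per section).
#' @export
synth_camera_fixture <- function(seed = 1, width = 96, height = 48,
                                 n_spots = 3) {
  set.seed(seed)
  u <- seq_len(height); v <- seq_len(width)
  pano <- outer(u, v, function(a, b) 0.2 + 0.3 * b / width + 0.1 * a / height)
  for (k in 1:4) {
    cu <- stats::runif(1, 5, height - 5); cv <- stats::runif(1, 5, width - 5)
    s <- stats::runif(1, 4, 9)
    pano <- pano + 0.5 * outer(u, v, function(a, b)
      exp(-((a - cu)^2 + (b - cv)^2) / (2 * s^2)))
  }
  w3 <- width / 3
  secs <- lapply(1:3, function(s) round((s - 1) * w3) + seq_len(round(w3)))
  warp_pars <- lapply(1:3, function(s)
    c(a = stats::runif(1, 0.9, 1.1), b = stats::runif(1, -0.002, 0.002),
      c = stats::runif(1, 2, 6), d = stats::runif(1, 0.9, 1.1),
      e = stats::runif(1, -0.002, 0.002), f = stats::runif(1, 2, 6)))
  # true warp: grid (u,v) -> pixel (x,y), mildly quadratic
  warp <- function(p, uv)
    cbind(p["a"] * uv[, 1] + p["b"] * uv[, 1] * uv[, 2] + p["c"],
          p["d"] * uv[, 2] + p["e"] * uv[, 2]^2 + p["f"])
  raw <- list(); maps <- list(); control <- list(); spots <- list()
  for (s in 1:3) {
    cols <- secs[[s]]
    sec_img <- pano[, cols, drop = FALSE]
    nu <- nrow(sec_img); nv <- ncol(sec_img)
    p <- warp_pars[[s]]
    # raw image big enough to hold the warped section
    corner <- warp(p, cbind(c(1, nu, 1, nu), c(1, 1, nv, nv)))
    nxr <- ceiling(max(corner[, 1])) + 2
    nyr <- ceiling(max(corner[, 2])) + 2
    # render raw image by inverse lookup: for each raw pixel, invert the
    # warp numerically on the regular structure (warp is separable enough
    # to invert per-coordinate by iteration)
    xr <- seq_len(nxr); yr <- seq_len(nyr)
    gridpix <- as.matrix(expand.grid(x = xr, y = yr))
    uv <- gridpix
    for (it in 1:25) {   # fixed-point inversion of the mild warp
      xy <- warp(p, uv)
      uv <- uv + 0.9 * (gridpix - xy)
    }
    vals <- bilinear_sample(sec_img, uv[, 1], uv[, 2])
    vals[is.na(vals)] <- 0
    img <- matrix(vals, nxr, nyr)
    # plant saturated spots inside the warped area
    sp <- matrix(NA_real_, 0, 2)
    for (q in seq_len(n_spots)) {
      cx <- stats::runif(1, 8, nxr - 8); cy <- stats::runif(1, 8, nyr - 8)
      d2 <- outer((xr - cx)^2, (yr - cy)^2, `+`)
      img[d2 <= 2^2] <- 1.5
      sp <- rbind(sp, c(cx, cy))
    }
    spots[[s]] <- sp
    raw[[s]] <- img
    # control points: the printed calibration lattice every 4 units
    cu_ <- seq(1, nu, by = 4); cv_ <- seq(1, nv, by = 4)
    cp_grid <- as.matrix(expand.grid(u = cu_, v = cv_))
    cp_pix <- warp(p, cp_grid)
    control[[s]] <- list(pixel = cp_pix, grid = cp_grid)
    maps[[s]] <- fit_unwrap_transform(cp_pix, cp_grid, degree = 3)
  }
  list(raw = raw, maps = maps, control = control, truth = pano,
       spots = spots, sections = secs)
}
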