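#' Thresholded intersection-over-union
#'
#' `IoU = |{recon > threshold} n {truth > 0}| / |{recon > threshold} u
#' {truth > 0}|`, counted over voxels of the region mask (default: the whole
#' cylinder mask). The reconstruction is expected in std-normalized units,
#' so the default threshold 1 means "one standard deviation".
#'
#' @param recon Array or `recon_volume` (std-normalized amplitudes).
#' @param truth Array or `fluor_map` of the ground truth.
#' @param threshold Reconstruction threshold (default 1).
#' @param region Optional logical array restricting the counted voxels;
#'   default the grid mask if `recon` is a `recon_volume`, else all voxels.
#' @return IoU in `[0, 1]`; 0 with a warning when both sets are empty.
#' @export
iou <- function(recon, truth, threshold = 1, region = NULL) {
  if (inherits(recon, "recon_volume")) {
    if (is.null(region)) region <- recon$grid$mask
    recon <- recon$values
  }
  if (inherits(truth, "fluor_map")) truth <- truth$values
  stopifnot(all(dim(recon) == dim(truth)))
  if (is.null(region)) region <- array(TRUE, dim(recon))
  a <- recon > threshold & region
  b <- truth > 0 & region
  uni <- sum(a | b)
  if (uni == 0) {
    warning("empty union: IoU defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Center-of-mass bias
#'
#' Euclidean distance (mm) between the intensity-weighted centroid of the
#' thresholded reconstruction within a region and the true inclusion center.
#'
#' @param recon Array or `recon_volume` of amplitudes.
#' @param grid The `voxel_grid` (for voxel coordinates).
#' @param true_center Length-3 true inclusion center (mm).
#' @param threshold Amplitude threshold defining the region's support
#'   (default 1, std-normalized units).
#' @param region Optional logical array (e.g. a per-inclusion half-cylinder).
#' @return Bias in mm, or `NA` (with a warning) if the thresholded region is
#'   empty.
#' @export
com_bias <- function(recon, grid, true_center, threshold = 1, region = NULL) {
  if (inherits(recon, "recon_volume")) recon <- recon$values
  if (is.null(region)) region <- grid$mask
  sel <- which(recon > threshold & region)
  if (length(sel) == 0) {
    warning("empty thresholded region: bias undefined")
    return(NA_real_)
  }
  w <- recon[sel]
  cen <- voxel_centers(grid, sel)
  com <- colSums(cen * w) / sum(w)
  sqrt(sum((com - true_center)^2))
}

#' Full width at half maximum (equivalent spherical diameter)
#'
#' Size summary of the above-half-peak region: with `V` the total volume of
#' voxels whose amplitude is at least half the regional peak,
#' `FWHM = 2 * (3V / 4 pi)^(1/3)` — the diameter of the sphere of equal
#' volume. Deterministic and shape-independent; an axis-aligned maximum
#' extent is available via `method = "extent"` (the largest of the x/y/z
#' bounding-box extents of the half-max set).
#'
#' @param recon Array or `recon_volume`.
#' @param grid The `voxel_grid`.
#' @param region Optional logical array (default grid mask).
#' @param method `"equivalent_sphere"` (default) or `"extent"`.
#' @return FWHM in mm; `NA` with a warning if the region has no positive
#'   peak.
#' @export
fwhm <- function(recon, grid, region = NULL,
                 method = c("equivalent_sphere", "extent")) {
  method <- match.arg(method)
  if (inherits(recon, "recon_volume")) recon <- recon$values
  if (is.null(region)) region <- grid$mask
  vals <- recon[region]
  peak <- max(vals)
  if (!is.finite(peak) || peak <= 0) {
    warning("no positive peak in region: FWHM undefined")
    return(NA_real_)
  }
  half_set <- which(recon >= peak / 2 & region)
  if (method == "equivalent_sphere") {
    V <- length(half_set) * voxel_volume(grid)
    2 * (3 * V / (4 * pi))^(1 / 3)
  } else {
    cen <- voxel_centers(grid, half_set)
    max(apply(cen, 2, function(v) diff(range(v))) +
          grid$spacing)  # include the voxel extent itself
  }
}

#' Structural similarity over a subregion around the true inclusions
#'
#' Both volumes are normalized by their maxima over the subregion (the union
#' of balls of `radius` mm about the true centers), then a single-window
#' SSIM is computed with constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`,
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 1`:
#' `SSIM = (2 mx my + C1)(2 sxy + C2) / ((mx^2 + my^2 + C1)(sx^2 + sy^2 + C2))`
#' with population moments over the subregion.
#'
#' @param recon,truth Arrays or volume objects.
#' @param grid The `voxel_grid`.
#' @param centers Matrix (k x 3) or length-3 vector of true inclusion
#'   centers (mm).
#' @param radius Subregion ball radius in mm (default 30).
#' @param K1,K2 SSIM stability constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_subregion <- function(recon, truth, grid, centers, radius = 30,
                           K1 = 0.01, K2 = 0.03) {
  if (inherits(recon, "recon_volume")) recon <- recon$values
  if (inherits(truth, "fluor_map")) truth <- truth$values
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  cen <- voxel_centers(grid)
  inball <- rep(FALSE, nrow(cen))
  for (i in seq_len(nrow(centers)))
    inball <- inball | (cen[, 1] - centers[i, 1])^2 +
      (cen[, 2] - centers[i, 2])^2 + (cen[, 3] - centers[i, 3])^2 <= radius^2
  sub <- inball & as.vector(grid$mask)
  if (!any(sub)) stop("empty subregion")
  x <- recon[sub]; y <- truth[sub]
  mx_ <- max(abs(x)); my_ <- max(abs(y))
  if (mx_ <= 0 || my_ <= 0) stop("zero-max input to SSIM")
  x <- x / mx_; y <- y / my_
  C1 <- K1^2; C2 <- K2^2
  mux <- mean(x); muy <- mean(y)
  vx <- mean((x - mux)^2); vy <- mean((y - muy)^2)
  cxy <- mean((x - mux) * (y - muy))
  (2 * mux * muy + C1) * (2 * cxy + C2) /
    ((mux^2 + muy^2 + C1) * (vx + vy + C2))
}

#' Half-cylinder region masks
#'
#' Splits the grid mask along the y-z plane into the `x > 0` and `x < 0`
#' halves (used to score inclusions separately when two are present on
#' opposite sides).
#'
#' @param grid A `voxel_grid`.
#' @return List of two logical arrays `xpos`, `xneg`.
#' @export
half_cylinder_masks <- function(grid) {
  cen <- voxel_centers(grid)
  xpos <- array(cen[, 1] > 0, grid$dims) & grid$mask
  xneg <- array(cen[, 1] < 0, grid$dims) & grid$mask
  list(xpos = xpos, xneg = xneg)
}

#' Evaluate one case: classic vs denoised
#'
#' Computes all four metrics (IoU, center-of-mass bias, FWHM, subregion
#' SSIM) for both reconstructions against the truth. Reconstructions are
#' std-normalized first if they are not already flagged as such.
#'
#' @param classic,denoised `recon_volume`s or arrays (std-normalized or raw).
#' @param truth Array or `fluor_map`.
#' @param grid The `voxel_grid`.
#' @param centers Optional true inclusion centers (k x 3); defaults to the
#'   intensity centroid of the truth.
#' @param threshold IoU / support threshold (default 1).
#' @param ssim_radius Subregion radius (mm, default 30).
#' @return Object of class `evaluation_report`: data.frame with one row per
#'   method (`classic`, `denoised`) and columns `iou`, `bias_mm`, `fwhm_mm`,
#'   `ssim`; thresholds recorded as attributes.
#' @export
evaluate_case <- function(classic, denoised, truth, grid, centers = NULL,
                          threshold = 1, ssim_radius = 30) {
  norm_arr <- function(v) {
    if (inherits(v, "recon_volume")) {
      if (v$normalized) return(v$values)
      return(normalize_volume(v)$values)
    }
    v
  }
  cl <- norm_arr(classic); dn <- norm_arr(denoised)
  if (inherits(truth, "fluor_map")) truth <- truth$values
  if (is.null(centers)) {
    sel <- which(truth > 0)
    if (length(sel) == 0) stop("truth volume is empty")
    cenv <- voxel_centers(grid, sel)
    centers <- matrix(colSums(cenv * truth[sel]) / sum(truth[sel]), nrow = 1)
  }
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  one <- function(v) {
    c(iou = iou(v, truth, threshold, grid$mask),
      bias_mm = com_bias(v, grid, colMeans(centers), threshold),
      fwhm_mm = suppressWarnings(fwhm(v, grid)),
      ssim = ssim_subregion(v, truth, grid, centers, ssim_radius))
  }
  rep_ <- rbind(classic = one(cl), denoised = one(dn))
  out <- as.data.frame(rep_)
  out$method <- rownames(rep_)
  rownames(out) <- NULL
  out <- out[, c("method", "iou", "bias_mm", "fwhm_mm", "ssim")]
  attr(out, "threshold") <- threshold
  attr(out, "ssim_radius") <- ssim_radius
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Evaluate a test set: per-case IoU and the paired improvement test
#'
#' @param classic_list,denoised_list Lists of std-normalized arrays (or
#'   volumes).
#' @param truth_list List of truth arrays.
#' @param grid The `voxel_grid`.
#' @param threshold IoU threshold (default 1).
#' @return List: `iou` (data.frame case/classic/denoised), `mean_classic`,
#'   `sd_classic`, `mean_denoised`, `sd_denoised`, `fold_improvement`, and
#'   `paired_test` (`t.test` result on the paired IoU differences, or NULL
#'   when all differences are zero).
#' @export
evaluate_dataset <- function(classic_list, denoised_list, truth_list, grid,
                             threshold = 1) {
  n <- length(classic_list)
  stopifnot(length(denoised_list) == n, length(truth_list) == n)
  get_arr <- function(v) if (inherits(v, "recon_volume")) v$values else v
  iou_c <- numeric(n); iou_d <- numeric(n)
  for (i in seq_len(n)) {
    iou_c[i] <- iou(get_arr(classic_list[[i]]), truth_list[[i]], threshold,
                    grid$mask)
    iou_d[i] <- iou(get_arr(denoised_list[[i]]), truth_list[[i]], threshold,
                    grid$mask)
  }
  d <- iou_d - iou_c
  pt <- if (n > 1 && isTRUE(stats::sd(d) > 0))
    stats::t.test(iou_d, iou_c, paired = TRUE) else NULL
  list(iou = data.frame(case = seq_len(n), classic = iou_c, denoised = iou_d),
       mean_classic = mean(iou_c), sd_classic = stats::sd(iou_c),
       mean_denoised = mean(iou_d), sd_denoised = stats::sd(iou_d),
       fold_improvement = mean(iou_d) / mean(iou_c),
       paired_test = pt)
}
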