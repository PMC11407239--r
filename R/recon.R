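#' Measurement set for paired excitation/emission amplitudes
#'
#' A per-channel table of measured excitation and emission amplitudes with
#' the derived Born ratio and a validity mask.
#'
#' @param channels Channel table (`source`, `detector`, optionally
#'   `separation_mm`).
#' @param phix,phim Numeric vectors of excitation and emission amplitudes,
#'   one per channel (arbitrary units).
#' @return Object of class `measurement_set`: data.frame with columns
#'   `channel`, `source`, `detector`, `phix`, `phim`, `y` (NA until
#'   [born_ratio()] is called), `valid`.
#' @export
measurement_set <- function(channels, phix, phim) {
  M <- nrow(channels)
  stopifnot(length(phix) == M, length(phim) == M)
  ms <- data.frame(channel = seq_len(M),
                   source = channels$source, detector = channels$detector,
                   phix = phix, phim = phim,
                   y = NA_real_, valid = TRUE)
  class(ms) <- c("measurement_set", "data.frame")
  ms
}

#' Form normalized Born ratios
#'
#' Divides each emission amplitude by the excitation amplitude of the same
#' source-detector pair, cancelling channel-wise multiplicative systematics
#' (coupling loss, detector gain, mirror loss). Channels with non-positive
#' excitation are marked invalid.
#'
#' @param ms A [measurement_set()].
#' @return The measurement set with `y = phim / phix` populated on valid
#'   channels.
#' @export
born_ratio <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  bad <- !is.finite(ms$phix) | ms$phix <= 0
  ms$valid <- ms$valid & !bad
  if (!any(ms$valid)) stop("all channels invalid: no positive excitation amplitudes")
  ms$y <- ifelse(ms$valid, ms$phim / ms$phix, NA_real_)
  ms
}

#' Channel selection by amplitude standard deviation
#'
#' Keeps a channel iff both its emission and excitation amplitudes exceed
#' `factor` times the standard deviation of all channels' amplitudes at the
#' respective wavelength (the selection rule of the sparse-camera regime).
#' The sample standard deviation (`stats::sd`) is used.
#'
#' @param ms A `measurement_set`.
#' @param factor Multiplier on the standard deviation (default 0.8).
#' @return Logical validity mask (also stored in the returned set's `valid`
#'   column when assigned by the caller); returned as the updated
#'   `measurement_set`.
#' @export
select_channels_std <- function(ms, factor = 0.8) {
  stopifnot(inherits(ms, "measurement_set"))
  if (nrow(ms) < 2) stop("need at least 2 channels for a standard deviation")
  sd_m <- stats::sd(ms$phim)
  sd_x <- stats::sd(ms$phix)
  keep <- ms$phim > factor * sd_m & ms$phix > factor * sd_x
  ms$valid <- ms$valid & keep
  ms
}

#' Channel selection by percentage of a reference maximum
#'
#' Keeps a channel iff `phim > pct_m * ref_max_m` and
#' `phix > pct_x * ref_max_x`. By default the reference maxima are the
#' dataset maxima of the respective amplitude vectors ("expected max" is
#' otherwise undefined for synthetic data; a camera full-scale value may be
#' supplied instead).
#'
#' @param ms A `measurement_set`.
#' @param pct_m,pct_x Fractional thresholds (defaults 0.18 and 0.01).
#' @param ref_max_m,ref_max_x Reference maxima; default `max(phim)`,
#'   `max(phix)`. Must be positive.
#' @return The updated `measurement_set`.
#' @export
select_channels_percent <- function(ms, pct_m = 0.18, pct_x = 0.01,
                                    ref_max_m = NULL, ref_max_x = NULL) {
  stopifnot(inherits(ms, "measurement_set"))
  if (is.null(ref_max_m)) ref_max_m <- max(ms$phim)
  if (is.null(ref_max_x)) ref_max_x <- max(ms$phix)
  if (!is.finite(ref_max_m) || ref_max_m <= 0 ||
      !is.finite(ref_max_x) || ref_max_x <= 0)
    stop("reference maxima must be positive")
  keep <- ms$phim > pct_m * ref_max_m & ms$phix > pct_x * ref_max_x
  ms$valid <- ms$valid & keep
  ms
}

#' Tikhonov-regularized least-squares solve
#'
#' Returns the minimizer of `||y - J g||^2 + alpha ||g||^2`, i.e.
#' `(J'J + alpha I)^{-1} J' y`. For the typical underdetermined case
#' (`M <= N`) the equivalent dual form `J'(JJ' + alpha I)^{-1} y` is solved
#' by Cholesky on the small M x M system; otherwise the normal equations are
#' used. With `alpha = 0` the system must have full row (resp. column) rank.
#' The relative residual of the normal equations is checked against `1e-8`.
#'
#' @param J Dense matrix M x N (rows = selected channels).
#' @param y Length-M data vector (Born ratios).
#' @param alpha Regularization parameter, >= 0.
#' @return Length-N solution vector with attribute `normal_residual`.
#' @export
tikhonov_solve <- function(J, y, alpha) {
  J <- as.matrix(J)
  stopifnot(length(y) == nrow(J), is.numeric(alpha), length(alpha) == 1L,
            alpha >= 0)
  M <- nrow(J); N <- ncol(J)
  sol <- tryCatch({
    if (M <= N) {
      G <- tcrossprod(J)            # J J'
      diag(G) <- diag(G) + alpha
      R <- chol(G)
      drop(crossprod(J, backsolve(R, forwardsolve(t(R), y))))
    } else {
      G <- crossprod(J)             # J' J
      diag(G) <- diag(G) + alpha
      R <- chol(G)
      drop(backsolve(R, forwardsolve(t(R), crossprod(J, y))))
    }
  }, error = function(e) {
    if (alpha == 0)
      stop("alpha = 0 with a rank-deficient Jacobian: regularization required")
    # fall back to SVD filter factors for poor conditioning
    sv <- svd(J)
    drop(sv$v %*% ((sv$d / (sv$d^2 + alpha)) * crossprod(sv$u, y)))
  })
  jty <- drop(crossprod(J, y))
  resid <- jty - (drop(crossprod(J, J %*% sol)) + alpha * sol)
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(jty^2)), .Machine$double.eps)
  if (is.finite(rel) && rel > 1e-8 && alpha > 0) {
    sv <- svd(J)
    sol <- drop(sv$v %*% ((sv$d / (sv$d^2 + alpha)) * crossprod(sv$u, y)))
    resid <- jty - (drop(crossprod(J, J %*% sol)) + alpha * sol)
    rel <- sqrt(sum(resid^2)) / max(sqrt(sum(jty^2)), .Machine$double.eps)
  }
  attr(sol, "normal_residual") <- rel
  sol
}

#' Reconstruction configuration
#'
#' @param alpha Tikhonov regularization parameter (100 for the dense
#'   simulated-layout regime; 1 for the sparse camera regime).
#' @param props Assumed background [optical_props()] used to build the
#'   Jacobian (deliberately allowed to mismatch the truth).
#' @param selection Channel-selection policy: `"none"`, `"std"` (0.8 x sd
#'   rule), or `"percent"` (18% / 1% rule).
#' @param selection_args List of extra arguments for the selection function.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(alpha, props, selection = c("none", "std", "percent"),
                         selection_args = list()) {
  selection <- match.arg(selection)
  stopifnot(alpha >= 0, inherits(props, "optical_props"))
  structure(list(alpha = alpha, props = props, selection = selection,
                 selection_args = selection_args),
            class = "recon_config")
}

apply_selection <- function(ms, config) {
  switch(config$selection,
         none = ms,
         std = do.call(select_channels_std, c(list(ms), config$selection_args)),
         percent = do.call(select_channels_percent,
                           c(list(ms), config$selection_args)))
}

#' Reconstruction volume container
#' @param values Array on the grid (signed, arbitrary units).
#' @param grid The `voxel_grid`.
#' @param normalized Logical: has the volume been divided by its masked
#'   standard deviation?
#' @return Object of class `recon_volume`.
#' @export
recon_volume <- function(values, grid, normalized = FALSE) {
  stopifnot(all(dim(values) == grid$dims))
  structure(list(values = values, grid = grid, normalized = normalized),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("Reconstruction volume %dx%dx%d (%s), range [%.3g, %.3g]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              if (x$normalized) "std-normalized" else "raw",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Classic (first-step) normalized-Born reconstruction
#'
#' Builds the Jacobian under the configured (assumed, possibly mismatched)
#' optical properties, applies channel selection, solves the Tikhonov
#' problem on the valid channels, and maps the solution onto the grid
#' (zeros outside the cylinder mask).
#'
#' @param ms A `measurement_set` with Born ratios formed (or amplitudes, in
#'   which case [born_ratio()] is applied).
#' @param layout The `optode_layout` (channels must match the measurement
#'   set).
#' @param grid The reconstruction `voxel_grid`.
#' @param config A [recon_config()].
#' @param jacobian Optional precomputed `born_jacobian` for `layout`/`grid`/
#'   `config$props` (built once and reused across many cases).
#' @return A raw [recon_volume()].
#' @export
classic_reconstruct <- function(ms, layout, grid, config, jacobian = NULL) {
  stopifnot(inherits(config, "recon_config"))
  if (all(is.na(ms$y))) ms <- born_ratio(ms)
  ms <- apply_selection(ms, config)
  keep <- which(ms$valid & is.finite(ms$y))
  if (is.null(jacobian)) jacobian <- build_jacobian(layout, grid, config$props)
  vol <- array(0, grid$dims)
  if (length(keep) > 0) {
    g_hat <- tikhonov_solve(jacobian$J[keep, , drop = FALSE], ms$y[keep],
                            config$alpha)
    vol[which(grid$mask)] <- g_hat
  }
  recon_volume(vol, grid, normalized = FALSE)
}

#' Precompute a linear reconstruction operator
#'
#' For repeated reconstructions with a fixed Jacobian, selection-free policy
#' and fixed `alpha`, precomputes `J'(JJ' + alpha I)^{-1}` so each case is a
#' single matrix-vector product.
#'
#' @param jacobian A `born_jacobian`.
#' @param alpha Regularization parameter.
#' @param rows Optional row subset (channel indices) to use.
#' @return Function `f(y)` mapping a ratio vector (length = rows used) to the
#'   masked-voxel solution vector.
#' @export
recon_operator <- function(jacobian, alpha, rows = NULL) {
  J <- jacobian$J
  if (!is.null(rows)) J <- J[rows, , drop = FALSE]
  G <- tcrossprod(J)
  diag(G) <- diag(G) + alpha
  R <- chol(G)
  force(J); force(R)
  function(y) drop(crossprod(J, backsolve(R, forwardsolve(t(R), y))))
}

#' Write a measurement set to CSV
#' @param ms A `measurement_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}
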