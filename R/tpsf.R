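#' @keywords internal
c_mm_per_ns <- 299.792458   # vacuum speed of light

#' Condition a raw trace into an instrument response function
#'
#' Smooths the raw temporal trace with a moving-average window (default
#' 0.5 ns), subtracts the pre-pulse baseline (mean of the first
#' `baseline_frac` of samples), and normalizes the peak to 1.
#'
#' @param t Time vector (ns), uniform step, strictly increasing.
#' @param amplitude Raw amplitudes (arbitrary units).
#' @param window Moving-average window length in ns (default 0.5); rounded
#'   to the nearest odd sample count, minimum 1.
#' @param baseline_frac Fraction of leading samples defining the pre-pulse
#'   baseline (default 0.1).
#' @return Object of class `irf`: `t`, `h` (max 1, baseline 0).
#' @export
estimate_irf <- function(t, amplitude, window = 0.5, baseline_frac = 0.1) {
  stopifnot(length(t) == length(amplitude), length(t) >= 2,
            all(diff(t) > 0))
  dt <- t[2] - t[1]
  w <- max(1L, round(window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > length(t)) stop("trace shorter than the smoothing window")
  sm <- if (w == 1L) amplitude else {
    as.numeric(stats::filter(amplitude, rep(1 / w, w), sides = 2))
  }
  # moving average leaves NAs at the ends; pad with partial-window means
  if (anyNA(sm)) {
    half <- (w - 1L) %/% 2L
    n <- length(sm)
    for (i in which(is.na(sm))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] <- mean(amplitude[lo:hi])
    }
  }
  nb <- max(1L, floor(baseline_frac * length(sm)))
  sm <- sm - mean(sm[seq_len(nb)])
  pk <- max(sm)
  if (pk <= 0) stop("trace has no positive peak after baseline removal")
  structure(list(t = t, h = sm / pk), class = "irf")
}

#' Analytical semi-infinite-medium TPSF
#'
#' Time-resolved diffuse reflectance of a homogeneous semi-infinite medium
#' for a pencil beam, modeled as an isotropic point source buried at
#' `z0 = 1/mus'` with the extrapolated-boundary image source at
#' `-(z0 + 2 zb)`, `zb = 2 A D`:
#'
#' `R(rho, t) = (4 pi D v)^(-3/2) t^(-5/2) / 2 * exp(-mua v t - rho^2/(4 D v t))
#'   * ( z0 exp(-z0^2/(4 D v t)) + (z0 + 2 zb) exp(-(z0+2zb)^2/(4 D v t)) )`
#'
#' with `v = c/n` the speed of light in the medium and the
#' absorption-independent diffusion coefficient `D = 1/(3 mus')` (so that
#' absorption enters only through the exact factor `exp(-mua v t)`).
#' A zero-boundary variant (single image at `-z0`, `zb = 0`) is available.
#'
#' @param mua Absorption coefficient (mm^-1), > 0.
#' @param musp Reduced scattering coefficient (mm^-1), > 0.
#' @param rho Source-detector distance on the surface (mm), > 0.
#' @param t Time vector (ns), all > 0.
#' @param n_refr Refractive index (default 1.33).
#' @param boundary `"extrapolated"` (default) or `"zero"`.
#' @return Amplitude vector (mm^-2 ns^-1 scale; only relative shape is used
#'   by the fitter).
#' @export
semi_infinite_tpsf <- function(mua, musp, rho, t, n_refr = 1.33,
                               boundary = c("extrapolated", "zero")) {
  boundary <- match.arg(boundary)
  if (!all(is.finite(c(mua, musp, rho))) || mua <= 0 || musp <= 0 || rho <= 0)
    stop("mua, musp and rho must be positive")
  if (any(t <= 0)) stop("time points must be positive")
  v <- c_mm_per_ns / n_refr
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  zb <- if (boundary == "extrapolated") 2 * robin_constant(n_refr) * D else 0
  z1 <- z0 + 2 * zb
  q <- 4 * D * v * t
  0.5 * (4 * pi * D * v)^(-3 / 2) * t^(-5 / 2) *
    exp(-mua * v * t - rho^2 / q) *
    (z0 * exp(-z0^2 / q) + z1 * exp(-z1^2 / q))
}

#' Extract TPSF features: peak amplitude and mean time of flight
#'
#' `Ipeak` is the average of the five largest amplitudes; the mean time of
#' flight is the amplitude-weighted mean `sum(t * I) / sum(I)`.
#'
#' @param t Time vector (ns).
#' @param amplitude Amplitudes (>= 5 samples, positive total intensity).
#' @return List `ipeak`, `tmean` (ns).
#' @export
extract_features <- function(t, amplitude) {
  stopifnot(length(t) == length(amplitude))
  if (length(amplitude) < 5) stop("need at least 5 samples for the peak average")
  s <- sum(amplitude)
  if (!is.finite(s) || s <= 0) stop("non-positive total intensity")
  ipeak <- mean(sort(amplitude, decreasing = TRUE)[1:5])
  list(ipeak = ipeak, tmean = sum(t * amplitude) / s)
}

# discrete linear convolution of the IRF with a model curve; returns the
# full-length product with its time axis (t_model[1] + t_irf[1] + k dt)
convolve_full <- function(h, x, dt, t0) {
  n <- length(h) + length(x) - 1L
  nfft <- 2^ceiling(log2(n))
  z <- Re(stats::fft(stats::fft(c(h, numeric(nfft - length(h)))) *
                       stats::fft(c(x, numeric(nfft - length(x)))),
                     inverse = TRUE)) / nfft
  list(t = t0 + (seq_len(n) - 1L) * dt, y = z[seq_len(n)] * dt)
}

#' Model features: IRF-convolved TPSF peak and mean time
#'
#' Convolves the instrument response with the analytical TPSF (discrete
#' linear convolution on the shared time step) and extracts the same two
#' features as [extract_features()].
#'
#' @param mua,musp Candidate optical properties (mm^-1).
#' @param rho Source-detector distance (mm).
#' @param irf An [estimate_irf()] object.
#' @param t Model time grid (ns); must share the IRF's step.
#' @param ... Passed to [semi_infinite_tpsf()].
#' @return List `ipeak`, `tmean` (ns, on the convolved time axis).
#' @export
model_features <- function(mua, musp, rho, irf, t, ...) {
  dt <- t[2] - t[1]
  dt_h <- irf$t[2] - irf$t[1]
  if (abs(dt - dt_h) > 1e-9 * dt) stop("IRF and model time grids must share the step")
  tpsf <- semi_infinite_tpsf(mua, musp, rho, t, ...)
  cv <- convolve_full(irf$h, tpsf, dt, t[1] + irf$t[1])
  extract_features(cv$t, cv$y)
}

#' Precompute the model feature table over a parameter grid
#'
#' For every `(mua, mus')` grid point and every distance, computes the
#' IRF-convolved TPSF features. This is the expensive part of the grid
#' search and is reusable across fits sharing the same IRF and grids
#' (FFT-based convolution, batched over the absorption grid).
#'
#' @param irf An [estimate_irf()] object.
#' @param distances Source-detector distances (mm).
#' @param mua_grid,musp_grid Parameter grids (mm^-1).
#' @param t Model time grid (ns; default 0.01-10 ns at 10 ps).
#' @param n_refr,boundary Passed to [semi_infinite_tpsf()].
#' @return Object of class `tpsf_feature_table`: arrays `tmean` and
#'   `log_ipeak` of dim `(n_mua, n_musp, n_dist)` plus the grids.
#' @export
tpsf_feature_table <- function(irf, distances,
                               mua_grid = seq(1e-5, 1e-3, by = 1e-5),
                               musp_grid = seq(0.02, 0.2, by = 0.001),
                               t = seq(0.01, 10, by = 0.01),
                               n_refr = 1.33, boundary = "extrapolated") {
  dt <- t[2] - t[1]
  dt_h <- irf$t[2] - irf$t[1]
  if (abs(dt - dt_h) > 1e-9 * dt) stop("IRF and model time grids must share the step")
  v <- c_mm_per_ns / n_refr
  nm <- length(mua_grid); ns <- length(musp_grid); nd <- length(distances)
  n <- length(irf$h) + length(t) - 1L
  nfft <- 2^ceiling(log2(n))
  Hf <- stats::fft(c(irf$h, numeric(nfft - length(irf$h))))
  tconv <- t[1] + irf$t[1] + (seq_len(n) - 1L) * dt
  decay <- exp(-outer(v * t, mua_grid))          # nt x nm
  tm <- array(NA_real_, c(nm, ns, nd))
  ip <- array(NA_real_, c(nm, ns, nd))
  pad <- matrix(0, nfft - length(t), nm)
  for (d in seq_len(nd)) {
    for (s in seq_len(ns)) {
      base <- semi_infinite_tpsf(1e-12, musp_grid[s], distances[d], t,
                                 n_refr, boundary)
      A <- base * decay                           # nt x nm, mua columns
      Z <- Re(stats::mvfft(stats::mvfft(rbind(A, pad)) * Hf,
                           inverse = TRUE)) / nfft
      Z <- Z[seq_len(n), , drop = FALSE] * dt
      tm[, s, d] <- colSums(tconv * Z) / colSums(Z)
      ip[, s, d] <- log(apply(Z, 2, function(col)
        mean(sort(col, decreasing = TRUE)[1:5])))
    }
  }
  structure(list(tmean = tm, log_ipeak = ip, mua_grid = mua_grid,
                 musp_grid = musp_grid, distances = distances,
                 boundary = boundary, n_refr = n_refr, t = t),
            class = "tpsf_feature_table")
}

#' Weighted grid search for background optical properties
#'
#' Minimizes, over the `(mua, mus')` grid, the weighted sum over distances
#' `i = 2..n` of
#' `weight * ((tmean_i - tmean_1) - (tmean'_i - tmean'_1))^2 +
#'  (log(Ipeak_i/Ipeak_1) - log(Ipeak'_i/Ipeak'_1))^2`,
#' i.e. only the relative flight times and relative log amplitudes with
#' respect to the first distance matter. Ties are broken deterministically
#' toward the smallest `mua`, then the smallest `mus'`.
#'
#' @param features Measured features: list with vectors `ipeak` and `tmean`
#'   (one entry per distance, same order as the table's distances).
#' @param table A [tpsf_feature_table()], or an [estimate_irf()] object (in
#'   which case the table is computed here with the default grids).
#' @param weight Weight on the flight-time term (default 100).
#' @param distances,mua_grid,musp_grid,t Used only when `table` is an IRF.
#' @return Object of class `tpsf_fit`: `mua`, `musp` (mm^-1), `loss`
#'   (matrix n_mua x n_musp), `argmin` (indices), grids.
#' @export
grid_search_fit <- function(features, table, weight = 100,
                            distances = NULL,
                            mua_grid = seq(1e-5, 1e-3, by = 1e-5),
                            musp_grid = seq(0.02, 0.2, by = 0.001),
                            t = seq(0.01, 10, by = 0.01)) {
  if (inherits(table, "irf")) {
    if (is.null(distances)) stop("distances required when passing a raw IRF")
    table <- tpsf_feature_table(table, distances, mua_grid, musp_grid, t)
  }
  stopifnot(inherits(table, "tpsf_feature_table"))
  nd <- length(table$distances)
  if (nd < 2) stop("need at least 2 distances (terms are relative to the first)")
  ip <- features$ipeak; tmn <- features$tmean
  stopifnot(length(ip) == nd, length(tmn) == nd)
  if (any(!is.finite(ip)) || any(ip <= 0)) stop("degenerate features: non-positive peaks")
  nm <- length(table$mua_grid); ns <- length(table$musp_grid)
  loss <- matrix(0, nm, ns)
  for (i in 2:nd) {
    dt_meas <- tmn[i] - tmn[1]
    dl_meas <- log(ip[i] / ip[1])
    dt_mod <- table$tmean[, , i] - table$tmean[, , 1]
    dl_mod <- table$log_ipeak[, , i] - table$log_ipeak[, , 1]
    loss <- loss + weight * (dt_meas - dt_mod)^2 + (dl_meas - dl_mod)^2
  }
  k <- which.min(loss)   # column-major: mua varies fastest within each musp
  # enforce the documented tie-break: smallest mua, then smallest musp
  ties <- which(loss == loss[k], arr.ind = TRUE)
  ties <- ties[order(ties[, 1], ties[, 2]), , drop = FALSE]
  im <- ties[1, 1]; is_ <- ties[1, 2]
  structure(list(mua = table$mua_grid[im], musp = table$musp_grid[is_],
                 loss = loss, argmin = c(mua = im, musp = is_),
                 mua_grid = table$mua_grid, musp_grid = table$musp_grid),
            class = "tpsf_fit")
}

#' @export
print.tpsf_fit <- function(x, ...) {
  cat(sprintf("TPSF fit: mua = %.3g mm^-1, mus' = %.3g mm^-1 (loss %.3g)\n",
              x$mua, x$musp, x$loss[x$argmin[1], x$argmin[2]]))
  invisible(x)
}

#' Synthetic Gaussian-pulse IRF
#'
#' Convenience generator for tests and demonstrations: a Gaussian pulse
#' centered at `t0` with standard deviation `sigma`, passed through
#' [estimate_irf()] conditioning.
#'
#' @param t Time grid (ns).
#' @param t0 Pulse center (ns).
#' @param sigma Pulse width (ns).
#' @param window Smoothing window passed to [estimate_irf()].
#' @param baseline_frac Pre-pulse baseline fraction; the default 0.03 keeps
#'   the baseline segment ahead of the pulse for the default `t0`.
#' @return An `irf` object.
#' @export
gaussian_irf <- function(t = seq(0.01, 10, by = 0.01), t0 = 1, sigma = 0.2,
                         window = 0.5, baseline_frac = 0.03) {
  estimate_irf(t, exp(-(t - t0)^2 / (2 * sigma^2)), window = window,
               baseline_frac = baseline_frac)
}
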