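#' Simulation case configuration
#'
#' Describes one data-generation regime: nominal background optical
#' properties with fractional jitter, inclusion count/shape/size/yield
#' ranges, and the noise model. All random draws are uniform over their
#' ranges.
#'
#' Two presets reproduce the study regimes:
#' * [sim_config_table1()] — dense simulated layout: `mua = 0.0089 +- 10%`,
#'   `mus' = 1.314 +- 10%` (mm^-1, equal at both wavelengths), 1-2
#'   non-overlapping spheres of radius 7-15 mm, yield `gamma` in
#'   `4e-4 .. 4e-2` mm^-1, Gaussian noise added to the Born ratios with a
#'   per-case standard deviation drawn from 0-2% of the maximum ratio.
#' * [sim_config_table2()] — sparse camera layout: `mua = 0.0005 +- 30%`,
#'   `mus' = 0.1 +- 30%`, 1-3 non-overlapping z-aligned cylinders of radius
#'   5-10 mm and height 10-30 mm, same `gamma` range, independent 0-1%
#'   Gaussian noise on the excitation and emission amplitudes.
#'
#' @param mua_nominal,mua_frac Nominal absorption (mm^-1) and fractional
#'   half-range (e.g. 0.10 for +-10%).
#' @param musp_nominal,musp_frac Nominal reduced scattering and half-range.
#' @param n_inclusions Integer range `c(min, max)` of inclusion count.
#' @param shape `"sphere"` or `"cylinder"` (z-aligned).
#' @param radius_range Inclusion radius range (mm).
#' @param height_range Inclusion height range (mm; cylinders only).
#' @param gamma_range Yield range (mm^-1).
#' @param noise `"ratio"` (on Born ratios) or `"per_wavelength"`.
#' @param noise_max For `"ratio"`: maximum per-case noise level (fraction of
#'   max |ratio|).
#' @param noise_max_x,noise_max_m For `"per_wavelength"`: maximum levels for
#'   the two amplitude vectors.
#' @param margin_mm Containment margin from the vessel wall/ends (mm),
#'   about one full-resolution voxel.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(mua_nominal, mua_frac, musp_nominal, musp_frac,
                       n_inclusions, shape = c("sphere", "cylinder"),
                       radius_range, height_range = NULL,
                       gamma_range = c(4e-4, 4e-2),
                       noise = c("ratio", "per_wavelength"),
                       noise_max = 0.02, noise_max_x = 0.01,
                       noise_max_m = 0.01, margin_mm = 3) {
  shape <- match.arg(shape)
  noise <- match.arg(noise)
  if (shape == "cylinder" && is.null(height_range))
    stop("cylindrical inclusions need a height_range")
  stopifnot(mua_nominal > 0, musp_nominal > 0, mua_frac >= 0, musp_frac >= 0,
            diff(radius_range) >= 0, diff(gamma_range) >= 0,
            n_inclusions[1] >= 1, n_inclusions[2] >= n_inclusions[1],
            noise_max >= 0, noise_max_x >= 0, noise_max_m >= 0)
  structure(list(mua_nominal = mua_nominal, mua_frac = mua_frac,
                 musp_nominal = musp_nominal, musp_frac = musp_frac,
                 n_inclusions = as.integer(n_inclusions), shape = shape,
                 radius_range = radius_range, height_range = height_range,
                 gamma_range = gamma_range, noise = noise,
                 noise_max = noise_max, noise_max_x = noise_max_x,
                 noise_max_m = noise_max_m, margin_mm = margin_mm),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
sim_config_table1 <- function() {
  sim_config(0.0089, 0.10, 1.314, 0.10, c(1L, 2L), "sphere",
             radius_range = c(7, 15), gamma_range = c(4e-4, 4e-2),
             noise = "ratio", noise_max = 0.02)
}

#' @rdname sim_config
#' @export
sim_config_table2 <- function() {
  sim_config(0.0005, 0.30, 0.1, 0.30, c(1L, 3L), "cylinder",
             radius_range = c(5, 10), height_range = c(10, 30),
             gamma_range = c(4e-4, 4e-2),
             noise = "per_wavelength", noise_max_x = 0.01, noise_max_m = 0.01)
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

inclusions_overlap <- function(a, b, shape) {
  if (shape == "sphere") {
    d <- sqrt(sum((a$center - b$center)^2))
    d <= a$radius + b$radius
  } else {
    dr <- sqrt(sum((a$center[1:2] - b$center[1:2])^2))
    z_overlap <- abs(a$center[3] - b$center[3]) <= (a$height + b$height) / 2
    dr <= a$radius + b$radius && z_overlap
  }
}

sample_inclusion <- function(config, domain) {
  R <- runif1(config$radius_range[1], config$radius_range[2])
  H <- if (config$shape == "cylinder")
    runif1(config$height_range[1], config$height_range[2]) else NA_real_
  m <- config$margin_mm
  r_max <- domain$radius - R - m
  if (r_max <= 0) stop("inclusion radius too large for the domain (containment unsatisfiable)")
  half_h <- if (config$shape == "sphere") R else H / 2
  z_lo <- half_h + m; z_hi <- domain$height - half_h - m
  if (z_lo >= z_hi) stop("inclusion height too large for the domain (containment unsatisfiable)")
  repeat {                 # uniform over the allowed disc by rejection
    x <- runif1(-r_max, r_max); y <- runif1(-r_max, r_max)
    if (x^2 + y^2 <= r_max^2) break
  }
  list(center = c(x, y, runif1(z_lo, z_hi)), radius = R, height = H,
       gamma = runif1(config$gamma_range[1], config$gamma_range[2]))
}

#' Draw one randomized phantom case
#'
#' Samples background optical properties (equal at both wavelengths, as in
#' the data-generation regimes), the inclusion set (rejection-resampled
#' until all inclusions are fully contained with the configured margin and
#' pairwise non-overlapping), and per-inclusion yields. Uses the current RNG
#' state; seed with `set.seed()` for reproducibility.
#'
#' @param config A [sim_config()].
#' @param domain A [cyl_domain()].
#' @param max_reject Maximum placement rejections before erroring (default
#'   1000).
#' @return Object of class `sim_case`: `props` ([optical_props()]),
#'   `inclusions` (list of `center`, `radius`, `height`, `gamma`), `shape`,
#'   and `noise_level` fields filled later by the noise stage.
#' @export
sample_case <- function(config, domain, max_reject = 1000L) {
  stopifnot(inherits(config, "sim_config"), inherits(domain, "cyl_domain"))
  mua <- runif1(config$mua_nominal * (1 - config$mua_frac),
                config$mua_nominal * (1 + config$mua_frac))
  musp <- runif1(config$musp_nominal * (1 - config$musp_frac),
                 config$musp_nominal * (1 + config$musp_frac))
  props <- optical_props(mua, mua, musp, musp)
  k <- if (config$n_inclusions[1] == config$n_inclusions[2])
    config$n_inclusions[1]
  else sample(config$n_inclusions[1]:config$n_inclusions[2], 1)
  inclusions <- list()
  rejections <- 0L
  while (length(inclusions) < k) {
    cand <- sample_inclusion(config, domain)
    ok <- all(vapply(inclusions, function(ex)
      !inclusions_overlap(cand, ex, config$shape), logical(1)))
    if (ok) inclusions[[length(inclusions) + 1L]] <- cand
    else {
      rejections <- rejections + 1L
      if (rejections > max_reject)
        stop("could not place non-overlapping inclusions within ", max_reject,
             " rejections")
    }
  }
  structure(list(props = props, inclusions = inclusions,
                 shape = config$shape, config = config,
                 noise_level = NULL),
            class = "sim_case")
}

#' Rasterize a case's inclusions onto a grid
#'
#' Voxel yield equals the inclusion's `gamma` wherever the voxel center lies
#' inside an inclusion (later inclusions overwrite earlier ones; cases from
#' [sample_case()] never overlap), zero elsewhere.
#'
#' @param case A `sim_case` (or a bare list of inclusions with a `shape`
#'   attribute).
#' @param grid A `voxel_grid`.
#' @return Object of class `fluor_map`: `values` (array, mm^-1), `grid`.
#' @export
rasterize_inclusions <- function(case, grid) {
  vol <- array(0, grid$dims)
  cen <- voxel_centers(grid)
  for (inc in case$inclusions) {
    if (case$shape == "sphere") {
      inside <- (cen[, 1] - inc$center[1])^2 + (cen[, 2] - inc$center[2])^2 +
        (cen[, 3] - inc$center[3])^2 <= inc$radius^2
    } else {
      inside <- (cen[, 1] - inc$center[1])^2 + (cen[, 2] - inc$center[2])^2 <=
        inc$radius^2 &
        abs(cen[, 3] - inc$center[3]) <= inc$height / 2
    }
    vol[inside] <- inc$gamma
  }
  vol[!grid$mask] <- 0
  structure(list(values = vol, grid = grid), class = "fluor_map")
}

#' Simulate noiseless boundary measurements for a case
#'
#' Excitation amplitudes come from diffusion solves with the case's true
#' properties; emission amplitudes from emission solves driven by
#' `Phi_x * gamma`. One sparse factorization is shared by all sources (the
#' regimes use equal properties at both wavelengths, so the excitation and
#' emission operators coincide).
#'
#' @param case A `sim_case`.
#' @param layout An `optode_layout` with channels formed.
#' @param grid The simulation `voxel_grid`.
#' @param gamma Optional precomputed [rasterize_inclusions()] map.
#' @return A noiseless [measurement_set()] with Born ratios formed.
#' @export
simulate_measurements <- function(case, layout, grid, gamma = NULL) {
  if (nrow(layout$channels) == 0) stop("layout has no channels")
  if (is.null(gamma)) gamma <- rasterize_inclusions(case, grid)
  sys_x <- assemble_system(grid, case$props, "excitation")
  same_props <- case$props$mua_x == case$props$mua_m &&
    case$props$musp_x == case$props$musp_m
  sys_m <- if (same_props) sys_x else assemble_system(grid, case$props, "emission")

  S <- as.matrix(layout$sources[, c("x", "y", "z")])
  D <- as.matrix(layout$detectors[, c("x", "y", "z")])
  phix <- batch_fields(sys_x, S)
  # emission fields: solve once per source with source term Phi_x * gamma * dV
  gmask <- gamma$values[sys_m$mask_idx]
  Bm <- phix * gmask * sys_m$dV
  phim <- solve_system(sys_m, Bm)

  det_tw <- lapply(seq_len(nrow(D)), function(d) {
    ip <- optode_interior_point(D[d, ], sys_x$musp)
    trilinear_weights(sys_x, ip)
  })
  ch <- layout$channels
  phix_amp <- vapply(seq_len(nrow(ch)), function(i) {
    tw <- det_tw[[ch$detector[i]]]
    sum(phix[tw$rows, ch$source[i]] * tw$w)
  }, numeric(1))
  phim_amp <- vapply(seq_len(nrow(ch)), function(i) {
    tw <- det_tw[[ch$detector[i]]]
    sum(phim[tw$rows, ch$source[i]] * tw$w)
  }, numeric(1))
  born_ratio(measurement_set(ch, phix_amp, phim_amp))
}

#' Add Gaussian noise to the Born ratios
#'
#' `y <- y + e` with `e ~ N(0, (level * max|y|)^2)` i.i.d. per channel —
#' the dense-layout noise regime, where the level is drawn per case from
#' `[0, noise_max]` by the dataset generator.
#'
#' @param ms A `measurement_set` with ratios formed.
#' @param level Noise standard deviation as a fraction of the maximum
#'   absolute ratio.
#' @return The noisy measurement set (`noise_level` attribute records the
#'   level).
#' @export
add_ratio_noise <- function(ms, level) {
  stopifnot(level >= 0)
  if (level > 0) {
    s <- level * max(abs(ms$y), na.rm = TRUE)
    ok <- ms$valid & is.finite(ms$y)
    ms$y[ok] <- ms$y[ok] + stats::rnorm(sum(ok), 0, s)
  }
  attr(ms, "noise_level") <- level
  attr(ms, "noise_regime") <- "ratio"
  ms
}

#' Add independent Gaussian noise to the two wavelengths
#'
#' Adds zero-mean Gaussian noise to the excitation and emission amplitude
#' vectors with standard deviations `level_x * max(phix)` and
#' `level_m * max(phim)` respectively, then recomputes the Born ratios —
#' the sparse camera-layout noise regime.
#'
#' @param ms A `measurement_set`.
#' @param level_x,level_m Fractional noise levels.
#' @return The noisy measurement set with ratios recomputed.
#' @export
add_per_wavelength_noise <- function(ms, level_x, level_m) {
  stopifnot(level_x >= 0, level_m >= 0)
  if (level_x > 0)
    ms$phix <- ms$phix + stats::rnorm(nrow(ms), 0, level_x * max(ms$phix))
  if (level_m > 0)
    ms$phim <- ms$phim + stats::rnorm(nrow(ms), 0, level_m * max(ms$phim))
  ms <- born_ratio(ms)
  attr(ms, "noise_level") <- c(x = level_x, m = level_m)
  attr(ms, "noise_regime") <- "per_wavelength"
  ms
}

# deterministic per-case seed from the master seed (documented counter
# scheme; kept below 2^31)
case_seed <- function(master_seed, index) {
  (as.integer(master_seed) %% 1000003L) * 2048L + as.integer(index) %% 2048L
}

#' Generate a paired (classic reconstruction, ground truth) dataset
#'
#' Runs the full per-case chain `sample -> rasterize -> simulate -> noise ->
#' classic reconstruction` under a fixed master seed, with the inversion
#' always using the supplied (mismatched) assumed properties while data are
#' generated with each case's true properties. The Jacobian and
#' reconstruction operator are built once and reused.
#'
#' @param config A [sim_config()].
#' @param domain,grid,layout Geometry: [cyl_domain()], [build_voxel_grid()]
#'   grid, [form_channels()] layout.
#' @param n_total Number of cases.
#' @param split Integer triple `c(train, val, test)` summing to `n_total`.
#' @param recon A [recon_config()] holding the assumed properties, `alpha`
#'   and the channel-selection policy.
#' @param seed Master seed (integer).
#' @param verbose Print progress every 32 cases.
#' @return Object of class `fdot_dataset`: `cases` (list of `truth` array,
#'   `classic` array, `meta`), `split` (factor train/val/test), `manifest`
#'   (parameters and seeds), `grid`.
#' @export
generate_dataset <- function(config, domain, grid, layout, n_total, split,
                             recon, seed, verbose = FALSE) {
  stopifnot(sum(split) == n_total, length(split) == 3L,
            inherits(recon, "recon_config"))
  jac <- build_jacobian(layout, grid, recon$props)
  op_all <- if (recon$selection == "none")
    recon_operator(jac, recon$alpha) else NULL
  mask_lin <- which(grid$mask)

  cases <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(case_seed(seed, i))
    case <- sample_case(config, domain)
    truth <- rasterize_inclusions(case, grid)
    ms <- simulate_measurements(case, layout, grid, gamma = truth)
    if (config$noise == "ratio") {
      lvl <- runif1(0, config$noise_max)
      ms <- add_ratio_noise(ms, lvl)
      noise_rec <- lvl
    } else {
      lx <- runif1(0, config$noise_max_x)
      lm <- runif1(0, config$noise_max_m)
      ms <- add_per_wavelength_noise(ms, lx, lm)
      noise_rec <- c(lx, lm)
    }
    if (!is.null(op_all)) {
      vol <- array(0, grid$dims)
      ok <- ms$valid & is.finite(ms$y)
      if (all(ok)) vol[mask_lin] <- op_all(ms$y)
      else if (any(ok))
        vol[mask_lin] <- tikhonov_solve(jac$J[ok, , drop = FALSE],
                                        ms$y[ok], recon$alpha)
      classic <- recon_volume(vol, grid)
    } else {
      classic <- classic_reconstruct(ms, layout, grid, recon, jacobian = jac)
    }
    cases[[i]] <- list(
      truth = truth$values, classic = classic$values,
      meta = list(seed = case_seed(seed, i),
                  mua = case$props$mua_x, musp = case$props$musp_x,
                  noise = noise_rec,
                  inclusions = case$inclusions, shape = case$shape))
    if (verbose && i %% 32 == 0)
      message(sprintf("generated %d / %d cases", i, n_total))
  }
  split_f <- factor(rep(c("train", "val", "test"), times = split),
                    levels = c("train", "val", "test"))
  manifest <- list(
    n_total = n_total, split = as.integer(split), seed = as.integer(seed),
    regime = config$noise, shape = config$shape,
    mua_nominal = config$mua_nominal, mua_frac = config$mua_frac,
    musp_nominal = config$musp_nominal, musp_frac = config$musp_frac,
    radius_range = config$radius_range, height_range = config$height_range,
    gamma_range = config$gamma_range,
    noise_max = if (config$noise == "ratio") config$noise_max
                else c(config$noise_max_x, config$noise_max_m),
    alpha = recon$alpha, selection = recon$selection,
    assumed_props = list(mua_x = recon$props$mua_x, mua_m = recon$props$mua_m,
                         musp_x = recon$props$musp_x,
                         musp_m = recon$props$musp_m),
    grid_dims = grid$dims, grid_spacing = grid$spacing,
    domain = c(radius = domain$radius, height = domain$height),
    n_sources = nrow(layout$sources), n_detectors = nrow(layout$detectors),
    n_channels = nrow(layout$channels))
  structure(list(cases = cases, split = split_f, manifest = manifest,
                 grid = grid),
            class = "fdot_dataset")
}

#' @export
print.fdot_dataset <- function(x, ...) {
  cat(sprintf("fDOT dataset: %d cases (%s), grid %dx%dx%d\n",
              length(x$cases),
              paste(table(x$split), collapse = "/"),
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Write a dataset manifest as JSON
#' @param dataset An `fdot_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
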