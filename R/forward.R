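#' Background optical properties
#'
#' Holds absorption and reduced scattering at the excitation and emission
#' wavelengths, the refractive index, and the derived diffusion coefficients
#' `kappa = 1 / (3 (mua + mus'))` (mm) and Robin constant `A`.
#'
#' `A` is computed from the internal-reflection parameterization
#' `R_eff = -1.440/n^2 + 0.710/n + 0.668 + 0.0636 n`,
#' `A = (1 + R_eff) / (1 - R_eff)`, the standard diffuse-optics fit for a
#' medium-air interface.
#'
#' @param mua_x,mua_m Absorption coefficients (mm^-1) at the excitation and
#'   emission wavelengths.
#' @param musp_x,musp_m Reduced scattering coefficients (mm^-1).
#' @param n_refr Refractive index of the medium (default 1.33, aqueous).
#' @return An object of class `optical_props` with fields `mua_x`, `mua_m`,
#'   `musp_x`, `musp_m`, `n_refr`, `kappa_x`, `kappa_m`, `A`.
#' @examples
#' optical_props(0.0089, 0.0062, 1.314, 1.274)
#' @export
optical_props <- function(mua_x, mua_m = mua_x, musp_x, musp_m = musp_x,
                          n_refr = 1.33) {
  vals <- c(mua_x, mua_m, musp_x, musp_m, n_refr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all optical coefficients must be positive and finite")
  structure(list(
    mua_x = mua_x, mua_m = mua_m, musp_x = musp_x, musp_m = musp_m,
    n_refr = n_refr,
    kappa_x = 1 / (3 * (mua_x + musp_x)),
    kappa_m = 1 / (3 * (mua_m + musp_m)),
    A = robin_constant(n_refr)
  ), class = "optical_props")
}

#' Robin boundary constant from the refractive index
#'
#' @param n_refr Refractive-index ratio medium/environment.
#' @return The dimensionless constant `A` in the Robin condition
#'   `Phi + 2 A kappa dPhi/dnu = 0`.
#' @export
robin_constant <- function(n_refr) {
  r_eff <- -1.440 / n_refr^2 + 0.710 / n_refr + 0.668 + 0.0636 * n_refr
  (1 + r_eff) / (1 - r_eff)
}

wavelength_props <- function(props, wavelength) {
  wavelength <- match.arg(wavelength, c("excitation", "emission"))
  if (wavelength == "excitation")
    list(mua = props$mua_x, musp = props$musp_x, kappa = props$kappa_x)
  else
    list(mua = props$mua_m, musp = props$musp_m, kappa = props$kappa_m)
}

# 6-connected flood fill over the mask (vectorized frontier BFS);
# TRUE iff the masked voxels form a single connected component.
mask_connected <- function(mask, dims) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  sub <- arrayInd(idx, dims)
  visited <- logical(length(mask))
  frontier <- idx[1]
  visited[frontier] <- TRUE
  offs <- c(1L, -1L, nx, -nx, nx * ny, -(nx * ny))
  while (length(frontier)) {
    f_sub <- arrayInd(frontier, dims)
    nbrs <- integer(0)
    for (a in 1:6) {
      cand <- frontier + offs[a]
      ax <- (a + 1L) %/% 2L        # axis 1,1,2,2,3,3
      step <- if (a %% 2L == 1L) 1L else -1L
      coord <- f_sub[, ax] + step
      ok <- coord >= 1L & coord <= dims[ax]
      nbrs <- c(nbrs, cand[ok])
    }
    nbrs <- unique(nbrs)
    nbrs <- nbrs[mask[nbrs] & !visited[nbrs]]
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  all(visited[idx])
}

#' Assemble the discrete diffusion operator
#'
#' Builds the symmetric positive-definite finite-volume discretization of
#' `-div(kappa grad Phi) + mua Phi` on the masked voxels of a regular grid,
#' with the Robin condition `Phi + 2 A kappa dPhi/dnu = 0` applied on exposed
#' faces (faces between a masked voxel and an unmasked/outside voxel). The
#' operator is in integrated (conservation) form: interior face conductances
#' are `kappa * area / h`, the Robin face term is
#' `area / (2A + h / (2 kappa))` (half-cell resistance in series with the
#' boundary admittance), and the diagonal carries `mua * voxel volume`.
#'
#' @param grid A [build_voxel_grid()] grid with a non-empty, connected mask.
#' @param props An [optical_props()] object.
#' @param wavelength `"excitation"` or `"emission"` — selects which
#'   coefficients to use.
#' @return An object of class `diffusion_system`: sparse operator `A`
#'   (`Matrix::dgCMatrix`, N x N over masked voxels), `grid`, `props`,
#'   `wavelength`, `mask_idx` (linear voxel indices of the rows), `row_of`
#'   (integer array mapping voxel index to row, 0 outside), scalar `kappa`,
#'   `mua`, `musp`, and a cache environment for the factorization.
#' @export
assemble_system <- function(grid, props, wavelength = "excitation") {
  stopifnot(inherits(grid, "voxel_grid"), inherits(props, "optical_props"))
  wp <- wavelength_props(props, wavelength)
  dims <- grid$dims; h <- grid$spacing
  mask <- grid$mask
  mask_idx <- which(mask)
  n <- length(mask_idx)
  if (n == 0L) stop("grid mask is empty")
  if (!mask_connected(mask, dims)) stop("masked voxels are disconnected")
  row_of <- array(0L, dims)
  row_of[mask_idx] <- seq_len(n)

  dV <- prod(h)
  area <- dV / h                      # face areas per axis
  g_int <- wp$kappa * area / h        # interior face conductance per axis
  g_rob <- area / (2 * props$A + h / (2 * wp$kappa))  # Robin face term per axis

  sub <- arrayInd(mask_idx, dims)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_v <- rep(wp$mua * dV, n)
  offs <- c(1L, dims[1], dims[1] * dims[2])
  for (axis in 1:3) {
    for (step in c(1L, -1L)) {
      coord <- sub[, axis] + step
      inb <- coord >= 1L & coord <= dims[axis]
      nb <- mask_idx + step * offs[axis]
      nb_masked <- inb
      nb_masked[inb] <- mask[nb[inb]]
      # interior faces: neighbor masked
      r_i <- row_of[mask_idx[nb_masked]]
      r_j <- row_of[nb[nb_masked]]
      ii <- c(ii, r_i); jj <- c(jj, r_j)
      xx <- c(xx, rep(-g_int[axis], length(r_i)))
      diag_v[r_i] <- diag_v[r_i] + g_int[axis]
      # exposed faces: neighbor outside grid or unmasked -> Robin
      exposed <- !nb_masked
      r_e <- row_of[mask_idx[exposed]]
      diag_v[r_e] <- diag_v[r_e] + g_rob[axis]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_v), dims = c(n, n))
  structure(list(A = A, grid = grid, props = props, wavelength = wavelength,
                 kappa = wp$kappa, mua = wp$mua, musp = wp$musp,
                 mask_idx = mask_idx, row_of = row_of, dV = dV,
                 cache = new.env(parent = emptyenv())),
            class = "diffusion_system")
}

#' @export
print.diffusion_system <- function(x, ...) {
  cat(sprintf("Diffusion system (%s): %d voxels, kappa = %.4g mm, mua = %.4g mm^-1\n",
              x$wavelength, length(x$mask_idx), x$kappa, x$mua))
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems.
cg_solve <- function(A, b, tol = 1e-10, maxit = 5000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iter = 0L, relres = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres < tol) return(list(x = x, iter = it, relres = relres))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iter = maxit, relres = sqrt(sum(r^2)) / bnorm)
}

#' Solve the discrete system for one or more right-hand sides
#'
#' Uses a cached sparse Cholesky factorization (reused across repeated solves
#' with the same operator) or, for large single solves, Jacobi-preconditioned
#' conjugate gradients with relative residual tolerance `tol`.
#'
#' @param system A `diffusion_system`.
#' @param b Numeric vector (length N) or matrix (N x k) of right-hand sides
#'   over masked voxels.
#' @param method `"auto"` (Cholesky up to 2e5 unknowns, else CG), `"chol"`,
#'   or `"cg"`.
#' @param tol Relative residual tolerance for CG (default 1e-10).
#' @return Vector or matrix of solutions, same shape as `b`.
#' @export
solve_system <- function(system, b, method = c("auto", "chol", "cg"),
                         tol = 1e-10) {
  method <- match.arg(method)
  n <- length(system$mask_idx)
  if (method == "auto") method <- if (n <= 2e5) "chol" else "cg"
  if (method == "chol") {
    if (is.null(system$cache$chol))
      system$cache$chol <- Matrix::Cholesky(system$A, LDL = FALSE, perm = TRUE)
    x <- Matrix::solve(system$cache$chol, b)
    x <- as.matrix(x)
    if (is.null(dim(b))) as.numeric(x) else x
  } else {
    if (is.null(dim(b))) {
      res <- cg_solve(system$A, b, tol = tol)
      if (res$relres >= tol)
        warning(sprintf("CG did not converge: relative residual %.3g after %d iterations",
                        res$relres, res$iter))
      res$x
    } else {
      apply(b, 2, function(col) solve_system(system, col, "cg", tol))
    }
  }
}

# Outward surface normal at a lateral-surface point of the cylinder.
lateral_normal <- function(point) {
  r <- sqrt(point[1]^2 + point[2]^2)
  c(point[1] / r, point[2] / r, 0)
}

#' Interior placement point for a surface optode
#'
#' Sources and detectors on the boundary are represented inside the diffusive
#' medium at one transport mean free path, `depth = 1/mus'`, beneath the
#' surface along the inward normal (the standard diffuse-optics convention).
#'
#' @param position Length-3 surface coordinate (mm) on the lateral surface.
#' @param musp Reduced scattering coefficient (mm^-1) used for the depth.
#' @param depth Optional explicit depth (mm), overrides `1/musp`.
#' @return Length-3 interior coordinate.
#' @export
optode_interior_point <- function(position, musp, depth = NULL) {
  if (is.null(depth)) depth <- 1 / musp
  position - depth * lateral_normal(position)
}

# Trilinear interpolation weights over masked voxel centers.
# Returns masked-row indices and renormalized weights; errors if the point
# has no masked corner voxel.
trilinear_weights <- function(system, point) {
  grid <- system$grid
  u <- (point - grid$origin) / grid$spacing - 0.5
  i0 <- floor(u)
  f <- u - i0
  idx <- integer(8); w <- numeric(8); m <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ijk <- i0 + c(dx, dy, dz) + 1   # 1-based
    if (any(ijk < 1) || any(ijk > grid$dims)) next
    lin <- ijk[1] + (ijk[2] - 1) * grid$dims[1] +
      (ijk[3] - 1) * grid$dims[1] * grid$dims[2]
    r <- system$row_of[lin]
    if (r == 0L) next
    wt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    m <- m + 1L
    idx[m] <- r; w[m] <- wt
  }
  if (m == 0L) stop("point has no masked voxel in its interpolation cell")
  idx <- idx[seq_len(m)]; w <- w[seq_len(m)]
  if (sum(w) <= 0) stop("degenerate interpolation weights")
  list(rows = idx, w = w / sum(w))
}

# Distributed point-source right-hand side (total strength `strength`).
point_source_rhs <- function(system, interior_point, strength = 1) {
  tw <- trilinear_weights(system, interior_point)
  b <- numeric(length(system$mask_idx))
  b[tw$rows] <- strength * tw$w
  b
}

fluence_field <- function(system, values_masked, role, source = NULL) {
  v <- array(0, system$grid$dims)
  v[system$mask_idx] <- values_masked
  structure(list(values = v, grid = system$grid,
                 wavelength = system$wavelength, role = role,
                 source = source),
            class = "fluence_field")
}

#' Solve the excitation (or emission) fluence for a point source
#'
#' The source is deposited at the optode's interior point (see
#' [optode_interior_point()]) with trilinear weights over the surrounding
#' masked voxel centers; the same weights are used when fields are read out
#' at optodes, which makes modelled measurements exactly reciprocal.
#'
#' @param system A `diffusion_system`.
#' @param position Surface position of the source (mm).
#' @param strength Total source strength (arbitrary units, default 1).
#' @param depth Optional placement depth (mm), default `1/mus'` of the system.
#' @param ... Passed to [solve_system()].
#' @return A `fluence_field`: `values` (full grid array, zeros outside the
#'   mask), `grid`, `wavelength`, `role = "direct"`.
#' @export
solve_fluence <- function(system, position, strength = 1, depth = NULL, ...) {
  ip <- optode_interior_point(position, system$musp, depth)
  b <- point_source_rhs(system, ip, strength)
  x <- solve_system(system, b, ...)
  fluence_field(system, x, role = "direct", source = position)
}

#' Adjoint (Green's-function) field of a detector
#'
#' Places a unit source at the detector's interior point in the
#' emission-wavelength system; by symmetry of the operator the resulting
#' field evaluated at voxel `j` equals the detector reading of a unit source
#' at `j`.
#'
#' @param system_emission A `diffusion_system` built for the emission
#'   wavelength.
#' @param position Detector surface position (mm).
#' @param depth Optional placement depth (mm).
#' @param ... Passed to [solve_system()].
#' @return A `fluence_field` with `role = "adjoint"`.
#' @export
adjoint_green <- function(system_emission, position, depth = NULL, ...) {
  f <- solve_fluence(system_emission, position, strength = 1, depth = depth, ...)
  f$role <- "adjoint"
  f
}

#' Emission forward solve
#'
#' Solves the emission diffusion equation with volumetric source
#' `Phi_x(r) * gamma(r)`: the discrete right-hand side carries
#' `Phi_x * gamma * dV` per masked voxel.
#'
#' @param phi_x A `fluence_field` (excitation).
#' @param gamma Fluorescence yield volume: array matching the grid, or a
#'   `fluor_map`.
#' @param system_emission Emission-wavelength `diffusion_system` on the same
#'   grid.
#' @param ... Passed to [solve_system()].
#' @return A `fluence_field` of the emitted light.
#' @export
emission_forward <- function(phi_x, gamma, system_emission, ...) {
  if (inherits(gamma, "fluor_map")) gamma <- gamma$values
  stopifnot(all(dim(gamma) == system_emission$grid$dims),
            all(phi_x$grid$dims == system_emission$grid$dims))
  b <- phi_x$values[system_emission$mask_idx] *
    gamma[system_emission$mask_idx] * system_emission$dV
  x <- solve_system(system_emission, b, ...)
  fluence_field(system_emission, x, role = "direct")
}

#' Read a field out at a surface optode
#'
#' Returns the field value at the optode's interior point, interpolated with
#' the same (mask-renormalized trilinear) weights used to deposit sources —
#' the package's documented extraction convention.
#'
#' @param field A `fluence_field`.
#' @param system The `diffusion_system` the field was solved on (provides the
#'   mask and placement depth convention).
#' @param position Optode surface position (mm).
#' @param depth Optional placement depth (mm).
#' @return Scalar amplitude.
#' @export
boundary_measurement <- function(field, system, position, depth = NULL) {
  ip <- optode_interior_point(position, system$musp, depth)
  if (sqrt(ip[1]^2 + ip[2]^2) > system$grid$domain$radius ||
      ip[3] < 0 || ip[3] > system$grid$domain$height)
    stop("optode interior point lies outside the domain")
  tw <- trilinear_weights(system, ip)
  sum(field$values[system$mask_idx[tw$rows]] * tw$w)
}

#' Excitation fields for all sources / adjoint fields for all detectors
#'
#' Convenience batch solvers sharing one factorization.
#' @param system A `diffusion_system`.
#' @param positions Matrix (n x 3) of surface positions.
#' @param role `"direct"` or `"adjoint"`.
#' @return Matrix N x n of masked-voxel field values (one column per optode).
#' @export
batch_fields <- function(system, positions, role = c("direct", "adjoint")) {
  role <- match.arg(role)
  positions <- as.matrix(positions)
  B <- vapply(seq_len(nrow(positions)), function(i) {
    ip <- optode_interior_point(positions[i, ], system$musp)
    point_source_rhs(system, ip)
  }, numeric(length(system$mask_idx)))
  solve_system(system, B)
}

#' Assemble the normalized-Born Jacobian
#'
#' Row `i` (channel `i` = source `s`, detector `d`) has entries
#' `J[i, j] = Phi_x(s, j) * G_m(d, j) * dV / Phi_x(s, d)`:
#' the excitation field at voxel `j`, the adjoint emission Green's function
#' of the detector at `j`, the voxel support volume, normalized by the
#' modelled excitation measurement of the channel.
#'
#' @param phix Matrix N x n_sources of excitation fields (masked voxels).
#' @param gm Matrix N x n_detectors of adjoint emission fields.
#' @param phix_det Vector (length = channels) of modelled excitation
#'   amplitudes `Phi_x(s_i, d_i)`; must be positive.
#' @param channels Channel table (`source`, `detector`).
#' @param dV Voxel volume (mm^3).
#' @return List of class `born_jacobian`: `J` (M x N dense matrix), `dV`,
#'   `channels`, and `valid` (channels with positive excitation).
#' @export
compute_jacobian <- function(phix, gm, phix_det, channels, dV) {
  M <- nrow(channels)
  stopifnot(length(phix_det) == M)
  valid <- is.finite(phix_det) & phix_det > 0
  J <- matrix(0, M, nrow(phix))
  for (i in seq_len(M)) {
    if (!valid[i]) next
    J[i, ] <- phix[, channels$source[i]] * gm[, channels$detector[i]] *
      dV / phix_det[i]
  }
  structure(list(J = J, dV = dV, channels = channels, valid = valid),
            class = "born_jacobian")
}

#' Build the Jacobian for a layout and grid under assumed properties
#'
#' End-to-end helper: solves all excitation fields, all adjoint emission
#' fields, extracts the modelled excitation amplitudes per channel, and calls
#' [compute_jacobian()].
#'
#' @param layout An `optode_layout` with channels formed.
#' @param grid A `voxel_grid`.
#' @param props Assumed [optical_props()].
#' @return A `born_jacobian` (see [compute_jacobian()]); also carries the
#'   systems used in attributes `sys_x` and `sys_m`.
#' @export
build_jacobian <- function(layout, grid, props) {
  if (nrow(layout$channels) == 0) stop("layout has no channels; call form_channels()")
  sys_x <- assemble_system(grid, props, "excitation")
  sys_m <- assemble_system(grid, props, "emission")
  phix <- batch_fields(sys_x, layout$sources[, c("x", "y", "z")])
  gm <- batch_fields(sys_m, layout$detectors[, c("x", "y", "z")], role = "adjoint")
  ch <- layout$channels
  phix_det <- vapply(seq_len(nrow(ch)), function(i) {
    f <- fluence_field(sys_x, phix[, ch$source[i]], "direct")
    boundary_measurement(f, sys_x, as.numeric(layout$detectors[ch$detector[i],
                                                               c("x", "y", "z")]))
  }, numeric(1))
  jac <- compute_jacobian(phix, gm, phix_det, ch, voxel_volume(grid))
  attr(jac, "sys_x") <- sys_x
  attr(jac, "sys_m") <- sys_m
  attr(jac, "phix_det") <- phix_det
  jac
}
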