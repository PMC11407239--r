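props_equal <- function(mua = 0.01, musp = 1) optical_props(mua, mua, musp, musp)

test_that("optical properties derive kappa and the Robin constant consistently", {
  pr <- optical_props(0.0089, 0.0062, 1.314, 1.274)
  expect_equal(pr$kappa_x, 1 / (3 * (0.0089 + 1.314)))
  expect_equal(pr$kappa_m, 1 / (3 * (0.0062 + 1.274)))
  expect_gt(pr$A, 1)            # internal reflection makes A > 1 for n > 1
  expect_error(optical_props(-1e-3, 1e-3, 1, 1), "positive")
})

test_that("assembled operator is symmetric positive definite", {
  p <- small_problem(c(8, 8, 10))
  sys <- assemble_system(p$grid, props_equal(), "excitation")
  A <- as.matrix(sys$A)
  expect_equal(A, t(A), tolerance = 1e-14)
  expect_true(all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("single-voxel system is mua*dV plus six Robin face terms", {
  dom <- cyl_domain(10, 10)
  g <- build_voxel_grid(dom, c(1, 1, 1))
  pr <- props_equal(0.02, 1)
  sys <- assemble_system(g, pr, "excitation")
  h <- g$spacing
  rob <- sum((prod(h) / h) / (2 * pr$A + h / (2 * pr$kappa_x)) * 2)
  expect_equal(as.numeric(sys$A), 0.02 * prod(h) + rob, tolerance = 1e-12)
})

test_that("interior rows reproduce the hand-assembled 7-point stencil", {
  # all-masked 3x3x3 cube: inscribe the grid fully inside a wide cylinder
  dom <- cyl_domain(100, 30)
  g <- build_voxel_grid(dom, c(3, 3, 3))
  g$mask[] <- TRUE
  pr <- props_equal(0.01, 1)
  sys <- assemble_system(g, pr, "excitation")
  A <- as.matrix(sys$A)
  h <- g$spacing; dV <- prod(h); kap <- pr$kappa_x
  ctr <- 14                                  # center voxel (2,2,2)
  g_int <- kap * (dV / h) / h                # per-axis face conductance
  expect_equal(A[ctr, ctr], 0.01 * dV + 2 * sum(g_int), tolerance = 1e-12)
  expect_equal(A[ctr, 13], -g_int[1], tolerance = 1e-12)  # x neighbor
  expect_equal(A[ctr, 11], -g_int[2], tolerance = 1e-12)  # y neighbor
  expect_equal(A[ctr, 5], -g_int[3], tolerance = 1e-12)   # z neighbor
  # corner voxel: 3 interior faces + 3 Robin faces
  rob <- (dV / h) / (2 * pr$A + h / (2 * kap))
  expect_equal(A[1, 1], 0.01 * dV + sum(g_int) + sum(rob), tolerance = 1e-12)
})

test_that("fluence solves are linear, non-negative and mirror-symmetric", {
  p <- small_problem(c(12, 12, 14))
  sys <- assemble_system(p$grid, props_equal(), "excitation")
  pos <- c(65, 0, 75)
  f1 <- solve_fluence(sys, pos, strength = 1)
  f2 <- solve_fluence(sys, pos, strength = 2)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-10)
  expect_true(all(f1$values[p$grid$mask] > 0))
  # mirror-symmetric sources about the mid-plane give mirrored fields
  fa <- solve_fluence(sys, c(65, 0, 60))
  fb <- solve_fluence(sys, c(65, 0, 90))
  flipped <- fb$values[, , rev(seq_len(p$grid$dims[3]))]
  expect_equal(fa$values, flipped, tolerance = 1e-7)
})

test_that("interior fluence matches the infinite-medium closed form in a large domain", {
  dom <- cyl_domain(100, 200)
  pr <- props_equal(0.01, 1)
  errs <- vapply(c(64, 96), function(n) {
    g <- build_voxel_grid(dom, c(n, n, n))
    sys <- assemble_system(g, pr, "excitation")
    v <- voxel_at(g, c(0, 0, 100))
    ctr <- as.numeric(voxel_centers(g, v))
    b <- numeric(length(sys$mask_idx)); b[sys$row_of[v]] <- 1
    x <- solve_system(sys, b, method = "cg")
    cen <- voxel_centers(g, sys$mask_idx)
    r <- sqrt(colSums((t(cen) - ctr)^2))
    sel <- r >= 10 & r <= 30
    mueff <- sqrt(pr$mua_x / pr$kappa_x)
    phi <- exp(-mueff * r[sel]) / (4 * pi * pr$kappa_x * r[sel])
    max(abs(x[sel] - phi) / phi)
  }, numeric(1))
  expect_lt(errs[2], errs[1])     # error decreases under refinement
  expect_lt(errs[2], 0.05)
})

test_that("adjoint fields equal dense-inverse columns and obey reciprocity", {
  p <- small_problem(c(8, 8, 8))
  pr <- props_equal()
  sys <- assemble_system(p$grid, pr, "emission")
  det <- c(65, 0, 75)
  gm <- adjoint_green(sys, det)
  # dense-inverse oracle
  Ainv <- solve(as.matrix(sys$A))
  ip <- optode_interior_point(det, sys$musp)
  tw <- fdot:::trilinear_weights(sys, ip)
  b <- numeric(length(sys$mask_idx)); b[tw$rows] <- tw$w
  expect_equal(gm$values[sys$mask_idx], as.numeric(Ainv %*% b),
               tolerance = 1e-8)
  # reciprocity: swapping source and detector leaves the measurement unchanged
  s_pos <- c(0, 65, 40); d_pos <- c(-65, 0, 110)
  m1 <- boundary_measurement(solve_fluence(sys, s_pos), sys, d_pos)
  m2 <- boundary_measurement(solve_fluence(sys, d_pos), sys, s_pos)
  expect_equal(m1, m2, tolerance = 1e-6)
  # two detectors 180 degrees apart at the same height: rotated fields
  g1 <- adjoint_green(sys, c(65, 0, 75))
  g2 <- adjoint_green(sys, c(-65, 0, 75))
  expect_equal(g1$values, g2$values[rev(seq_len(8)), , ],
               tolerance = 1e-6)
})

test_that("emission forward is linear in gamma and zero for zero yield", {
  p <- small_problem(c(10, 10, 12))
  pr <- props_equal()
  sx <- assemble_system(p$grid, pr, "excitation")
  sm <- assemble_system(p$grid, pr, "emission")
  phix <- solve_fluence(sx, c(65, 0, 75))
  g0 <- array(0, p$grid$dims)
  expect_equal(max(abs(emission_forward(phix, g0, sm)$values)), 0)
  g1 <- g0; g1[5, 5, 6] <- 2e-3
  e1 <- emission_forward(phix, g1, sm)
  e2 <- emission_forward(phix, 3 * g1, sm)
  expect_equal(e2$values, 3 * e1$values, tolerance = 1e-10)
})

test_that("single-voxel emission equals the Born kernel", {
  p <- small_problem(c(10, 10, 12))
  pr <- props_equal()
  sx <- assemble_system(p$grid, pr, "excitation")
  sm <- assemble_system(p$grid, pr, "emission")
  src <- c(65, 0, 60); det <- c(0, 65, 90)
  phix <- solve_fluence(sx, src)
  j <- which(p$grid$mask)[200]
  gam <- array(0, p$grid$dims); gam[j] <- 5e-3
  phim_det <- boundary_measurement(emission_forward(phix, gam, sm), sm, det)
  gm <- adjoint_green(sm, det)
  kernel <- gam[j] * voxel_volume(p$grid) * phix$values[j] * gm$values[j]
  expect_equal(phim_det, kernel, tolerance = 1e-8)
})

test_that("boundary measurement interpolates fields and validates positions", {
  p <- small_problem(c(10, 10, 12))
  sys <- assemble_system(p$grid, props_equal(), "excitation")
  f <- fdot:::fluence_field(sys, rep(1, length(sys$mask_idx)), "direct")
  expect_equal(boundary_measurement(f, sys, c(65, 0, 75)), 1)
  # linear-in-z field is reproduced at the interior point's z
  cen <- voxel_centers(p$grid, sys$mask_idx)
  fz <- fdot:::fluence_field(sys, cen[, 3], "direct")
  pos <- c(0, 65, 72)
  ip <- optode_interior_point(pos, sys$musp)
  expect_equal(boundary_measurement(fz, sys, pos), ip[3], tolerance = 1e-6)
  # symmetric detectors see equal values of a symmetric field
  fr <- fdot:::fluence_field(sys, sqrt(cen[, 1]^2 + cen[, 2]^2), "direct")
  expect_equal(boundary_measurement(fr, sys, c(65, 0, 75)),
               boundary_measurement(fr, sys, c(0, 65, 75)), tolerance = 1e-9)
  expect_error(boundary_measurement(f, sys, c(200, 0, 75)), "outside")
})

test_that("Jacobian rows follow Born sensitivity and flag invalid channels", {
  # 2-channel 4-voxel toy with hand-set fields
  phix <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  gm <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8), 4, 2)
  ch <- data.frame(source = c(1L, 2L), detector = c(2L, 1L))
  jac <- compute_jacobian(phix, gm, phix_det = c(2, 4), ch, dV = 10)
  expect_equal(jac$J[1, ], phix[, 1] * gm[, 2] * 10 / 2)
  expect_equal(jac$J[2, ], phix[, 2] * gm[, 1] * 10 / 4)
  # zero excitation at the detector invalidates the channel
  jac2 <- compute_jacobian(phix, gm, phix_det = c(0, 4), ch, dV = 10)
  expect_false(jac2$valid[1])
  expect_equal(jac2$J[1, ], rep(0, 4))
  # zero excitation field for a source makes its rows zero
  phix0 <- phix; phix0[, 1] <- 0
  jac3 <- compute_jacobian(phix0, gm, phix_det = c(2, 4), ch, dV = 10)
  expect_equal(jac3$J[1, ], rep(0, 4))
})

test_that("J gamma reproduces the full emission Born ratio (linearity of the model)", {
  p <- small_problem(c(16, 16, 20), n_src = 4, n_det = 4, max_sep = 200)
  pr <- props_equal(0.0089, 1.314)
  jac <- build_jacobian(p$layout, p$grid, pr)
  # uniform small gamma over a few voxels
  gam <- array(0, p$grid$dims)
  sel <- which(p$grid$mask)[c(300, 700, 1100)]
  gam[sel] <- 1e-4
  sx <- attr(jac, "sys_x"); sm <- attr(jac, "sys_m")
  S <- as.matrix(p$layout$sources[, c("x", "y", "z")])
  D <- as.matrix(p$layout$detectors[, c("x", "y", "z")])
  ch <- p$layout$channels
  ratio <- vapply(seq_len(nrow(ch)), function(i) {
    phix <- solve_fluence(sx, S[ch$source[i], ])
    phim <- emission_forward(phix, gam, sm)
    boundary_measurement(phim, sm, D[ch$detector[i], ]) /
      boundary_measurement(phix, sx, D[ch$detector[i], ])
  }, numeric(1))
  pred <- as.numeric(jac$J %*% gam[p$grid$mask])
  expect_equal(pred, ratio, tolerance = 0.01)
  # Born consistency: halving gamma does not increase the relative discrepancy
  gam2 <- gam / 2
  ratio2 <- vapply(seq_len(nrow(ch)), function(i) {
    phix <- solve_fluence(sx, S[ch$source[i], ])
    phim <- emission_forward(phix, gam2, sm)
    boundary_measurement(phim, sm, D[ch$detector[i], ]) /
      boundary_measurement(phix, sx, D[ch$detector[i], ])
  }, numeric(1))
  pred2 <- as.numeric(jac$J %*% gam2[p$grid$mask])
  rel1 <- max(abs(pred - ratio) / pmax(abs(ratio), 1e-300))
  rel2 <- max(abs(pred2 - ratio2) / pmax(abs(ratio2), 1e-300))
  expect_lt(rel2, rel1 * 1.01)
})

test_that("disconnected masks are rejected", {
  dom <- cyl_domain(10, 40)
  g <- build_voxel_grid(dom, c(3, 3, 8))
  g$mask[, , 4] <- FALSE            # sever the cylinder
  expect_error(assemble_system(g, props_equal(), "excitation"), "disconnected")
})
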