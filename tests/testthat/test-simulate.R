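test_that("sampled cases stay within the configured parameter ranges", {
  cfg <- sim_config_table1()
  dom <- vessel()
  set.seed(7)
  draws <- replicate(1000, {
    cs <- sample_case(cfg, dom)
    c(mua = cs$props$mua_x, musp = cs$props$musp_x,
      r = cs$inclusions[[1]]$radius, g = cs$inclusions[[1]]$gamma,
      k = length(cs$inclusions))
  })
  expect_true(all(draws["mua", ] >= 0.0089 * 0.9 &
                    draws["mua", ] <= 0.0089 * 1.1))
  expect_true(all(draws["musp", ] >= 1.314 * 0.9 &
                    draws["musp", ] <= 1.314 * 1.1))
  expect_true(all(draws["r", ] >= 7 & draws["r", ] <= 15))
  expect_true(all(draws["g", ] >= 4e-4 & draws["g", ] <= 4e-2))
  expect_true(all(draws["k", ] %in% 1:2))
  # empirical extremes approach the bounds (uniform sampling)
  expect_lt(min(draws["mua", ]), 0.0089 * 0.9 + 0.01 * 0.0089 * 0.2)
  expect_gt(max(draws["mua", ]), 0.0089 * 1.1 - 0.01 * 0.0089 * 0.2)
  expect_lt(min(draws["r", ]), 7 + 0.08)
  expect_gt(max(draws["r", ]), 15 - 0.08)
})

test_that("inclusions never overlap and stay inside the vessel", {
  cfg <- sim_config_table1()
  cfg$n_inclusions <- c(2L, 2L)
  dom <- vessel()
  set.seed(42)
  ok_overlap <- ok_contain <- TRUE
  for (k in 1:2000) {
    cs <- sample_case(cfg, dom)
    a <- cs$inclusions[[1]]; b <- cs$inclusions[[2]]
    ok_overlap <- ok_overlap &&
      sqrt(sum((a$center - b$center)^2)) > a$radius + b$radius
    ok_contain <- ok_contain && all(vapply(cs$inclusions, function(inc)
      sqrt(sum(inc$center[1:2]^2)) + inc$radius <=
        dom$radius - cfg$margin_mm + 1e-9 &&
        inc$center[3] - inc$radius >= cfg$margin_mm - 1e-9 &&
        inc$center[3] + inc$radius <= dom$height - cfg$margin_mm + 1e-9,
      logical(1)))
  }
  expect_true(ok_overlap)
  expect_true(ok_contain)
  # oversized inclusions are rejected
  cfg$radius_range <- c(100, 120)
  expect_error(sample_case(cfg, dom), "containment")
})

test_that("cylindrical inclusions honor the second-regime geometry", {
  cfg <- sim_config_table2()
  dom <- vessel()
  set.seed(3)
  cs <- sample_case(cfg, dom)
  expect_true(all(vapply(cs$inclusions, function(i)
    i$radius >= 5 && i$radius <= 10 && i$height >= 10 && i$height <= 30,
    logical(1))))
  expect_true(length(cs$inclusions) %in% 1:3)
})

test_that("rasterization matches brute-force center-in-shape tests", {
  dom <- cyl_domain(30, 60)
  grid <- build_voxel_grid(dom, c(12, 12, 16))
  cen <- voxel_centers(grid)
  # sphere centered on a voxel center, radius 1.6 x spacing
  c0 <- as.numeric(voxel_centers(grid, voxel_at(grid, c(0, 0, 30))))
  r0 <- 1.6 * grid$spacing[1]
  case <- structure(list(inclusions = list(list(center = c0, radius = r0,
                                                height = NA, gamma = 0.01)),
                         shape = "sphere"), class = "sim_case")
  fm <- rasterize_inclusions(case, grid)
  brute <- sum(rowSums(sweep(cen, 2, c0)^2) <= r0^2 & as.vector(grid$mask))
  expect_equal(sum(fm$values > 0), brute)
  # no inclusions -> all-zero map
  case0 <- structure(list(inclusions = list(), shape = "sphere"),
                     class = "sim_case")
  expect_equal(max(abs(rasterize_inclusions(case0, grid)$values)), 0)
  # two disjoint inclusions with different yields -> exactly 3 distinct values
  case2 <- structure(list(inclusions = list(
    list(center = c(-10, 0, 15), radius = 6, height = NA, gamma = 0.01),
    list(center = c(10, 0, 45), radius = 6, height = NA, gamma = 0.03)),
    shape = "sphere"), class = "sim_case")
  expect_equal(sort(unique(as.vector(rasterize_inclusions(case2, grid)$values))),
               c(0, 0.01, 0.03))
})

test_that("simulated measurements scale linearly with the yield", {
  p <- small_problem(c(12, 12, 14), n_src = 4, n_det = 4, max_sep = 120)
  cfg <- sim_config_table1()
  set.seed(9)
  cs <- sample_case(cfg, vessel())
  truth <- rasterize_inclusions(cs, p$grid)
  ms1 <- simulate_measurements(cs, p$layout, p$grid, gamma = truth)
  # zero yield -> zero emission everywhere
  zero <- truth; zero$values[] <- 0
  ms0 <- simulate_measurements(cs, p$layout, p$grid, gamma = zero)
  expect_equal(max(abs(ms0$phim)), 0)
  expect_equal(ms0$phix, ms1$phix)      # excitation unaffected by gamma
  # doubling gamma doubles every emission amplitude
  dbl <- truth; dbl$values <- 2 * truth$values
  ms2 <- simulate_measurements(cs, p$layout, p$grid, gamma = dbl)
  expect_equal(ms2$phim, 2 * ms1$phim, tolerance = 1e-10)
})

test_that("ratio noise has the configured standard deviation and is seed-stable", {
  ch <- data.frame(source = 1:10000, detector = 1:10000)
  ms <- measurement_set(ch, rep(1, 10000), rep(0.5, 10000))
  ms <- born_ratio(ms)
  set.seed(1)
  noisy <- add_ratio_noise(ms, 0.02)
  e <- noisy$y - 0.5
  expect_equal(sd(e), 0.02 * 0.5, tolerance = 0.05)
  expect_equal(mean(e), 0, tolerance = 0.001)
  # zero level leaves ratios untouched
  expect_equal(add_ratio_noise(ms, 0)$y, ms$y)
  # identical seeds give identical noise
  set.seed(33); n1 <- add_ratio_noise(ms, 0.01)$y
  set.seed(33); n2 <- add_ratio_noise(ms, 0.01)$y
  expect_identical(n1, n2)
})

test_that("per-wavelength noise perturbs both amplitudes and recomputes ratios", {
  ch <- data.frame(source = 1:5000, detector = 1:5000)
  ms <- born_ratio(measurement_set(ch, rep(2, 5000), rep(1, 5000)))
  set.seed(2)
  noisy <- add_per_wavelength_noise(ms, 0.01, 0.005)
  expect_equal(sd(noisy$phix - 2), 0.01 * max(ms$phix), tolerance = 0.05)
  expect_equal(sd(noisy$phim - 1), 0.005 * max(ms$phim), tolerance = 0.05)
  expect_equal(noisy$y, noisy$phim / noisy$phix)
  # zero levels are the identity
  same <- add_per_wavelength_noise(ms, 0, 0)
  expect_equal(same$y, ms$y)
})

test_that("dataset generation is reproducible and self-consistent", {
  dom <- vessel()
  grid <- build_voxel_grid(dom, c(16, 16, 20))
  lay <- form_channels(place_optodes(dom, 8, 8, c(2, 4), c(2, 4)), 80)
  rc <- recon_config(100, table3_assumed(), "none")
  cfg <- sim_config_table1()
  ds1 <- generate_dataset(cfg, dom, grid, lay, 8, c(4, 2, 2), rc, seed = 5)
  ds2 <- generate_dataset(cfg, dom, grid, lay, 8, c(4, 2, 2), rc, seed = 5)
  expect_equal(ds1$cases[[3]]$classic, ds2$cases[[3]]$classic)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_equal(as.integer(table(ds1$split)), c(4L, 2L, 2L))
  # every classic volume is nonzero; truths re-rasterize from the manifest
  for (cs in ds1$cases) {
    expect_gt(max(abs(cs$classic)), 0)
    case <- structure(list(inclusions = cs$meta$inclusions,
                           shape = cs$meta$shape), class = "sim_case")
    expect_equal(rasterize_inclusions(case, grid)$values, cs$truth)
  }
  # split membership is disjoint by construction
  expect_equal(length(ds1$split), 8L)
})

test_that("the sparse camera regime generates cylinder datasets with channel selection", {
  dom <- vessel()
  grid <- build_voxel_grid(dom, c(16, 16, 20))
  lay <- form_channels(place_optodes(dom, 8, 8, c(2, 4), c(2, 4)), 100)
  rc <- recon_config(1, optical_props(0.0005, 0.0005, 0.1, 0.1), "std",
                     list(factor = 0.8))
  ds <- generate_dataset(sim_config_table2(), dom, grid, lay, 4, c(2, 1, 1),
                         rc, seed = 8)
  expect_equal(ds$manifest$regime, "per_wavelength")
  expect_equal(ds$manifest$alpha, 1)
  expect_equal(ds$manifest$selection, "std")
  for (cs in ds$cases) {
    expect_true(all(vapply(cs$meta$inclusions, function(i)
      is.finite(i$height), logical(1))))       # cylindrical inclusions
    expect_gt(max(abs(cs$classic)), 0)
  }
})
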