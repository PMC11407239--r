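test_that("polynomial transforms recover known warps and validate inputs", {
  # rectilinear control points give (numerically) the identity transform
  g <- as.matrix(expand.grid(u = seq(1, 40, 4), v = seq(1, 30, 4)))
  m_id <- fit_unwrap_transform(g, g, degree = 2)
  expect_lt(m_id$rms_roundtrip_px, 1e-8)
  expect_equal(apply_transform(m_id, rbind(c(7.5, 12.25))),
               rbind(c(7.5, 12.25)), tolerance = 1e-8, ignore_attr = TRUE)
  # a known affine map is recovered on held-out points
  A <- rbind(c(1.05, 0.08), c(-0.04, 0.97)); b <- c(3, -2)
  px <- g %*% t(A) + matrix(b, nrow(g), 2, byrow = TRUE)
  m <- fit_unwrap_transform(px, g, degree = 3)
  held <- rbind(c(10.3, 7.7), c(25.1, 18.9))
  held_px <- held %*% t(A) + matrix(b, 2, 2, byrow = TRUE)
  expect_lt(max(abs(apply_transform(m, held_px) - held)), 0.1)
  expect_lt(max(abs(apply_transform(m, held, "inverse") - held_px)), 0.1)
  # degree too high for the control-point count
  few <- g[1:8, ]
  expect_error(fit_unwrap_transform(few, few, degree = 4), "control points")
})

test_that("unwrapping is the identity for an identity map and preserves constants", {
  set.seed(1)
  img <- matrix(runif(30 * 20), 30, 20)
  g <- as.matrix(expand.grid(u = seq(1, 30, 3), v = seq(1, 20, 3)))
  m_id <- fit_unwrap_transform(g, g, degree = 2)
  uw <- unwrap_section(img, m_id, list(u = c(1, 30), v = c(1, 20)), pitch = 1)
  expect_equal(uw$values, img, tolerance = 1e-6)
  const <- matrix(4.2, 30, 20)
  uwc <- unwrap_section(const, m_id, list(u = c(2, 29), v = c(2, 19)),
                        pitch = 0.5)
  expect_equal(range(uwc$values), c(4.2, 4.2), tolerance = 1e-9)
})

test_that("unwrapping a warped checkerboard restores uniform squares", {
  # checkerboard in rectilinear space, viewed through a known mild warp
  nu <- 40; nv <- 32
  board <- outer(seq_len(nu), seq_len(nv), function(i, j)
    (floor((i - 1) / 8) + floor((j - 1) / 8)) %% 2)
  warp <- function(uv) cbind(1.1 * uv[, 1] + 0.003 * uv[, 1] * uv[, 2] + 3,
                             0.95 * uv[, 2] + 0.002 * uv[, 2]^2 + 5)
  # render the warped (camera) image by inverse fixed-point lookup
  nxr <- 60; nyr <- 50
  pix <- as.matrix(expand.grid(x = seq_len(nxr), y = seq_len(nyr)))
  uv <- pix
  for (it in 1:30) uv <- uv + 0.8 * (pix - warp(uv))
  raw <- matrix(fdot:::bilinear_sample(board, uv[, 1], uv[, 2]), nxr, nyr)
  raw[is.na(raw)] <- 0
  cp <- as.matrix(expand.grid(u = seq(1, nu, 4), v = seq(1, nv, 4)))
  map <- fit_unwrap_transform(warp(cp), cp, degree = 3)
  uw <- unwrap_section(raw, map, list(u = c(5, 36), v = c(5, 28)), pitch = 1)
  truth <- board[5:36, 5:28]
  ok <- !is.na(uw$values)
  expect_gt(mean(abs(uw$values - truth)[ok] < 0.25), 0.9)
})

test_that("stitching concatenates sections and rejects mismatches", {
  a <- matrix(1, 10, 4); b <- matrix(2, 10, 6); c_ <- matrix(3, 10, 5)
  st <- stitch_sections(list(a, b, c_))
  expect_equal(dim(st$values), c(10, 15))
  expect_equal(st$sections, rep(1:3, c(4, 6, 5)))
  expect_equal(unique(as.vector(st$values[, 1:4])), 1)
  # constant sections stitch to a constant
  st2 <- stitch_sections(list(matrix(7, 5, 3), matrix(7, 5, 3)))
  expect_equal(unique(as.vector(st2$values)), 7)
  expect_error(stitch_sections(list(matrix(1, 10, 4), matrix(1, 9, 4))),
               "vertical")
})

test_that("spot removal fills saturated regions from their surroundings", {
  # linear ramp with a planted saturated disk
  nr <- 40; nc <- 40
  ramp <- outer(seq_len(nr), seq_len(nc), function(i, j) i / nr + 0.5 * j / nc)
  img <- ramp
  d2 <- outer((seq_len(nr) - 20)^2, (seq_len(nc) - 22)^2, `+`)
  img[d2 <= 9] <- 10                       # saturated spot
  out <- remove_spots(img, threshold = 10, dilate_radius = 5)
  filled <- attr(out, "spot_mask")
  expect_true(all(out[filled] < 10))
  expect_lt(max(abs(out[filled] - ramp[filled]) / ramp[filled]), 0.02)
  expect_equal(out[!filled], img[!filled])
  # no saturated pixels: image returned unchanged
  clean <- remove_spots(ramp, threshold = 5)
  expect_equal(as.vector(clean), as.vector(ramp))
  # adjacent spots merge after dilation and no saturated pixel survives
  img2 <- ramp
  img2[15:16, 10] <- 10; img2[15:16, 13] <- 10
  out2 <- remove_spots(img2, threshold = 10, dilate_radius = 5)
  expect_true(all(out2 < 10))
  expect_error(remove_spots(matrix(1, 4, 4), threshold = 1), "saturated")
})

test_that("median smoothing matches the brute-force oracle exactly", {
  set.seed(12)
  img <- matrix(runif(400), 20, 20)
  out <- median_smooth(img, 7)
  # brute force with explicit reflective padding
  refl <- function(i, n) { k <- (abs(i - 1)) %% (2 * (n - 1))
    ifelse(k < n, k + 1, 2 * n - 1 - k) }
  brute <- img
  for (i in 1:20) for (j in 1:20) {
    ii <- refl(i + (-3:3), 20); jj <- refl(j + (-3:3), 20)
    brute[i, j] <- median(img[ii, jj])
  }
  expect_equal(out, brute)
  # constants are fixed points; single impulses are removed
  expect_equal(median_smooth(matrix(3, 9, 9), 7), matrix(3, 9, 9))
  imp <- matrix(0, 11, 11); imp[6, 6] <- 5
  expect_equal(median_smooth(imp, 7), matrix(0, 11, 11))
  # idempotent on piecewise-constant output
  pc <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  expect_equal(median_smooth(median_smooth(pc, 3), 3), median_smooth(pc, 3))
})

test_that("3x3 neighborhood sampling takes the block median", {
  img <- matrix(1:9, 3, 3)                 # block values 1..9
  expect_equal(sample_measurements(img, cbind(2, 2)), 5)
  const <- matrix(2.5, 10, 10)
  expect_equal(sample_measurements(const, cbind(c(3, 7), c(4, 9))),
               c(2.5, 2.5))
  # identical mapped pixels give identical amplitudes
  set.seed(3)
  rnd <- matrix(runif(100), 10, 10)
  two <- sample_measurements(rnd, rbind(c(5, 5), c(5, 5)))
  expect_equal(two[1], two[2])
  expect_error(sample_measurements(rnd, cbind(50, 5)), "outside")
})

test_that("the synthetic fixture is deterministic and the full chain recovers the panorama", {
  fx1 <- synth_camera_fixture(seed = 4)
  fx2 <- synth_camera_fixture(seed = 4)
  expect_identical(fx1$raw, fx2$raw)
  expect_identical(fx1$truth, fx2$truth)
  # full chain: unwrap each section, stitch, despot, median-smooth
  nu <- nrow(fx1$truth)
  secs <- lapply(1:3, function(s) {
    nv <- length(fx1$sections[[s]])
    unwrap_section(fx1$raw[[s]], fx1$maps[[s]],
                   list(u = c(1, nu), v = c(1, nv)), pitch = 1)
  })
  pano <- stitch_sections(secs)
  img <- pano$values
  img[is.na(img)] <- 0
  img <- remove_spots(img, threshold = 1.4, dilate_radius = 5)
  img <- median_smooth(img, 3)
  truth_sm <- median_smooth(fx1$truth, 3)
  interior <- matrix(FALSE, nrow(img), ncol(img))
  interior[4:(nrow(img) - 3), 4:(ncol(img) - 3)] <- TRUE
  # section seams carry resampling transients; exclude a 3-px band
  seams <- cumsum(vapply(secs, function(s) ncol(s$values), numeric(1)))
  for (s in seams[-3]) interior[, pmax(1, s - 2):pmin(ncol(img), s + 3)] <- FALSE
  rmse <- sqrt(mean((img - truth_sm)[interior]^2))
  expect_lt(rmse, 0.05)
  # chain is deterministic
  expect_equal(img, {
    secs2 <- lapply(1:3, function(s) {
      nv <- length(fx1$sections[[s]])
      unwrap_section(fx1$raw[[s]], fx1$maps[[s]],
                     list(u = c(1, nu), v = c(1, nv)), pitch = 1)
    })
    p2 <- stitch_sections(secs2)$values
    p2[is.na(p2)] <- 0
    median_smooth(remove_spots(p2, threshold = 1.4, dilate_radius = 5), 3)
  }, ignore_attr = TRUE)
  # a fixture with no spots passes remove_spots unchanged
  fx0 <- synth_camera_fixture(seed = 4, n_spots = 0)
  r0 <- fx0$raw[[1]]
  expect_equal(as.vector(remove_spots(r0, threshold = 1.4)), as.vector(r0))
})
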