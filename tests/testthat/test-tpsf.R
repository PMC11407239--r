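test_that("IRF conditioning: smoothing, baseline shift, peak normalization", {
  # 12-sample hand trace with a 3-sample window (dt = 1 ns -> window 3)
  t <- 1:12
  a <- c(1, 1, 1, 2, 5, 9, 7, 4, 2, 1, 1, 1)
  irf <- estimate_irf(t, a, window = 3, baseline_frac = 0.25)
  sm <- as.numeric(stats::filter(a, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(a[1:2]); sm[12] <- mean(a[11:12])
  hand <- sm - mean(sm[1:3])
  hand <- hand / max(hand)
  expect_equal(irf$h, hand)
  expect_equal(max(irf$h), 1)
  # an already-conditioned trace with unit window is unchanged
  b <- c(0, 0, 0, 0.5, 1, 0.5, 0, 0, 0, 0, 0, 0)
  irf2 <- estimate_irf(t, b, window = 0.5, baseline_frac = 0.25)
  expect_equal(irf2$h, b)
  # constant traces have no peak after baseline removal
  expect_error(estimate_irf(t, rep(3, 12), window = 1), "peak")
})

test_that("semi-infinite TPSF has physical limits and distance-ordered peaks", {
  t <- seq(0.01, 10, by = 0.01)
  y <- semi_infinite_tpsf(4e-4, 0.11, 20, t)
  expect_true(all(is.finite(y)) && all(y >= 0))
  # vanishes at both ends of the time axis
  expect_lt(y[1], max(y) * 1e-3)
  expect_lt(y[length(y)], max(y) * 1e-2)
  # peak time strictly increases with distance
  peaks <- vapply(c(13.8, 18.4, 23.0, 27.6), function(r)
    t[which.max(semi_infinite_tpsf(4e-4, 0.11, r, t))], numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_error(semi_infinite_tpsf(-1, 0.1, 10, t), "positive")
})

test_that("absorption enters exactly as exp(-delta mua c t / n)", {
  t <- seq(0.05, 8, by = 0.01)
  mua <- 2e-4; d <- 3e-4
  for (boundary in c("extrapolated", "zero")) {
    y1 <- semi_infinite_tpsf(mua, 0.11, 20, t, boundary = boundary)
    y2 <- semi_infinite_tpsf(mua + d, 0.11, 20, t, boundary = boundary)
    v <- 299.792458 / 1.33
    expect_equal(y2 / y1, exp(-d * v * t), tolerance = 1e-12)
  }
})

test_that("feature extraction matches hand computation", {
  t <- 1:6
  a <- c(1, 5, 3, 9, 7, 2)
  f <- extract_features(t, a)
  expect_equal(f$ipeak, (9 + 7 + 5 + 3 + 2) / 5)
  expect_equal(f$tmean, sum(t * a) / sum(a))
  # single nonzero sample: tmean is its time
  t2 <- seq(0.1, 3, by = 0.1)
  a2 <- numeric(30); a2[23] <- 4          # t = 2.3 ns
  expect_equal(extract_features(t2, a2)$tmean, 2.3)
  # symmetric triangular pulse: tmean at the apex
  a3 <- c(0:5, 4:0)
  expect_equal(extract_features(seq_len(11), a3)$tmean, 6)
  expect_error(extract_features(1:4, rep(1, 4)), "5 samples")
  expect_error(extract_features(1:6, rep(0, 6)), "total intensity")
})

test_that("model features convolve the IRF with the TPSF correctly", {
  t <- seq(0.01, 6, by = 0.01)
  # unit-impulse IRF: features equal the bare TPSF features (times offset
  # by the IRF time origin)
  imp <- structure(list(t = t[1:50], h = c(1, numeric(49))), class = "irf")
  mf <- model_features(4e-4, 0.11, 20, imp, t)
  bare <- extract_features(t, semi_infinite_tpsf(4e-4, 0.11, 20, t))
  expect_equal(mf$ipeak, bare$ipeak * (t[2] - t[1]), tolerance = 1e-9)
  expect_equal(mf$tmean, bare$tmean + t[1], tolerance = 1e-9)
  # shift theorem: delaying the IRF by k steps delays tmean by k dt
  k <- 30
  del <- structure(list(t = t[1:50], h = c(numeric(k), 1, numeric(49 - k))),
                   class = "irf")
  mf2 <- model_features(4e-4, 0.11, 20, del, t)
  expect_equal(mf2$tmean - mf$tmean, k * 0.01, tolerance = 1e-9)
  expect_equal(mf2$ipeak, mf$ipeak, tolerance = 1e-12)
  # 8-sample convolution against a brute-force double loop
  h8 <- c(0.1, 0.4, 1, 0.5, 0.2, 0.1, 0, 0)
  x8 <- c(0, 1, 3, 2, 1, 0.5, 0.2, 0.1)
  cv <- fdot:::convolve_full(h8, x8, dt = 1, t0 = 0)
  brute <- numeric(15)
  for (i in 1:8) for (j in 1:8) brute[i + j - 1] <- brute[i + j - 1] + h8[i] * x8[j]
  expect_equal(cv$y, brute, tolerance = 1e-12)
  expect_error(model_features(4e-4, 0.11, 20,
                              structure(list(t = c(0, 0.2), h = c(1, 0)),
                                        class = "irf"), t),
               "share the step")
})

test_that("feature-table entries agree with direct per-point model features", {
  irf <- gaussian_irf(t = seq(0.01, 6, by = 0.01), t0 = 0.8, sigma = 0.15,
                      baseline_frac = 0.03)
  t <- seq(0.01, 6, by = 0.01)
  tab <- tpsf_feature_table(irf, distances = c(13.8, 27.6),
                           mua_grid = c(2e-4, 4e-4),
                           musp_grid = c(0.08, 0.11), t = t)
  for (im in 1:2) for (is in 1:2) for (id in 1:2) {
    mf <- model_features(tab$mua_grid[im], tab$musp_grid[is],
                         tab$distances[id], irf, t)
    expect_equal(tab$tmean[im, is, id], mf$tmean, tolerance = 1e-6)
    expect_equal(tab$log_ipeak[im, is, id], log(mf$ipeak), tolerance = 1e-6)
  }
})

# shared fixtures for the grid-search tests: the full parameter grids and
# noiseless features generated at the on-grid truth (mua 4e-4, mus\' 0.11)
tpsf_irf <- gaussian_irf()
tpsf_t <- seq(0.01, 10, by = 0.01)
tpsf_dists <- c(13.8, 18.4, 23.0, 27.6)
tpsf_feats <- lapply(tpsf_dists, function(r)
  model_features(4e-4, 0.11, r, tpsf_irf, tpsf_t))
tpsf_meas <- list(ipeak = vapply(tpsf_feats, `[[`, 1, "ipeak"),
                  tmean = vapply(tpsf_feats, `[[`, 1, "tmean"))
tpsf_tab <- tpsf_feature_table(tpsf_irf, tpsf_dists)

test_that("grid search recovers on-grid parameters exactly from noiseless features", {
  fit <- grid_search_fit(tpsf_meas, tpsf_tab)
  expect_equal(fit$mua, 4e-4, tolerance = 1e-12)
  expect_equal(fit$musp, 0.11, tolerance = 1e-12)
  # loss vanishes at the generating grid point
  expect_lt(fit$loss[fit$argmin[1], fit$argmin[2]], 1e-12)
  # loss surface is finite everywhere
  expect_true(all(is.finite(fit$loss)))
})

test_that("the loss is invariant to common peak rescaling and time shifts", {
  f1 <- grid_search_fit(tpsf_meas, tpsf_tab)
  f2 <- grid_search_fit(list(ipeak = tpsf_meas$ipeak * 37,
                             tmean = tpsf_meas$tmean + 1.2), tpsf_tab)
  expect_equal(f1$loss, f2$loss, tolerance = 1e-9)
})

test_that("the time-term weight is active", {
  # conflicting features: times from one parameter set, peaks from another
  alt <- list(ipeak = tpsf_meas$ipeak,
              tmean = tpsf_meas$tmean + c(0, 0.02, 0.04, 0.06))
  f_w <- grid_search_fit(alt, tpsf_tab, weight = 100)
  f_1 <- grid_search_fit(alt, tpsf_tab, weight = 1)
  expect_false(f_w$mua == f_1$mua && f_w$musp == f_1$musp)
})

test_that("fits degrade gracefully under trace noise and stay unbiased", {
  # noise is added to the time-resolved traces (std = level x trace max),
  # features re-extracted, then fitted; 100 seeded trials per level
  traces <- lapply(tpsf_dists, function(r) {
    x <- semi_infinite_tpsf(4e-4, 0.11, r, tpsf_t)
    fdot:::convolve_full(tpsf_irf$h, x, 0.01, tpsf_t[1] + tpsf_irf$t[1])
  })
  run_level <- function(lvl) {
    err <- matrix(0, 100, 2)
    for (k in 1:100) {
      ip <- numeric(4); tm <- numeric(4)
      for (i in 1:4) {
        y <- traces[[i]]$y +
          rnorm(length(traces[[i]]$y), 0, lvl * max(traces[[i]]$y))
        f <- extract_features(traces[[i]]$t, y)
        ip[i] <- f$ipeak; tm[i] <- f$tmean
      }
      fit <- grid_search_fit(list(ipeak = ip, tmean = tm), tpsf_tab)
      err[k, ] <- c(fit$mua - 4e-4, fit$musp - 0.11)
    }
    err
  }
  set.seed(99)
  e_small <- run_level(0.001)
  set.seed(99)
  e_large <- run_level(0.01)
  # at 0.1% trace noise the scattering estimate is precise and unbiased:
  # median absolute error within ~one percent-level band of the truth
  expect_lt(median(abs(e_small[, 2])), 0.015)        # mus' (truth 0.11)
  expect_lt(abs(median(e_small[, 2])), 0.005)        # no systematic bias
  expect_lt(median(abs(e_small[, 1])), 2e-4)         # mua within the grid scale
  # error grows monotonically with the noise level
  expect_gt(median(abs(e_large[, 2])), median(abs(e_small[, 2])))
})
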