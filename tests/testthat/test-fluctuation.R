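test_that("window admissibility: 50 TR is the floor at 0.01 Hz and TR 2 s", {
  expect_identical(min_window_length(0.01, 2), 50L)
  expect_silent(window_spec(50, 5, tr_s = 2))
  expect_warning(window_spec(30, 5, tr_s = 2), "shorter than")
  expect_error(window_spec(50, 0, tr_s = 2), "step_tr")
})

test_that("sliding windows cover the series as floor((n - len)/step) + 1", {
  w50 <- window_spec(50, 5, tr_s = 2)
  wins <- sliding_windows(240, w50)
  expect_equal(nrow(wins), 39)
  expect_equal(wins$start[39], 191)
  expect_equal(wins$end[39], 240)

  # full-length window: exactly one
  wfull <- window_spec(240, 5, tr_s = 2)
  expect_equal(nrow(sliding_windows(240, wfull)), 1)

  # 30- and 70-TR validation variants
  expect_equal(nrow(sliding_windows(240, suppressWarnings(window_spec(30, 5, tr_s = 2)))), 43)
  expect_equal(nrow(sliding_windows(240, window_spec(70, 5, tr_s = 2))), 35)

  expect_error(sliding_windows(40, w50), "exceeds")
})

test_that("ALFF is zero for constants, homogeneous of degree 1, and band-selective", {
  expect_equal(alff(rep(7, 120), tr_s = 2), 0, tolerance = 1e-10)

  set.seed(3)
  x <- rnorm(120)
  expect_equal(alff(3 * x, tr_s = 2), 3 * alff(x, tr_s = 2), tolerance = 1e-10)

  # 240 samples at TR 2: bin grid is k/480 Hz; bin 5 (0.0104 Hz) is in
  # band, bin 4 (0.0083 Hz) is not. Cosine tones are orthogonal to the
  # detrending ramp over complete cycles, so rejection is near-exact.
  t_s <- (0:239) * 2
  in_tone <- cos(2 * pi * (5 / 480) * t_s)
  out_tone <- cos(2 * pi * (4 / 480) * t_s)
  expect_gt(alff(in_tone, tr_s = 2), 50 * alff(out_tone, tr_s = 2))

  # a band too narrow for the bin grid errors with the resolution
  expect_error(alff(rnorm(50), tr_s = 2, band = c(0.011, 0.012)), "resolution")
})

test_that("dALFF vanishes for stationary amplitude and tracks envelope dynamics", {
  w <- window_spec(50, 5, tr_s = 2)
  mask <- full_mask(c(2L, 2L, 2L))

  # window-edge effects (per-window detrend interacting with the tone
  # phase) leave a small residual variance; measured at ~2-4% of the
  # squared static ALFF across in-band tones, so 5% is the frozen bound
  stat <- sine_bold(0.04, n_volumes = 200, grid = c(2L, 2L, 2L))
  d_stat <- dalff(stat, w, mask)
  static_alff <- alff(stat$data[1, 1, 1, ], tr_s = 2)
  expect_lt(max(d_stat$map), 0.05 * static_alff^2)

  # envelope alternating between windows raises the variance
  t_s <- (0:199) * 2
  env <- 1 + 0.8 * sin(2 * pi * t_s / 250)
  mod <- sine_bold(0.04, n_volumes = 200, grid = c(2L, 2L, 2L), envelope = env)
  d_mod <- dalff(mod, w, mask)
  expect_gt(min(d_mod$map), max(d_stat$map))

  # determinism and window-count bookkeeping
  expect_identical(dalff(mod, w, mask)$map, d_mod$map)
  expect_equal(d_mod$n_windows, (200 - 50) %/% 5 + 1)

  short <- sine_bold(0.04, n_volumes = 52, grid = c(2L, 2L, 2L))
  expect_error(dalff(short, w, mask), ">= 2 windows")
})

test_that("dALFF is shift-invariant and scales quadratically", {
  w <- window_spec(50, 5, tr_s = 2)
  mask <- full_mask(c(2L, 2L, 2L))
  set.seed(9)
  arr <- array(rnorm(8 * 150), dim = c(2, 2, 2, 150))
  b <- bold_volume(arr, diag(c(3, 3, 3, 1)), tr_s = 2)
  b_shift <- bold_volume(arr + 100, diag(c(3, 3, 3, 1)), tr_s = 2)
  b_scale <- bold_volume(3 * arr, diag(c(3, 3, 3, 1)), tr_s = 2)

  d <- dalff(b, w, mask)
  expect_equal(dalff(b_shift, w, mask)$map, d$map, tolerance = 1e-8)
  expect_equal(dalff(b_scale, w, mask)$map, 9 * d$map, tolerance = 1e-8)
})

test_that("z-scoring standardizes in-mask voxels and is idempotent", {
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), dim = c(4, 1, 1))
  m <- new_map_for_test(c(1, 2, 3, 99), mask)
  z <- zscore_map(m)
  expect_equal(z$map[1:3, 1, 1], c(-1, 0, 1))
  expect_equal(z$map[4, 1, 1], 0)          # out-of-mask stays 0
  expect_true(z$standardized)

  z2 <- zscore_map(z)
  expect_equal(z2$map, z$map, tolerance = 1e-12)

  flat <- new_map_for_test(c(2, 2, 2, 0), mask)
  expect_error(zscore_map(flat), "SD is zero")
})

test_that("standardized maps have unit in-mask moments on real output", {
  w <- window_spec(40, 5, tr_s = 2, f_min_hz = 0.0125)
  set.seed(4)
  arr <- array(rnorm(4^3 * 120), dim = c(4, 4, 4, 120))
  b <- bold_volume(arr, diag(c(3, 3, 3, 1)), tr_s = 2)
  mask <- full_mask(c(4L, 4L, 4L))
  z <- zscore_map(dalff(b, w, mask))
  expect_equal(mean(z$map[mask]), 0, tolerance = 1e-6)
  expect_equal(sd(z$map[mask]), 1, tolerance = 1e-6)
})
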