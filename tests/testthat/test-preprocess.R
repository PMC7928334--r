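test_that("initial-volume discard drops exactly the leading frames", {
  b <- sine_bold(0.05, n_volumes = 30)
  out <- discard_initial(b, 10)
  expect_equal(dim(out$data)[4], 20)
  expect_identical(out$data[, , , 1], b$data[, , , 11])
  expect_identical(out$affine, b$affine)
  expect_identical(discard_initial(b, 0)$data, b$data)
  expect_error(discard_initial(b, 30), "discard")
})

test_that("framewise displacement follows the Power formulation", {
  m <- zero_motion(5)
  expect_equal(compute_fd(m)$fd, rep(0, 5))

  # one step of known size: FD = 0.6 mm translation + 50 mm * 0.004 rad
  m2 <- zero_motion(3)
  m2[2, ] <- c(0.1, 0.2, 0.3, 0.001, 0.001, 0.002)
  fd <- compute_fd(m2)
  expect_equal(fd$fd[1], 0)          # first volume is 0 by convention
  expect_equal(fd$fd[2], 0.6 + 50 * 0.004)

  # permuting the translation columns leaves FD unchanged
  m3 <- m2[, c(3, 1, 2, 4, 5, 6)]
  expect_equal(compute_fd(m3)$fd, fd$fd)

  expect_error(compute_fd(m2[, 1:5]), "6 columns")
})

test_that("motion QC excludes at 3 mm / 3 degrees", {
  m <- zero_motion(10)
  expect_false(qc_exclude(m)$exclude)

  m$trans_x[5] <- 3.1
  v <- qc_exclude(m)
  expect_true(v$exclude)
  expect_match(v$reason, "translation")

  m2 <- zero_motion(10)
  m2$rot_y[4] <- 0.06          # 3.44 degrees
  expect_true(qc_exclude(m2)$exclude)
  m2$rot_y[4] <- 0.05          # 2.86 degrees
  expect_false(qc_exclude(m2)$exclude)
})

test_that("scrubbing drops flagged volumes with their 2-before/1-after neighborhood", {
  fd <- tibble::tibble(volume = 1:8, fd = c(0, 0.1, 0.6, 0.1, 0.1, 0, 0, 0))
  ret <- scrub(fd, threshold = 0.5)
  expect_equal(which(!ret$keep), 1:4)
  expect_equal(ret$reason[3], "fd_spike")
  expect_equal(ret$reason[c(1, 2, 4)], rep("neighbor", 3))

  all_low <- tibble::tibble(volume = 1:8, fd = rep(0.1, 8))
  expect_true(all(scrub(all_low, threshold = 0.5)$keep))

  # adjacent flagged volumes: neighborhoods union, nothing double-counted
  fd2 <- tibble::tibble(volume = 1:10, fd = c(0, 0, 0, 0.7, 0.7, 0, 0, 0, 0, 0))
  ret2 <- scrub(fd2, threshold = 0.5)
  expect_equal(which(!ret2$keep), 2:6)

  # idempotence: scrubbing the retained series drops nothing further
  kept_fd <- fd2[ret2$keep, ]
  expect_true(all(scrub(kept_fd, threshold = 0.5)$keep))
})

test_that("Friston-24 expansion has the documented block structure", {
  m <- zero_motion(6)
  f0 <- friston24(m)
  expect_equal(dim(f0), c(6L, 24L))
  expect_true(all(f0 == 0))

  m2 <- zero_motion(6)
  m2[, ] <- 0.5                # constant nonzero motion
  f2 <- friston24(m2)
  expect_equal(f2[2:6, 7:12], f2[2:6, 1:6],
               ignore_attr = TRUE)            # lag equals unlagged from row 2
  expect_equal(unname(f2[1, 7:12]), rep(0, 6))  # zero-filled lag at t = 1
  expect_equal(f2[, 13:18], f2[, 1:6]^2, ignore_attr = TRUE)
  expect_equal(f2[, 19:24], f2[, 7:12]^2, ignore_attr = TRUE)
})

test_that("nuisance regression projects out the design", {
  set.seed(1)
  grid <- c(3L, 3L, 3L); nt <- 60
  arr <- array(rnorm(prod(grid) * nt), dim = c(grid, nt))
  common <- sin(2 * pi * 0.03 * (0:(nt - 1)) * 2)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    arr[i, j, k, ] <- arr[i, j, k, ] + 2 * common
  }
  b <- bold_volume(arr, diag(c(3, 3, 3, 1)), tr_s = 2)

  # regressing the common signal removes it everywhere
  X <- cbind(common = common, intercept = 1)
  res <- nuisance_regress(b, X)
  cors <- apply(matrix(res$data, 27, nt), 1, function(v) abs(cor(v, common)))
  expect_lt(max(cors), 0.05)
  expect_lt(max(abs(rowMeans(matrix(res$data, 27, nt)))), 1e-10)

  # a voxel's own series in the design zeroes that voxel's residual
  own <- arr[1, 1, 1, ]
  res2 <- nuisance_regress(b, cbind(own = own, intercept = 1))
  expect_lt(max(abs(res2$data[1, 1, 1, ])), 1e-8)

  # design orthogonal to the data returns the demeaned input
  ortho <- rep(c(1, -1), nt / 2)
  ortho <- residuals(lm(ortho ~ common))      # exactly orthogonal regressor
  arr_even <- array(rep(common, each = 27), dim = c(grid, nt))
  b_even <- bold_volume(arr_even, diag(c(3, 3, 3, 1)), tr_s = 2)
  res3 <- nuisance_regress(b_even, cbind(x = ortho, intercept = 1))
  expect_equal(res3$data[1, 1, 1, ], common - mean(common), tolerance = 1e-8)

  expect_error(nuisance_regress(b, cbind(a = common, b = common, intercept = 1)),
               "rank deficient")
})

test_that("Gaussian smoothing conserves mass and spreads a delta", {
  grid <- c(11L, 11L, 11L)
  delta <- array(0, dim = grid); delta[6, 6, 6] <- 1
  sm <- smooth_gaussian(delta, fwhm_mm = 6, voxel_size_mm = 3)
  expect_equal(which.max(sm), which.max(delta))
  expect_equal(sum(sm), 1, tolerance = 1e-6)    # mass conserved (interior)
  expect_lt(max(sm), 1)

  # kernel reach is 4 voxels; voxels >= 5 from the edge see the full mass
  const <- array(5, dim = grid)
  smc <- smooth_gaussian(const, fwhm_mm = 6, voxel_size_mm = 3)
  expect_equal(as.vector(smc[5:7, 5:7, 5:7]), rep(5, 27), tolerance = 1e-6)

  expect_error(smooth_gaussian(const, fwhm_mm = 0, voxel_size_mm = 3), "fwhm")
})

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  inband <- sine_bold(0.05, n_volumes = 200)
  out <- bandpass(inband)
  v_in <- inband$data[1, 1, 1, ]
  v_out <- out$data[1, 1, 1, ]
  expect_gt(sd(v_out) / sd(v_in), 0.99)

  high <- sine_bold(0.2, n_volumes = 200)
  v_high <- bandpass(high)$data[1, 1, 1, ]
  expect_lt(sum(v_high^2) / sum(high$data[1, 1, 1, ]^2), 0.01)

  const <- bold_volume(array(3, dim = c(2, 2, 2, 40)), diag(4), tr_s = 2)
  expect_lt(max(abs(bandpass(const)$data)), 1e-10)

  expect_error(bandpass(inband, 0.01, 0.3), "Nyquist")
})

test_that("scrub application supports delete and interpolate modes", {
  b <- sine_bold(0.05, n_volumes = 20, grid = c(2L, 2L, 2L))
  ret <- tibble::tibble(volume = 1:20, keep = rep(TRUE, 20), reason = NA)
  ret$keep[5:6] <- FALSE
  del <- apply_scrub(b, ret, mode = "delete")
  expect_equal(dim(del$data)[4], 18)
  expect_identical(del$data[, , , 5], b$data[, , , 7])

  interp <- apply_scrub(b, ret, mode = "interpolate")
  expect_equal(dim(interp$data)[4], 20)
  v <- b$data[1, 1, 1, ]
  expect_equal(interp$data[1, 1, 1, 5],
               v[4] + (v[7] - v[4]) / 3, tolerance = 1e-10)
})
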