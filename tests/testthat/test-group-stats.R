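make_maps <- function(n, grid, f, mask) {
  lapply(seq_len(n), function(i) array(f(i), dim = grid))
}

test_that("two-sample t-map matches t.test voxel-wise and handles degeneracy", {
  grid <- c(4L, 4L, 4L)
  mask <- full_mask(grid)
  set.seed(21)
  a <- make_maps(5, grid, function(i) rnorm(64), mask)
  b <- make_maps(6, grid, function(i) rnorm(64, mean = 0.3), mask)
  tm <- two_sample_t_map(a, b, mask)
  expect_equal(tm$df, 9)

  # cross-check one voxel against stats::t.test (pooled variance)
  va <- sapply(a, function(m) m[2, 3, 1])
  vb <- sapply(b, function(m) m[2, 3, 1])
  ref <- t.test(va, vb, var.equal = TRUE)
  expect_equal(tm$map[2, 3, 1], unname(ref$statistic), tolerance = 1e-10)

  # identical groups give t = 0 everywhere
  tm0 <- two_sample_t_map(a, a, mask)
  expect_true(all(tm0$map == 0))
})

test_that("smoothness estimation recovers a known kernel and scales with voxel size", {
  set.seed(7)
  grid <- c(20L, 20L, 20L)
  mask <- full_mask(grid)
  maps <- lapply(1:6, function(i) {
    smooth_gaussian(array(rnorm(prod(grid)), dim = grid),
                    fwhm_mm = 6, voxel_size_mm = 3)
  })
  est3 <- estimate_smoothness(maps, mask, 3)
  expect_true(all(abs(est3$fwhm_mm - 6) / 6 < 0.2))

  # same voxel data at doubled voxel size: FWHM doubles in mm
  est6 <- estimate_smoothness(maps, mask, 6)
  expect_equal(est6$fwhm_mm, 2 * est3$fwhm_mm, tolerance = 1e-10)
  expect_equal(est6$resel_count, est3$resel_count, tolerance = 1e-10)

  # unsmoothed white noise: FWHM near the voxel size, reported unclamped
  raw <- lapply(1:6, function(i) array(rnorm(prod(grid)), dim = grid))
  est_raw <- estimate_smoothness(raw, mask, 3)
  expect_true(all(est_raw$fwhm_mm > 2 & est_raw$fwhm_mm < 4.5))

  expect_error(estimate_smoothness(maps[1:2], mask, 3), ">= 3")
  flat <- lapply(1:4, function(i) array(1, dim = grid))
  expect_error(estimate_smoothness(flat, mask, 3), "constant")
})

test_that("component labeling respects connectivity", {
  m <- array(FALSE, dim = c(8, 8, 8))
  m[1:5, 1, 1] <- TRUE
  m[7:8, 7:8, 7] <- TRUE            # disjoint blob of 4 + 1 more
  m[7, 7, 8] <- TRUE
  lab <- label_components(m, 26)
  expect_equal(max(lab), 2)
  expect_equal(sort(tabulate(lab[lab > 0])), c(5, 5))

  # diagonal pair: one component under 26, two under 6
  d <- array(FALSE, dim = c(4, 4, 4))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(max(label_components(d, 26)), 1)
  expect_equal(max(label_components(d, 6)), 2)
  expect_equal(max(label_components(d, 18)), 2)  # corner-diagonal not 18-adjacent
})

test_that("cluster peaks report signed maxima in mm coordinates", {
  vals <- array(0, dim = c(16, 16, 16))
  above <- array(FALSE, dim = c(16, 16, 16))
  vals[10:12, 10:12, 10] <- -4
  vals[11, 11, 10] <- -6
  above[10:12, 10:12, 10] <- TRUE
  tab <- cluster_peaks(vals, above, affine = diag(4))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$extent_voxels, 9)
  expect_equal(tab$peak_t, -6)
  # identity affine: 0-based voxel (10, 10, 9) reports those mm coordinates
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(10, 10, 9))

  # two disjoint blobs give two records
  above2 <- array(FALSE, dim = c(16, 16, 16))
  above2[1:5, 1, 1] <- TRUE
  above2[1:5, 8, 8] <- TRUE
  vals2 <- array(1, dim = c(16, 16, 16))
  tab2 <- cluster_peaks(vals2, above2, affine = diag(4))
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$extent_voxels, c(5, 5))
})

test_that("GRF inference finds a strong planted cluster and not an empty map", {
  grid <- c(16L, 16L, 16L)
  mask <- full_mask(grid)
  set.seed(5)
  blob <- array(FALSE, dim = grid); blob[6:10, 6:10, 6:10] <- TRUE
  a <- lapply(1:8, function(i) {
    m <- smooth_gaussian(array(rnorm(prod(grid)), dim = grid), 6, 3)
    m[blob] <- m[blob] - 2
    m
  })
  b <- lapply(1:8, function(i) {
    smooth_gaussian(array(rnorm(prod(grid)), dim = grid), 6, 3)
  })
  tm <- two_sample_t_map(a, b, mask)
  resid <- c(lapply(a, function(m) m - Reduce(`+`, a) / 8),
             lapply(b, function(m) m - Reduce(`+`, b) / 8))
  sm <- estimate_smoothness(resid, mask, 3)
  cl <- grf_cluster_inference(tm, sm, affine = diag(c(3, 3, 3, 1)))
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$sign == "negative"))
  expect_true(all(cl$peak_t < 0))

  # peak should sit inside the planted blob (voxel indices)
  pk <- cl$peak_ijk[[1]]
  expect_true(blob[pk[1], pk[2], pk[3]])

  # cluster masks rebuild the suprathreshold component containing the peak
  cm <- cluster_masks(cl, tm)
  expect_equal(length(cm), nrow(cl))
  expect_true(cm[[1]][pk[1], pk[2], pk[3]])

  # a null contrast of identical noise fields yields an empty table
  tm0 <- two_sample_t_map(b, lapply(1:8, function(i) {
    smooth_gaussian(array(rnorm(prod(grid)), dim = grid), 6, 3)
  }), mask)
  cl0 <- grf_cluster_inference(tm0, sm, cluster_forming_p = 0.001,
                               affine = diag(c(3, 3, 3, 1)))
  expect_s3_class(cl0, "cluster_table")

  expect_error(grf_cluster_inference(tm, sm, cluster_forming_p = 0.2), "cluster_forming_p")
})
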