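test_that("parameter validation rejects impossible study conditions", {
  expect_error(tiny_params(n_per_group = 1), "n_per_group")
  expect_error(tiny_params(envelope_sd_patient = -0.1), "depths")
  expect_error(tiny_params(covariate_r_target = -1.5), "-1, 1")
  expect_error(tiny_params(carrier_band_hz = c(0.01, 0.4), tr_s = 2), "Nyquist")
  expect_error(
    tiny_params(effect_rois = list(list(center = c(11, 6, 6), radius = 3))),
    "outside the grid"
  )
})

test_that("subject generation is deterministic and validates the group label", {
  p <- tiny_params()
  s1 <- generate_subject(p, "patient", 7)
  s2 <- generate_subject(p, "patient", 7)
  expect_identical(s1$bold$data, s2$bold$data)
  expect_identical(s1$motion, s2$motion)
  expect_identical(s1$covariates, s2$covariates)

  s3 <- generate_subject(p, "patient", 8)
  expect_false(identical(s1$bold$data, s3$bold$data))

  expect_error(generate_subject(p, "case", 1), "patient")
})

test_that("without envelope modulation the in-ROI dALFF is residual only", {
  # With envelope_sd = 0 and no noise the carrier amplitude is stationary;
  # what remains is finite-window amplitude sampling of the multi-component
  # carrier (beating) plus window-edge effects. Brute force over 12 seeds
  # put this at 5-16% of the squared static ALFF; 0.2 is the frozen bound.
  p <- tiny_params(envelope_sd_control = 0, envelope_sd_patient = 0,
                   noise_sd = 0)
  s <- generate_subject(p, "control", 3)
  roi <- dynalff:::sphere_mask(p$grid_shape, p$effect_rois[[1]]$center,
                               p$effect_rois[[1]]$radius)
  w <- suppressWarnings(window_spec(40, 5, tr_s = 2))
  d <- dalff(s$bold, w, roi)
  a <- alff_map(s$bold, roi)
  ratio <- max(d$map[roi]) / max(a$map[roi])^2
  expect_lt(ratio, 0.2)

  # deep modulation on the same seed dominates the stationary residual
  p_mod <- tiny_params(envelope_sd_control = 0.8, noise_sd = 0)
  s_mod <- generate_subject(p_mod, "control", 3)
  d_mod <- dalff(s_mod$bold, w, roi)
  expect_gt(mean(d_mod$map[roi]), 3 * mean(d$map[roi]))
})

test_that("in-ROI signal power is concentrated in the carrier band", {
  p <- tiny_params(noise_sd = 0, envelope_sd_control = 0)
  s <- generate_subject(p, "control", 5)
  roi <- dynalff:::sphere_mask(p$grid_shape, p$effect_rois[[1]]$center,
                               p$effect_rois[[1]]$radius)
  idx <- which(roi, arr.ind = TRUE)
  for (r in seq_len(min(5, nrow(idx)))) {
    v <- s$bold$data[idx[r, 1], idx[r, 2], idx[r, 3], ]
    v <- v - mean(v)
    n <- length(v)
    pw <- Mod(fft(v))[1:(n %/% 2 + 1)]^2
    f <- (0:(n %/% 2)) / (n * p$tr_s)
    inband <- f >= p$carrier_band_hz[1] - 1e-9 & f <= p$carrier_band_hz[2] + 1e-9
    expect_gt(sum(pw[inband]) / sum(pw), 0.9)
  }
})

test_that("mean in-ROI dALFF is non-decreasing in envelope depth", {
  w <- suppressWarnings(window_spec(40, 5, tr_s = 2))
  grid_vals <- c(0, 0.4, 0.8)
  means <- sapply(grid_vals, function(sd_env) {
    mean(sapply(1:5, function(seed) {
      p <- tiny_params(envelope_sd_control = sd_env, noise_sd = 0.5)
      s <- generate_subject(p, "control", seed * 17)
      roi <- dynalff:::sphere_mask(p$grid_shape, p$effect_rois[[1]]$center,
                                   p$effect_rois[[1]]$radius)
      mean(dalff(s$bold, w, roi)$map[roi])
    }))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("patients show lower in-ROI dALFF than controls across seeds", {
  w <- suppressWarnings(window_spec(40, 5, tr_s = 2))
  hits <- sapply(1:10, function(seed) {
    p <- tiny_params(envelope_sd_patient = 0.2, envelope_sd_control = 0.8,
                     noise_sd = 0.5)
    roi <- Reduce(`|`, lapply(p$effect_rois, function(r) {
      dynalff:::sphere_mask(p$grid_shape, r$center, r$radius)
    }))
    pat <- generate_subject(p, "patient", seed * 31)
    con <- generate_subject(p, "control", seed * 31 + 1)
    mean(dalff(pat$bold, w, roi)$map[roi]) <
      mean(dalff(con$bold, w, roi)$map[roi])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cohort generation yields labeled groups, unique ids, ground truth", {
  p <- tiny_params()
  co <- generate_cohort(p)
  expect_length(co$subjects, 6)
  groups <- vapply(co$subjects, `[[`, character(1), "group")
  expect_equal(sum(groups == "patient"), 3)
  ids <- vapply(co$subjects, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)

  gt <- co$ground_truth
  expect_length(gt$roi_masks, 2)
  expect_true(all(sapply(gt$roi_masks, sum) > 0))
  overlap <- Reduce(`+`, lapply(gt$roi_masks, function(m) m * 1))
  expect_lte(max(overlap), 1)              # ROIs disjoint
  expect_true(all(gt$true_group_effect$direction == -1))

  # determinism: covariates identical on regeneration
  co2 <- generate_cohort(p)
  expect_identical(co2$covariates, co$covariates)
  expect_identical(co2$subjects[[1]]$bold$data, co$subjects[[1]]$bold$data)

  # patients carry VAS; controls do not
  expect_true(all(is.finite(co$covariates$vas[co$covariates$group == "patient"])))
  expect_true(all(is.na(co$covariates$vas[co$covariates$group == "control"])))
})

test_that("motion spikes push FD over the scrubbing threshold at known volumes", {
  p <- tiny_params(motion_spike_prob = 0.05)
  s <- generate_subject(p, "control", 11)
  spikes <- attr(s$motion, "spike_volumes")
  expect_gt(length(spikes), 0)
  fd <- compute_fd(s$motion)
  expect_true(all(fd$fd[spikes] >= 0.5))
})
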