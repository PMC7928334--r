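#' Simulation parameters for a synthetic resting-state cohort
#'
#' Defines the study conditions for the synthetic BOLD generator: grid and
#' timing, effect regions, the depth of the slow amplitude envelope per
#' group, background noise, motion spikes, and the target correlation
#' between regional amplitude dynamics and the simulated pain score (VAS).
#'
#' Defaults mirror the acquisition being emulated: TR = 2 s, 250 volumes,
#' 21 subjects per group, a 0.01-0.08 Hz carrier band, and a patient
#' envelope depth below the control depth so that patients show *decreased*
#' dALFF in the effect regions.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param grid_shape Integer length-3 voxel counts.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of volumes acquired (before any discard).
#' @param effect_rois List of ROI specs, each `list(center = c(i, j, k),
#'   radius = r)` in 1-based voxel units. `NULL` places two default spheres.
#' @param envelope_sd_control,envelope_sd_patient Modulation depth of the
#'   slow amplitude envelope in effect ROIs (unitless, >= 0).
#' @param carrier_band_hz Frequency interval of the in-ROI oscillation.
#' @param noise_sd SD of the background noise (AR(1) + white mixture).
#' @param motion_spike_prob Per-volume probability of an FD spike.
#' @param covariate_r_target Target Pearson correlation between in-ROI
#'   dALFF and VAS across patients (|r| <= 1).
#' @param seed Integer master seed; with identical parameters it fully
#'   determines the cohort.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(n_per_group = 21,
                              grid_shape = c(24L, 24L, 24L),
                              voxel_size_mm = 3,
                              tr_s = 2,
                              n_volumes = 250,
                              effect_rois = NULL,
                              envelope_sd_control = 0.8,
                              envelope_sd_patient = 0.2,
                              carrier_band_hz = c(0.01, 0.08),
                              noise_sd = 3.5,
                              motion_spike_prob = 0.02,
                              covariate_r_target = -0.5,
                              seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  if (n_per_group < 2) {
    stop("`n_per_group` must be >= 2 (group statistics are undefined below that).",
         call. = FALSE)
  }
  if (envelope_sd_control < 0 || envelope_sd_patient < 0) {
    stop("Envelope modulation depths must be >= 0.", call. = FALSE)
  }
  if (abs(covariate_r_target) > 1) {
    stop("`covariate_r_target` must lie in [-1, 1].", call. = FALSE)
  }
  if (length(carrier_band_hz) != 2L || carrier_band_hz[1] <= 0 ||
      carrier_band_hz[2] <= carrier_band_hz[1]) {
    stop("`carrier_band_hz` must be an increasing positive interval.",
         call. = FALSE)
  }
  if (carrier_band_hz[2] > 1 / (2 * tr_s)) {
    stop("Carrier band exceeds the Nyquist frequency ", 1 / (2 * tr_s),
         " Hz at TR = ", tr_s, " s.", call. = FALSE)
  }
  if (is.null(effect_rois)) {
    effect_rois <- default_effect_rois(grid_shape)
  }
  for (i in seq_along(effect_rois)) {
    roi <- effect_rois[[i]]
    if (is.null(roi$center) || is.null(roi$radius)) {
      stop("Effect ROI ", i, " needs `center` and `radius`.", call. = FALSE)
    }
    lo <- roi$center - roi$radius; hi <- roi$center + roi$radius
    if (any(lo < 1) || any(hi > grid_shape)) {
      stop("Effect ROI ", i, " (center ", paste(roi$center, collapse = ","),
           ", radius ", roi$radius, ") extends outside the grid.",
           call. = FALSE)
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), grid_shape = grid_shape,
         voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         n_volumes = as.integer(n_volumes), effect_rois = effect_rois,
         envelope_sd_control = envelope_sd_control,
         envelope_sd_patient = envelope_sd_patient,
         carrier_band_hz = carrier_band_hz, noise_sd = noise_sd,
         motion_spike_prob = motion_spike_prob,
         covariate_r_target = covariate_r_target, seed = as.integer(seed)),
    class = "simulation_params"
  )
}

# Two spheres in the anterior half of the grid, loosely bilateral, placed
# clear of the geometric WM core so smoothing bleed into the WM regressor
# stays small.
default_effect_rois <- function(grid_shape) {
  r <- max(2L, round(min(grid_shape) / 8))
  c1 <- round(grid_shape * c(1 / 3, 0.65, 1 / 2))
  c2 <- round(grid_shape * c(2 / 3, 0.65, 1 / 2))
  list(list(center = c1, radius = r), list(center = c2, radius = r))
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Disjoint ROI masks in spec order; a voxel reached by two spheres belongs
# to the earlier ROI.
roi_mask_list <- function(params) {
  taken <- array(FALSE, dim = params$grid_shape)
  out <- lapply(params$effect_rois, function(roi) {
    m <- sphere_mask(params$grid_shape, roi$center, roi$radius) & !taken
    taken <<- taken | m
    m
  })
  names(out) <- paste0("roi_", seq_along(out))
  out
}

sphere_mask <- function(grid_shape, center, radius) {
  ix <- array(0, dim = grid_shape)
  g <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                   k = seq_len(grid_shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(d2 <= radius^2, dim = grid_shape)
}

# Geometric tissue shells: brain ellipsoid, inner WM core, outer CSF rim.
tissue_masks <- function(grid_shape) {
  half <- grid_shape / 2
  g <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                   k = seq_len(grid_shape[3]))
  rho <- sqrt(((g$i - half[1] - 0.5) / (0.9 * half[1]))^2 +
              ((g$j - half[2] - 0.5) / (0.9 * half[2]))^2 +
              ((g$k - half[3] - 0.5) / (0.9 * half[3]))^2)
  rho <- array(rho, dim = grid_shape)
  brain <- rho <= 1
  csf <- rho > 0.88 & rho <= 1
  wm <- rho <= 0.25
  list(brain = brain, wm = wm, csf = csf)
}

# AR(1) (phi = 0.3) + white Gaussian mixture, unit marginal SD, n x v.
background_noise <- function(n, v, noise_sd) {
  phi <- 0.3
  innov <- matrix(stats::rnorm(n * v), n, v)
  ar <- stats::filter(innov, phi, method = "recursive")
  ar <- ar * sqrt(1 - phi^2)                # unit stationary variance
  white <- matrix(stats::rnorm(n * v), n, v)
  noise_sd * (ar + white) / sqrt(2)
}

# Band-limited unit-RMS carrier: per voxel, a sum of sinusoids at random
# in-band frequencies and phases.
carrier_signals <- function(t_s, v, band, k_components = 8L) {
  n <- length(t_s)
  out <- matrix(0, n, v)
  amp <- sqrt(2 / k_components)
  for (j in seq_len(v)) {
    f <- stats::runif(k_components, band[1], band[2])
    ph <- stats::runif(k_components, 0, 2 * pi)
    out[, j] <- cos(outer(2 * pi * t_s, f) + rep(ph, each = n)) %*%
      rep(amp, k_components)
  }
  out
}

# Slow sinusoidal envelope, period uniform in [200, 400] s -- long relative
# to the 100-s analysis window so windowed ALFF tracks it.
slow_envelope <- function(t_s, depth) {
  period <- stats::runif(1, 200, 400)
  phase <- stats::runif(1, 0, 2 * pi)
  1 + depth * sin(2 * pi * t_s / period + phase)
}

motion_trace <- function(n_volumes, spike_prob) {
  trans <- apply(matrix(stats::rnorm(n_volumes * 3, 0, 0.01), n_volumes), 2, cumsum)
  rot <- apply(matrix(stats::rnorm(n_volumes * 3, 0, 2e-4), n_volumes), 2, cumsum)
  spikes <- which(stats::runif(n_volumes) < spike_prob)
  spikes <- setdiff(spikes, 1L)
  for (s in spikes) {
    # transient displacement: the head jerks at volume s and settles back,
    # so FD spikes without accumulating drift toward the exclusion limit
    jump <- stats::runif(1, 0.8, 2) * sample(c(-1, 1), 1)
    axis <- sample(3L, 1)
    trans[s, axis] <- trans[s, axis] + jump
  }
  m <- tibble::tibble(
    trans_x = trans[, 1], trans_y = trans[, 2], trans_z = trans[, 3],
    rot_x = rot[, 1], rot_y = rot[, 2], rot_z = rot[, 3]
  )
  attr(m, "spike_volumes") <- spikes
  m
}

#' Generate one synthetic resting-state subject
#'
#' The BOLD series is, per voxel, AR(1)-plus-white background noise; inside
#' each effect ROI a band-limited oscillation is added whose amplitude is
#' modulated by a slow sinusoidal envelope (period 200-400 s) with the
#' group's modulation depth. Motion is a slow random walk with occasional
#' translation jumps of 0.8-2 mm, and tissue masks are geometric shells of
#' the grid.
#'
#' @param params A `simulation_params` object.
#' @param group `"patient"` or `"control"`.
#' @param subject_seed Integer seed for this subject's draws.
#' @param id Subject identifier.
#' @param envelope_depth_mult Optional multiplier on the group envelope
#'   depth (used by [generate_cohort()] to induce the VAS correlation).
#' @param vas Optional VAS value to record instead of an independent draw.
#' @return A `subject_record`: list with `id`, `group`, `bold`
#'   (a [bold_volume()]), `motion` (tibble, 6 columns), `masks`
#'   (brain/wm/csf logical arrays), and a one-row `covariates` tibble.
#' @export
generate_subject <- function(params, group, subject_seed,
                             id = paste0(substr(group, 1, 3), "_", subject_seed),
                             envelope_depth_mult = NULL, vas = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!group %in% c("patient", "control")) {
    stop("`group` must be \"patient\" or \"control\", got \"", group, "\".",
         call. = FALSE)
  }
  with_seed(subject_seed, {
    g <- params$grid_shape
    nt <- params$n_volumes
    t_s <- (seq_len(nt) - 1) * params$tr_s
    nvox <- prod(g)

    dat <- matrix(0, nt, nvox)
    if (params$noise_sd > 0) {
      dat <- background_noise(nt, nvox, params$noise_sd)
      # Globally coherent slow fluctuation (respiration/drift analogue):
      # this is what the global/WM/CSF regressors should be capturing, so
      # that nuisance regression does not instead chase the ROI signal.
      g_sig <- carrier_signals(t_s, 1L,
                               c(0.005, min(0.1, 0.4 / params$tr_s)),
                               k_components = 12L)
      w <- stats::runif(nvox, 0.7, 1.3)
      dat <- dat + (0.6 * params$noise_sd * g_sig[, 1]) %o% w
    }

    base_depth <- if (group == "patient") params$envelope_sd_patient
                  else params$envelope_sd_control
    if (is.null(envelope_depth_mult)) {
      envelope_depth_mult <- exp(stats::rnorm(1, 0, 0.2))
    }
    depth <- base_depth * envelope_depth_mult

    for (m in roi_mask_list(params)) {
      idx <- which(as.vector(m))
      # ROI voxels share most of their carrier (local BOLD coherence);
      # the rest is voxel-specific. Both ride the same slow envelope.
      w_shared <- 0.7
      shared <- carrier_signals(t_s, 1L, params$carrier_band_hz)
      own <- carrier_signals(t_s, length(idx), params$carrier_band_hz)
      carrier <- sqrt(w_shared) * shared[, rep(1L, length(idx))] +
        sqrt(1 - w_shared) * own
      env <- slow_envelope(t_s, depth)
      dat[, idx] <- dat[, idx] + carrier * env
    }

    bold <- bold_volume(array(t(dat), dim = c(g, nt)),
                        affine = diag(c(rep(params$voxel_size_mm, 3), 1)),
                        tr_s = params$tr_s)

    motion <- motion_trace(nt, params$motion_spike_prob)
    masks <- tissue_masks(g)

    if (group == "patient") {
      age <- stats::rnorm(1, 31.19, 6.38)
      sex <- sample(c("female", "male"), 1, prob = c(16, 5) / 21)
      duration <- stats::rlnorm(1, meanlog = 3.2, sdlog = 1.0)
      if (is.null(vas)) vas <- pmin(10, pmax(0, stats::rnorm(1, 4.33, 1.46)))
    } else {
      age <- stats::rnorm(1, 30.19, 6.3)
      sex <- sample(c("female", "male"), 1, prob = c(13, 8) / 21)
      duration <- NA_real_
      vas <- NA_real_
    }

    covariates <- tibble::tibble(
      id = id, group = group, age = age, sex = sex,
      vas = vas, duration_months = duration
    )

    structure(
      list(id = id, group = group, bold = bold, motion = motion,
           masks = masks, covariates = covariates,
           envelope_depth = depth),
      class = "subject_record"
    )
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s)\n", x$id, x$group))
  print(x$bold)
  invisible(x)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws `n_per_group` patients and controls with per-subject seeds derived
#' deterministically from `params$seed`. Patient VAS scores are drawn at
#' the target correlation with each patient's *realized* in-ROI dALFF
#' (computed on the generated BOLD before any preprocessing, standardized
#' across patients), then rescaled to the clinical scale (mean 4.33,
#' SD 1.46, clipped to 0-10). Targeting the realized quantity rather than
#' the underlying envelope depth keeps the correlation recoverable by the
#' analysis pipeline.
#'
#' @param params A `simulation_params` object.
#' @return A list of class `synthetic_cohort`:
#'   `subjects` (list of `subject_record`), `covariates` (tibble),
#'   `ground_truth` (ROI masks, per-ROI true effect direction/magnitude,
#'   the correlation target, and per-subject motion-spike indices).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_per_group

  seeds <- (as.numeric(params$seed) * 7919 + seq_len(2 * n) * 104729) %%
    2147483647
  seeds <- as.integer(seeds)

  subjects <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(
      params, "patient", seeds[i], id = sprintf("pat_%02d", i)
    )
  }
  for (i in seq_len(n)) {
    subjects[[n + i]] <- generate_subject(
      params, "control", seeds[n + i], id = sprintf("con_%02d", i)
    )
  }

  roi_masks <- roi_mask_list(params)

  # Patient VAS at the target correlation with the realized in-ROI dALFF,
  # measured the way the analysis pipeline measures it (preprocessing,
  # windowed ALFF variance, per-subject z-scoring). Envelope depth alone
  # underdetermines the measured value at these scan lengths, so targeting
  # the measured quantity is what makes the correlation recoverable.
  roi_union <- Reduce(`|`, roi_masks)
  win_len <- min(50L, (params$n_volumes - 10L) %/% 2L)
  proxy_win <- suppressWarnings(
    window_spec(win_len, 5L, tr_s = params$tr_s,
                f_min_hz = params$carrier_band_hz[1])
  )
  proxy_cfg <- analysis_config(band_hz = params$carrier_band_hz,
                               validation_lengths_tr = integer(0))
  proxy <- vapply(subjects[seq_len(n)], function(s) {
    gm <- s$masks$brain & !s$masks$wm & !s$masks$csf
    pre <- suppressMessages(preprocess_subject(s, proxy_cfg))
    m <- zscore_map(dalff(pre$bold, proxy_win, gm,
                          band = params$carrier_band_hz))
    mean(m$map[roi_union & gm])
  }, numeric(1))
  vas <- with_seed(params$seed + 1L, {
    r <- params$covariate_r_target
    if (stats::sd(proxy) > 0 && n >= 2L) {
      z <- r * scale(proxy)[, 1] +
        sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
      pmin(10, pmax(0, 4.33 + 1.46 * scale(z)[, 1]))
    } else {
      pmin(10, pmax(0, stats::rnorm(n, 4.33, 1.46)))
    }
  })
  for (i in seq_len(n)) {
    subjects[[i]]$covariates$vas <- vas[i]
  }

  effect <- params$envelope_sd_patient^2 - params$envelope_sd_control^2
  ground_truth <- list(
    roi_masks = roi_masks,
    true_group_effect = tibble::tibble(
      roi = names(roi_masks),
      direction = sign(effect),
      magnitude = abs(effect)
    ),
    true_covariate_r = params$covariate_r_target,
    spike_volumes = lapply(subjects, function(s) attr(s$motion, "spike_volumes"))
  )

  covariates <- dplyr::bind_rows(lapply(subjects, `[[`, "covariates"))

  structure(
    list(subjects = subjects, covariates = covariates,
         ground_truth = ground_truth, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d per group), grid %s, %d volumes\n",
              length(x$subjects), x$params$n_per_group,
              paste(x$params$grid_shape, collapse = "x"),
              x$params$n_volumes))
  invisible(x)
}
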