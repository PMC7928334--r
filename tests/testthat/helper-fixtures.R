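# Small-scale simulation parameters for fast tests.
tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(
    n_per_group = 3, grid_shape = c(12L, 12L, 12L), n_volumes = 120,
    seed = 42L
  )
  do.call(simulation_params, utils::modifyList(defaults, args))
}

# A bold_volume holding one sinusoid (plus optional envelope) in every
# voxel of a small grid.
sine_bold <- function(freq_hz, n_volumes = 120, tr_s = 2,
                      grid = c(4L, 4L, 4L), amplitude = 1,
                      envelope = NULL) {
  t_s <- (seq_len(n_volumes) - 1) * tr_s
  series <- amplitude * sin(2 * pi * freq_hz * t_s)
  if (!is.null(envelope)) series <- series * envelope
  arr <- array(rep(series, each = prod(grid)), dim = c(grid, n_volumes))
  bold_volume(arr, affine = diag(c(3, 3, 3, 1)), tr_s = tr_s)
}

full_mask <- function(grid = c(4L, 4L, 4L)) array(TRUE, dim = grid)

# Zero-motion table of n rows.
zero_motion <- function(n = 120) {
  m <- matrix(0, n, 6)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  as.data.frame(m)
}

# Sample of size n with exactly the given mean and SD.
sample_with_moments <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# dalff_map wrapper around raw values, for testing map utilities.
new_map_for_test <- function(values, mask) {
  arr <- array(values, dim = dim(mask))
  dynalff:::new_dalff_map(
    arr, mask, window = window_spec(50, 5, tr_s = 2),
    band = c(0.01, 0.08), n_windows = 2, standardized = FALSE
  )
}

# Pair of vectors with exactly the given Pearson correlation.
pair_with_correlation <- function(n, r, seed = 1) {
  raw <- withr::with_seed(seed, matrix(stats::rnorm(2 * n), n, 2))
  x <- scale(raw[, 1])[, 1]
  e <- stats::residuals(stats::lm(raw[, 2] ~ x))
  e <- scale(e)[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  list(x = x, y = y)
}

# Separable two-class feature tibble for classifier tests.
toy_features <- function(n_per_group = 6, sep = 3, seed = 1, p = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_group * p), ncol = p),
               matrix(rnorm(n_per_group * p, mean = sep), ncol = p))
    colnames(x) <- paste0("cluster_", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("s%02d", seq_len(2 * n_per_group)),
                     group = rep(c("patient", "control"), each = n_per_group)),
      tibble::as_tibble(x)
    )
  })
}

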