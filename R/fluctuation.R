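#' Minimum admissible sliding-window length
#'
#' The window must span at least one full cycle of the slowest frequency in
#' the analysis band: `length_tr * tr_s >= 1 / f_min`. At f_min = 0.01 Hz
#' and TR = 2 s this gives 50 TR (100 s).
#'
#' @param f_min_hz Lowest analysis frequency (Hz).
#' @param tr_s Repetition time (s).
#' @return Minimum window length in TR (integer).
#' @export
min_window_length <- function(f_min_hz = 0.01, tr_s = 2) {
  as.integer(ceiling(1 / (f_min_hz * tr_s)))
}

#' Sliding-window specification
#'
#' @param length_tr Window length in TR (default 50).
#' @param step_tr Step between window starts in TR (default 5).
#' @param tr_s Repetition time (s).
#' @param f_min_hz Lowest analysis frequency, used for the admissibility
#'   check. A window shorter than `1 / f_min_hz` cannot resolve the slowest
#'   band frequency; construction warns (it does not error, so that
#'   short-window sensitivity analyses remain expressible).
#' @return A `window_spec` object.
#' @export
window_spec <- function(length_tr = 50, step_tr = 5, tr_s = 2,
                        f_min_hz = 0.01) {
  length_tr <- as.integer(length_tr)
  step_tr <- as.integer(step_tr)
  if (step_tr < 1L) stop("`step_tr` must be >= 1.", call. = FALSE)
  if (length_tr < 2L) stop("`length_tr` must be >= 2.", call. = FALSE)
  min_len <- min_window_length(f_min_hz, tr_s)
  if (length_tr < min_len) {
    warning("Window of ", length_tr, " TR (", length_tr * tr_s,
            " s) is shorter than 1/f_min = ", 1 / f_min_hz,
            " s; the slowest band frequency is not resolved.", call. = FALSE)
  }
  structure(list(length_tr = length_tr, step_tr = step_tr, tr_s = tr_s,
                 f_min_hz = f_min_hz),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> length %d TR, step %d TR, TR = %g s\n",
              x$length_tr, x$step_tr, x$tr_s))
  invisible(x)
}

#' Enumerate sliding windows
#'
#' Windows are `[k*step + 1, k*step + length]` (1-based, inclusive) for
#' k = 0, 1, ...; trailing volumes not covered by a full window are
#' ignored, so `n_windows = floor((n_volumes - length) / step) + 1`.
#'
#' @param n_volumes Series length.
#' @param window A [window_spec()].
#' @return Tibble with `window`, `start`, `end`.
#' @export
sliding_windows <- function(n_volumes, window) {
  stopifnot(inherits(window, "window_spec"))
  if (window$length_tr > n_volumes) {
    stop("Window length ", window$length_tr, " exceeds series length ",
         n_volumes, ".", call. = FALSE)
  }
  n_win <- (n_volumes - window$length_tr) %/% window$step_tr + 1L
  starts <- (seq_len(n_win) - 1L) * window$step_tr + 1L
  ends <- starts + window$length_tr - 1L
  tibble::tibble(window = seq_len(n_win), start = starts, end = ends)
}

# In-band frequency bin selection for a series of length n at sampling tr_s.
# Returns the (1-based) FFT bin indices whose frequency lies in [low, high].
band_bins <- function(n, tr_s, band) {
  k <- 0:(n %/% 2)
  f <- k / (n * tr_s)
  idx <- which(f >= band[1] & f <= band[2])
  if (length(idx) == 0L) {
    stop("Band [", band[1], ", ", band[2], "] Hz contains no frequency bin; ",
         "resolution is ", signif(1 / (n * tr_s), 3), " Hz for ", n,
         " samples at TR = ", tr_s, " s.", call. = FALSE)
  }
  idx  # index into k+1, i.e. FFT bin idx corresponds to frequency (idx-1)/(n*tr)
}

#' Amplitude of low-frequency fluctuations of one series
#'
#' The series is linearly detrended, Fourier transformed, and the amplitude
#' spectrum taken as the square root of the periodogram power at each
#' positive-frequency bin; ALFF is the mean amplitude over the bins falling
#' inside the band.
#'
#' @param series Numeric time series.
#' @param tr_s Repetition time (s).
#' @param band Length-2 frequency interval in Hz (default `c(0.01, 0.08)`).
#' @return Scalar ALFF (signal-amplitude units).
#' @export
alff <- function(series, tr_s, band = c(0.01, 0.08)) {
  if (any(!is.finite(series))) stop("Series contains non-finite values.",
                                    call. = FALSE)
  n <- length(series)
  y <- detrend_linear(matrix(series, ncol = 1))
  idx <- band_bins(n, tr_s, band)
  amp <- amplitude_spectrum(y, n)
  mean(amp[idx, 1])
}

# Amplitude spectrum of time x voxel matrix: sqrt of periodogram power,
# rows = bins 1..(n/2 + 1).
amplitude_spectrum <- function(y, n) {
  co <- stats::mvfft(y)
  half <- n %/% 2 + 1L
  Mod(co[seq_len(half), , drop = FALSE]) / sqrt(n)
}

#' Dynamic ALFF map: variance of windowed ALFF
#'
#' For each in-mask voxel, ALFF is computed inside every sliding window
#' (each window independently linearly detrended), and the sample variance
#' (denominator `n_windows - 1`) of those per-window ALFF values is the
#' voxel's dALFF. The raw (unstandardized) map is returned; see
#' [zscore_map()].
#'
#' @param bold A preprocessed [bold_volume()].
#' @param window A [window_spec()].
#' @param mask Logical 3D array of analysis voxels.
#' @param band Analysis band in Hz.
#' @return A `dalff_map`: 3D array of per-voxel variances with the mask,
#'   window and band attached.
#' @export
dalff <- function(bold, window, mask, band = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold_volume"), inherits(window, "window_spec"))
  wins <- sliding_windows(n_volumes(bold), window)
  if (nrow(wins) < 2L) {
    stop("Need >= 2 windows for a variance; got ", nrow(wins), ".",
         call. = FALSE)
  }
  y <- mask_series(bold, mask)              # time x voxel
  len <- window$length_tr
  idx <- band_bins(len, bold$tr_s, band)
  alff_w <- matrix(0, ncol(y), nrow(wins))  # voxel x window
  for (w in seq_len(nrow(wins))) {
    seg <- y[wins$start[w]:wins$end[w], , drop = FALSE]
    seg <- detrend_linear(seg)
    amp <- amplitude_spectrum(seg, len)
    alff_w[, w] <- colMeans(amp[idx, , drop = FALSE])
  }
  v <- apply(alff_w, 1, stats::var)
  new_dalff_map(unmask_map(v, mask), mask, window, band,
                n_windows = nrow(wins), standardized = FALSE)
}

#' Static ALFF map
#'
#' ALFF over the full series per in-mask voxel (no windowing).
#'
#' @inheritParams dalff
#' @return An `alff_map`: 3D array with mask and band attached.
#' @export
alff_map <- function(bold, mask, band = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold_volume"))
  y <- detrend_linear(mask_series(bold, mask))
  n <- nrow(y)
  idx <- band_bins(n, bold$tr_s, band)
  amp <- amplitude_spectrum(y, n)
  vals <- colMeans(amp[idx, , drop = FALSE])
  structure(list(map = unmask_map(vals, mask), mask = mask, band = band),
            class = "alff_map")
}

new_dalff_map <- function(map, mask, window, band, n_windows, standardized) {
  structure(
    list(map = map, mask = mask, window = window, band = band,
         n_windows = n_windows, standardized = standardized),
    class = "dalff_map"
  )
}

#' @export
print.dalff_map <- function(x, ...) {
  d <- dim(x$map)
  cat(sprintf("<dalff_map> %dx%dx%d, %d in-mask voxels, %d windows (%d TR / %d TR)%s\n",
              d[1], d[2], d[3], sum(x$mask), x$n_windows,
              x$window$length_tr, x$window$step_tr,
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}

#' Z-standardize a dALFF map across in-mask voxels
#'
#' Subtracts the in-mask mean and divides by the in-mask SD, per subject.
#' Out-of-mask voxels stay 0 and are excluded from the moments.
#' Idempotent up to floating point: z-scoring a z-scored map leaves it
#' unchanged.
#'
#' @param map A `dalff_map`.
#' @return The standardized `dalff_map`.
#' @export
zscore_map <- function(map) {
  stopifnot(inherits(map, "dalff_map"))
  v <- map$map[map$mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("In-mask SD is zero; cannot z-score.", call. = FALSE)
  }
  out <- map
  out$map[map$mask] <- (v - mean(v)) / s
  out$map[!map$mask] <- 0
  out$standardized <- TRUE
  out
}

#' Write a dALFF/ALFF map as NIfTI with a JSON sidecar
#'
#' @param map A `dalff_map` or `alff_map`.
#' @param path Output NIfTI path (.nii or .nii.gz); the sidecar replaces
#'   the extension with .json.
#' @param affine 4x4 affine for the output grid.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, affine = diag(4)) {
  write_nifti_vol(map$map, path, affine = affine)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(band_hz = map$band)
  if (inherits(map, "dalff_map")) {
    meta$window_length_tr <- map$window$length_tr
    meta$window_step_tr <- map$window$step_tr
    meta$n_windows <- map$n_windows
    meta$standardized <- map$standardized
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
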