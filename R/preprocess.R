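#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes (magnetization-equilibration frames);
#' affine and TR are unchanged.
#'
#' @param bold A [bold_volume()].
#' @param n_discard Number of leading volumes to drop (default 10).
#' @return A [bold_volume()] with `n_volumes - n_discard` volumes.
#' @export
discard_initial <- function(bold, n_discard = 10) {
  stopifnot(inherits(bold, "bold_volume"))
  nt <- n_volumes(bold)
  if (n_discard >= nt) {
    stop("Cannot discard ", n_discard, " volumes from a series of ", nt, ".",
         call. = FALSE)
  }
  if (n_discard == 0) return(bold)
  bold_volume(bold$data[, , , (n_discard + 1):nt, drop = FALSE],
              affine = bold$affine, tr_s = bold$tr_s)
}

check_motion <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) {
    stop("Motion table must have 6 columns (3 translations mm, 3 rotations rad), got ",
         ncol(m), ".", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("Motion table needs >= 2 rows.", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Framewise displacement (Power formulation)
#'
#' FD at volume t is the sum of absolute frame-to-frame changes of the three
#' translations (mm) plus the three rotations (radians) converted to arc
#' length on a sphere of `sphere_radius_mm`. The first volume's FD is 0 by
#' convention.
#'
#' @param motion Data frame or matrix with 6 columns: translations (mm)
#'   then rotations (radians).
#' @param sphere_radius_mm Radius used to convert rotations to mm
#'   (default 50).
#' @param threshold Scrubbing threshold carried along (mm, default 0.5).
#' @return A tibble with columns `volume`, `fd` and the threshold as an
#'   attribute.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50, threshold = 0.5) {
  m <- check_motion(motion)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble::tibble(volume = seq_len(nrow(m)), fd = fd)
  attr(out, "threshold") <- threshold
  class(out) <- c("fd_series", class(out))
  out
}

#' Motion quality-control verdict
#'
#' A subject is excluded if any absolute translation exceeds `max_trans_mm`
#' or any absolute rotation exceeds `max_rot_deg` at any time point.
#'
#' @param motion 6-column motion table (translations mm, rotations rad).
#' @param max_trans_mm Translation limit (default 3 mm).
#' @param max_rot_deg Rotation limit (default 3 degrees).
#' @return A list with `exclude` (logical) and `reason` (string or `NA`).
#' @export
qc_exclude <- function(motion, max_trans_mm = 3, max_rot_deg = 3) {
  m <- check_motion(motion)
  max_trans <- max(abs(m[, 1:3]))
  max_rot_deg_obs <- max(abs(m[, 4:6])) * 180 / pi
  exclude <- max_trans > max_trans_mm || max_rot_deg_obs > max_rot_deg
  reason <- if (!exclude) NA_character_
    else if (max_trans > max_trans_mm)
      sprintf("max translation %.2f mm > %g mm", max_trans, max_trans_mm)
    else
      sprintf("max rotation %.2f deg > %g deg", max_rot_deg_obs, max_rot_deg)
  list(exclude = exclude, reason = reason,
       max_trans_mm = max_trans, max_rot_deg = max_rot_deg_obs)
}

#' Scrub high-motion volumes
#'
#' Volumes whose FD meets or exceeds the threshold are dropped together
#' with `n_before` preceding and `n_after` following volumes (clamped at
#' the series boundaries). The result records, per volume, whether it is
#' kept and which rule dropped it.
#'
#' @param fd Output of [compute_fd()] (or any tibble with `fd`), with a
#'   `threshold` attribute or via the `threshold` argument.
#' @param n_before,n_after Neighborhood sizes (defaults 2 and 1).
#' @param threshold FD threshold in mm; defaults to the series' attribute.
#' @return A tibble `volume`, `keep`, `reason`
#'   (`"fd_spike"` / `"neighbor"` / `NA`).
#' @export
scrub <- function(fd, n_before = 2, n_after = 1, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(fd, "threshold") %||% 0.5
  if (threshold <= 0) stop("FD threshold must be > 0.", call. = FALSE)
  v <- fd$fd
  n <- length(v)
  flagged <- which(v >= threshold)
  drop <- logical(n)
  neighbor <- logical(n)
  for (i in flagged) {
    lo <- max(1L, i - n_before); hi <- min(n, i + n_after)
    neighbor[lo:hi] <- TRUE
  }
  neighbor[flagged] <- FALSE
  drop[flagged] <- TRUE
  keep <- !(drop | neighbor)
  tibble::tibble(
    volume = seq_len(n), keep = keep,
    reason = dplyr::case_when(drop ~ "fd_spike", neighbor ~ "neighbor",
                              TRUE ~ NA_character_)
  )
}

#' Friston 24-parameter motion regressor block
#'
#' Expands the 6 rigid-body parameters into 24 regressors: the parameters,
#' their one-volume lags, and the squares of both. Lagged rows at t = 1 are
#' zero-filled.
#'
#' @param motion 6-column motion table.
#' @return Numeric matrix with 24 labelled columns.
#' @export
friston24 <- function(motion) {
  m <- check_motion(motion)
  lag1 <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag1, m^2, lag1^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Build the nuisance design matrix
#'
#' Friston-24 motion block plus mean white-matter, CSF and global (brain)
#' signals and an intercept. Constant duplicate columns are dropped with a
#' message; a design that remains rank-deficient is an error.
#'
#' @param motion 6-column motion table (rows matching the BOLD volumes).
#' @param bold A [bold_volume()].
#' @param masks List with logical arrays `brain`, `wm`, `csf`.
#' @return Numeric design matrix (n_volumes x k) with an `"intercept"`
#'   column.
#' @export
nuisance_design <- function(motion, bold, masks) {
  f24 <- friston24(motion)
  if (nrow(f24) != n_volumes(bold)) {
    stop("Motion table has ", nrow(f24), " rows but BOLD has ",
         n_volumes(bold), " volumes.", call. = FALSE)
  }
  wm <- rowMeans(mask_series(bold, masks$wm))
  csf <- rowMeans(mask_series(bold, masks$csf))
  global <- rowMeans(mask_series(bold, masks$brain))
  x <- cbind(f24, wm = wm, csf = csf, global = global,
             intercept = rep(1, nrow(f24)))
  drop_constant_duplicates(x)
}

# Drop non-intercept columns that are constant (duplicating the intercept).
drop_constant_duplicates <- function(x) {
  const <- apply(x, 2, function(col) max(col) - min(col) < .Machine$double.eps)
  const["intercept"] <- FALSE
  if (any(const)) {
    message("Dropping constant nuisance columns: ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  x
}

#' Voxel-wise nuisance regression
#'
#' Per voxel, returns the residuals of ordinary least squares of the time
#' series on the design (intercept included), so each voxel's output is
#' mean-zero.
#'
#' @param bold A [bold_volume()].
#' @param design Numeric matrix with `n_volumes` rows.
#' @return A [bold_volume()] of residuals.
#' @export
nuisance_regress <- function(bold, design) {
  stopifnot(inherits(bold, "bold_volume"))
  x <- as.matrix(design)
  if (nrow(x) != n_volumes(bold)) {
    stop("Design has ", nrow(x), " rows but BOLD has ", n_volumes(bold),
         " volumes.", call. = FALSE)
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("Nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- dim(bold$data)
  y <- matrix(bold$data, prod(d[1:3]), d[4])
  resid <- t(qr.resid(qr_x, t(y)))
  bold_volume(array(resid, dim = d), affine = bold$affine, tr_s = bold$tr_s)
}

gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Banded convolution matrix for one axis (zero padding at boundaries).
conv_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  k <- matrix(0, n, n)
  for (off in -half:half) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1 & j <= n
    k[cbind(idx[ok], j[ok])] <- kernel[off + half + 1L]
  }
  k
}

smooth_volume_3d <- function(vol, kmats) {
  d <- dim(vol)
  # axis 1
  v <- kmats[[1]] %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(v, d)
  # axis 2
  vol <- aperm(vol, c(2, 1, 3))
  v <- kmats[[2]] %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(v, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  vol <- aperm(vol, c(3, 1, 2))
  v <- kmats[[3]] %*% matrix(vol, d[3], d[1] * d[2])
  aperm(array(v, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume with a separable Gaussian of
#' `sigma = fwhm / (sqrt(8 log 2) * voxel_size)` voxels per axis. Total
#' intensity is conserved up to boundary truncation (zero padding).
#'
#' @param x A [bold_volume()] or a 3D array.
#' @param fwhm_mm Full width at half maximum in mm (default 6).
#' @param voxel_size_mm Voxel size for bare arrays; taken from the affine
#'   for `bold_volume` input.
#' @return Same type as the input, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, voxel_size_mm = NULL) {
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be > 0.", call. = FALSE)
  is_bold <- inherits(x, "bold_volume")
  if (is_bold) {
    vs <- voxel_size_mm(x$affine)
    arr <- x$data
  } else {
    if (is.null(voxel_size_mm)) {
      stop("`voxel_size_mm` is required for array input.", call. = FALSE)
    }
    vs <- rep(voxel_size_mm, length.out = 3)
    arr <- x
  }
  sigma_vox <- fwhm_mm / (sqrt(8 * log(2)) * vs)
  d3 <- dim(arr)[1:3]
  kmats <- lapply(1:3, function(a) conv_matrix(d3[a], gaussian_kernel_1d(sigma_vox[a])))
  if (length(dim(arr)) == 3L) {
    out <- smooth_volume_3d(arr, kmats)
    return(if (is_bold) bold_volume(out, x$affine, x$tr_s) else out)
  }
  nt <- dim(arr)[4]
  out <- arr
  for (t in seq_len(nt)) {
    out[, , , t] <- smooth_volume_3d(arr[, , , t], kmats)
  }
  if (is_bold) bold_volume(out, x$affine, x$tr_s) else out
}

#' Ideal band-pass temporal filter
#'
#' Removes the linear trend per voxel, transforms to the frequency domain,
#' zeroes all coefficients whose frequency falls outside
#' `[low_hz, high_hz]` (DC always removed), and inverse transforms. This is
#' the rectangular frequency-domain filter used by the classic
#' resting-state toolkits.
#'
#' @param bold A [bold_volume()].
#' @param low_hz,high_hz Pass band edges in Hz (defaults 0.01 and 0.08).
#' @return A filtered [bold_volume()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(bold, "bold_volume"))
  nyq <- 1 / (2 * bold$tr_s)
  if (high_hz <= low_hz) stop("Empty pass band.", call. = FALSE)
  if (high_hz > nyq) {
    stop("`high_hz` = ", high_hz, " Hz exceeds Nyquist (", nyq,
         " Hz at TR = ", bold$tr_s, " s).", call. = FALSE)
  }
  d <- dim(bold$data)
  nt <- d[4]
  y <- t(matrix(bold$data, prod(d[1:3]), nt))  # time x voxel
  y <- detrend_linear(y)
  freqs <- (seq_len(nt) - 1) / (nt * bold$tr_s)
  freqs <- pmin(freqs, 1 / bold$tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  co <- stats::mvfft(y)
  co[!keep, ] <- 0
  filt <- Re(stats::mvfft(co, inverse = TRUE)) / nt
  bold_volume(array(t(filt), dim = d), affine = bold$affine, tr_s = bold$tr_s)
}

# Remove per-column linear trend (least squares on time index).
detrend_linear <- function(y) {
  n <- nrow(y)
  tt <- seq_len(n)
  x <- cbind(1, tt - mean(tt))
  y - x %*% qr.solve(x, y)
}

#' Apply a retention mask to BOLD and motion
#'
#' In `"delete"` mode the dropped volumes are removed; in `"interpolate"`
#' mode they are replaced by linear interpolation between the nearest kept
#' volumes (series length unchanged). Deletion changes the effective
#' sampling and distorts spectra; interpolation preserves the time base.
#'
#' @param bold A [bold_volume()].
#' @param retention Output of [scrub()].
#' @param mode `"delete"` or `"interpolate"`.
#' @return A [bold_volume()].
#' @export
apply_scrub <- function(bold, retention, mode = c("delete", "interpolate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bold, "bold_volume"))
  keep <- retention$keep
  if (length(keep) != n_volumes(bold)) {
    stop("Retention mask length ", length(keep), " != volume count ",
         n_volumes(bold), ".", call. = FALSE)
  }
  if (all(keep)) return(bold)
  if (sum(keep) < 2L) stop("Scrubbing would retain < 2 volumes.", call. = FALSE)
  if (mode == "delete") {
    return(bold_volume(bold$data[, , , keep, drop = FALSE],
                       affine = bold$affine, tr_s = bold$tr_s))
  }
  d <- dim(bold$data)
  y <- matrix(bold$data, prod(d[1:3]), d[4])
  kept_idx <- which(keep)
  bad_idx <- which(!keep)
  y[, bad_idx] <- t(apply(y[, kept_idx, drop = FALSE], 1, function(row) {
    stats::approx(kept_idx, row, xout = bad_idx, rule = 2)$y
  }))
  bold_volume(array(y, dim = d), affine = bold$affine, tr_s = bold$tr_s)
}

#' Preprocess one subject
#'
#' Runs the default per-subject chain: discard initial volumes, spatial
#' smoothing, nuisance regression (Friston-24 + WM + CSF + global +
#' intercept), band-pass filtering, then FD-based scrubbing. Returns the
#' cleaned BOLD together with a QC row and a per-stage provenance log.
#'
#' @param subject A `subject_record` (see [generate_subject()]).
#' @param config An [analysis_config()].
#' @return List with `bold` (cleaned), `qc` (one-row tibble), `retention`
#'   (scrub table), `log` (character vector of stage entries).
#' @export
preprocess_subject <- function(subject, config = analysis_config()) {
  log <- character()
  nt0 <- n_volumes(subject$bold)
  bold <- discard_initial(subject$bold, config$n_discard)
  motion <- as.matrix(subject$motion)[(config$n_discard + 1):nt0, , drop = FALSE]
  log <- c(log, sprintf("discard: %d -> %d volumes", nt0, n_volumes(bold)))

  verdict <- qc_exclude(motion, config$max_trans_mm, config$max_rot_deg)
  fd <- compute_fd(motion, threshold = config$fd_threshold_mm)

  bold <- smooth_gaussian(bold, config$fwhm_mm)
  log <- c(log, sprintf("smooth: FWHM %g mm", config$fwhm_mm))

  design <- nuisance_design(motion, bold, subject$masks)
  bold <- nuisance_regress(bold, design)
  log <- c(log, sprintf("regress: %d nuisance columns", ncol(design)))

  bold <- bandpass(bold, config$band_hz[1], config$band_hz[2])
  log <- c(log, sprintf("bandpass: %g-%g Hz", config$band_hz[1], config$band_hz[2]))

  retention <- scrub(fd, config$scrub_before, config$scrub_after,
                     threshold = config$fd_threshold_mm)
  bold <- apply_scrub(bold, retention, mode = config$scrub_mode)
  log <- c(log, sprintf("scrub (%s): kept %d / %d volumes", config$scrub_mode,
                        sum(retention$keep), nrow(retention)))

  qc <- tibble::tibble(
    id = subject$id, group = subject$group,
    mean_fd = mean(fd$fd), max_trans_mm = verdict$max_trans_mm,
    max_rot_deg = verdict$max_rot_deg,
    volumes_kept = if (config$scrub_mode == "delete") n_volumes(bold)
                   else sum(retention$keep),
    exclude = verdict$exclude, exclude_reason = verdict$reason
  )
  list(bold = bold, qc = qc, retention = retention, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
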