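#' Voxel-wise two-sample t-map
#'
#' Pooled-variance two-sample t-test per in-mask voxel between two lists of
#' standardized dALFF maps, contrast `a - b`, with
#' `df = n_a + n_b - 2`. Voxels with zero pooled variance get t = 0 (with a
#' message).
#'
#' @param maps_a,maps_b Lists of `dalff_map` objects on the same grid.
#' @param mask Logical 3D analysis mask.
#' @param contrast Label stored with the map (default
#'   `"a - b"`).
#' @return A `stat_map`: 3D t-value array, `df`, `mask`, `contrast`.
#' @export
two_sample_t_map <- function(maps_a, maps_b, mask,
                             contrast = "a - b") {
  xa <- stack_maps(maps_a, mask)    # subject x voxel
  xb <- stack_maps(maps_b, mask)
  if (ncol(xa) != ncol(xb)) stop("Map grids do not match.", call. = FALSE)
  n1 <- nrow(xa); n2 <- nrow(xb)
  if (n1 < 2L || n2 < 2L) stop("Need >= 2 maps per group.", call. = FALSE)
  m1 <- colMeans(xa); m2 <- colMeans(xb)
  v1 <- colVars(xa); v2 <- colVars(xb)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  zero <- !is.finite(t)
  if (any(zero)) {
    message(sum(zero), " voxel(s) had zero pooled variance; t set to 0.")
    t[zero] <- 0
  }
  structure(
    list(map = unmask_map(t, mask), df = df, mask = mask, contrast = contrast),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$map)
  cat(sprintf("<stat_map> t (%s), df = %d, %dx%dx%d, %d in-mask voxels\n",
              x$contrast, x$df, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

stack_maps <- function(maps, mask) {
  rows <- lapply(maps, function(m) {
    if (inherits(m, "dalff_map")) {
      if (!all(dim(m$map) == dim(mask))) stop("Map grid does not match mask.",
                                              call. = FALSE)
      m$map[mask]
    } else {
      if (!all(dim(m) == dim(mask))) stop("Map grid does not match mask.",
                                          call. = FALSE)
      m[mask]
    }
  })
  do.call(rbind, rows)
}

colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Residual-based spatial smoothness estimation
#'
#' Estimates the effective per-axis FWHM of the spatial noise from a set of
#' residual maps: each map is variance-normalized per voxel across maps,
#' the variance of spatial first differences along each axis is compared
#' with the field variance, and the Gaussian-field relation
#' `FWHM = voxel_size * sqrt(4 log 2 / lambda)` (lambda = normalized
#' derivative variance) gives the FWHM. RESELs are the in-mask volume
#' divided by the product of the three FWHMs.
#'
#' @param residual_maps List of 3D arrays (e.g. per-subject deviations from
#'   the group mean).
#' @param mask Logical 3D analysis mask.
#' @param voxel_size_mm Length-3 (or scalar) voxel size in mm.
#' @return A `smoothness_estimate`: `fwhm_mm` (length 3), `resel_count`,
#'   `n_residual_maps`.
#' @export
estimate_smoothness <- function(residual_maps, mask, voxel_size_mm) {
  if (length(residual_maps) < 3L) {
    stop("Need >= 3 residual maps to estimate smoothness.", call. = FALSE)
  }
  vs <- rep(voxel_size_mm, length.out = 3)
  arr <- simplify2array(residual_maps)           # x,y,z,map
  n_maps <- length(residual_maps)
  arr <- sweep(arr, 1:3, apply(arr, 1:3, mean))  # center across maps
  ss <- apply(arr^2, 1:3, sum)                   # per-voxel sum of squares
  if (all(ss[mask] < .Machine$double.eps)) {
    stop("Residual maps are constant across maps; smoothness undefined.",
         call. = FALSE)
  }

  # Neighbor correlation per axis, each pair jointly normalized
  # (sum u_x u_y / sqrt(sum u_x^2 * sum u_y^2)): nearly unbiased even for
  # few maps, unlike normalizing each voxel separately. For a Gaussian
  # autocorrelation, lambda = 2 (1 - rho) and FWHM follows.
  d <- dim(mask)
  lambda <- numeric(3)
  for (axis in 1:3) {
    lo <- hi <- lapply(d, seq_len)
    lo[[axis]] <- seq_len(d[axis] - 1L)
    hi[[axis]] <- 2:d[axis]
    take <- function(x, idx) do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    cxy <- array(0, dim = d - (axis == 1:3))
    for (m in seq_len(n_maps)) {
      u <- arr[, , , m]
      cxy <- cxy + take(u, lo) * take(u, hi)
    }
    cxx <- take(ss, lo); cyy <- take(ss, hi)
    ok <- diff_mask_along(mask, axis) & cxx > 0 & cyy > 0
    rho <- mean(cxy[ok] / sqrt(cxx[ok] * cyy[ok]))
    lambda[axis] <- 2 * max(1e-8, 1 - rho)
  }
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  fwhm_mm <- fwhm_vox * vs
  mask_vol <- sum(mask) * prod(vs)
  structure(
    list(fwhm_mm = fwhm_mm, resel_count = mask_vol / prod(fwhm_mm),
         n_residual_maps = n_maps),
    class = "smoothness_estimate"
  )
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM = %.2f x %.2f x %.2f mm, %.1f RESELs (%d maps)\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$resel_count,
              x$n_residual_maps))
  invisible(x)
}

diff_along <- function(u, axis) {
  d <- dim(u)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  up <- aperm(u, perm)
  dd <- apply(up, 2:3, diff)
  inv <- order(perm)
  aperm(array(dd, dim = dim(up) - c(1, 0, 0)), inv)
}

# Pairs (i, i+1) along `axis` with both voxels in the mask.
diff_mask_along <- function(mask, axis) {
  d <- dim(mask)
  idx_lo <- idx_hi <- lapply(d, seq_len)
  idx_lo[[axis]] <- seq_len(d[axis] - 1L)
  idx_hi[[axis]] <- 2:d[axis]
  m_lo <- do.call(`[`, c(list(mask), idx_lo, list(drop = FALSE)))
  m_hi <- do.call(`[`, c(list(mask), idx_hi, list(drop = FALSE)))
  m_lo & m_hi
}

# Connectivity offsets for 6 / 18 / 26 neighborhoods.
connectivity_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  n_nonzero <- rowSums(g != 0)
  keep <- switch(as.character(connectivity),
                 "6" = n_nonzero == 1,
                 "18" = n_nonzero >= 1 & n_nonzero <= 2,
                 "26" = n_nonzero >= 1,
                 stop("`connectivity` must be 6, 18 or 26.", call. = FALSE))
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D mask
#'
#' Breadth-first labeling under 6-, 18- or 26-connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer 3D array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dim = d)
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0L) return(labels)
  lab <- 0L
  for (r in seq_len(nrow(vox))) {
    i <- vox[r, 1]; j <- vox[r, 2]; k <- vox[r, 3]
    if (labels[i, j, k] != 0L) next
    lab <- lab + 1L
    queue <- matrix(c(i, j, k), ncol = 3)
    labels[i, j, k] <- lab
    while (nrow(queue) > 0L) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) next
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- mask[lin] & labels[lin] == 0L
      if (any(new)) {
        labels[lin[new]] <- lab
        queue <- rbind(queue, nb[new, , drop = FALSE])
      }
    }
  }
  labels
}

#' Extract cluster records from a thresholded map
#'
#' One record per connected component: extent, the peak-|value| voxel, the
#' signed value there, and its mm coordinates under the affine.
#'
#' @param values 3D array of (signed) statistic values.
#' @param above Logical 3D array of suprathreshold voxels.
#' @param affine 4x4 voxel-to-mm affine.
#' @param connectivity 6, 18 or 26.
#' @return Tibble: `cluster`, `extent_voxels`, `peak_t`, `peak_x`,
#'   `peak_y`, `peak_z` (mm), plus `peak_ijk` list-column of voxel indices.
#' @export
cluster_peaks <- function(values, above, affine = diag(4), connectivity = 26) {
  labels <- label_components(above, connectivity)
  n_cl <- max(labels)
  if (n_cl == 0L) return(empty_cluster_table())
  recs <- lapply(seq_len(n_cl), function(l) {
    idx <- which(labels == l)
    vals <- values[idx]
    peak_lin <- idx[which.max(abs(vals))]
    ijk <- arrayInd(peak_lin, dim(values))
    mm <- voxel_to_mm(ijk, affine)
    tibble::tibble(
      cluster = l, extent_voxels = length(idx),
      peak_t = values[peak_lin],
      peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
      peak_ijk = list(as.integer(ijk))
    )
  })
  dplyr::bind_rows(recs)
}

empty_cluster_table <- function() {
  tibble::tibble(cluster = integer(), extent_voxels = integer(),
                 peak_t = numeric(), peak_x = numeric(), peak_y = numeric(),
                 peak_z = numeric(), peak_ijk = list(),
                 corrected_p = numeric(), sign = character())
}

# Expected-cluster GRF quantities for a 3D Gaussian field thresholded at z.
# EC density (3D): rho3(z) = (4 log 2)^{3/2} (2 pi)^{-2} (z^2 - 1) exp(-z^2/2).
grf_cluster_p <- function(extent_voxels, z_thr, resels, n_mask_voxels) {
  em <- resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (z_thr^2 - 1) *
    exp(-z_thr^2 / 2)
  em <- max(em, .Machine$double.eps)
  en <- n_mask_voxels * stats::pnorm(z_thr, lower.tail = FALSE) / em
  beta <- (gamma(5 / 2) / en)^(2 / 3)        # P(n >= k) = exp(-beta k^{2/3})
  p_ge_k <- exp(-beta * extent_voxels^(2 / 3))
  1 - exp(-em * p_ge_k)
}

#' Gaussian-random-field cluster-level inference
#'
#' Converts the t-map to z (via probability integral transform), thresholds
#' each tail at the one-sided `cluster_forming_p`, labels connected
#' components, and assigns each a GRF cluster-level corrected p-value from
#' the expected-cluster-count and cluster-extent distributions for 3D
#' Gaussian fields. The two tails are tested as two one-sided passes at
#' `cluster_alpha / 2` each and merged into one table with signed peak t.
#'
#' @param stat A `stat_map` from [two_sample_t_map()].
#' @param smooth A `smoothness_estimate`.
#' @param cluster_forming_p One-sided voxel-level threshold (default 0.01).
#' @param cluster_alpha Two-sided cluster-level significance (default 0.05).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param affine Voxel-to-mm affine for peak coordinates.
#' @return A `cluster_table` tibble: significant clusters only, columns as
#'   [cluster_peaks()] plus `corrected_p` and `sign`; empty if none.
#' @export
grf_cluster_inference <- function(stat, smooth, cluster_forming_p = 0.01,
                                  cluster_alpha = 0.05, connectivity = 26,
                                  affine = diag(4)) {
  stopifnot(inherits(stat, "stat_map"), inherits(smooth, "smoothness_estimate"))
  if (cluster_forming_p <= 0 || cluster_forming_p > 0.05) {
    stop("`cluster_forming_p` must lie in (0, 0.05].", call. = FALSE)
  }
  # t -> z via tail probability, numerically stable through log p.
  tmap <- stat$map
  z <- array(0, dim = dim(tmap))
  lp <- stats::pt(abs(tmap[stat$mask]), df = stat$df,
                  lower.tail = FALSE, log.p = TRUE)
  z[stat$mask] <- sign(tmap[stat$mask]) *
    stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z_thr <- stats::qnorm(cluster_forming_p, lower.tail = FALSE)
  n_mask <- sum(stat$mask)

  one_tail <- function(zs, tail_sign) {
    above <- array(FALSE, dim = dim(zs))
    above[stat$mask] <- (tail_sign * zs[stat$mask]) > z_thr
    if (!any(above)) return(NULL)
    tab <- cluster_peaks(tmap, above, affine = affine,
                         connectivity = connectivity)
    tab$corrected_p <- grf_cluster_p(tab$extent_voxels, z_thr,
                                     smooth$resel_count, n_mask)
    tab$sign <- if (tail_sign > 0) "positive" else "negative"
    tab
  }
  tabs <- dplyr::bind_rows(one_tail(z, 1), one_tail(z, -1))
  if (nrow(tabs) == 0L || is.null(tabs)) {
    out <- empty_cluster_table()
  } else {
    out <- dplyr::filter(tabs, .data$corrected_p < cluster_alpha / 2)
    out <- dplyr::arrange(out, .data$corrected_p)
    out$cluster <- seq_len(nrow(out))
  }
  attr(out, "z_threshold") <- z_thr
  attr(out, "cluster_alpha") <- cluster_alpha
  attr(out, "df") <- stat$df
  class(out) <- c("cluster_table", class(out))
  out
}

#' Binary masks of significant clusters
#'
#' Rebuilds the suprathreshold component containing each significant
#' cluster's peak, for use as feature-extraction masks.
#'
#' @param clusters A `cluster_table` from [grf_cluster_inference()].
#' @param stat The `stat_map` the table was derived from.
#' @param connectivity Same connectivity used for inference.
#' @return Named list of logical 3D arrays, one per cluster row.
#' @export
cluster_masks <- function(clusters, stat, connectivity = 26) {
  if (nrow(clusters) == 0L) return(list())
  z_thr <- attr(clusters, "z_threshold")
  lp <- stats::pt(abs(stat$map[stat$mask]), df = stat$df,
                  lower.tail = FALSE, log.p = TRUE)
  zvals <- sign(stat$map[stat$mask]) *
    stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z <- array(0, dim = dim(stat$map)); z[stat$mask] <- zvals
  out <- vector("list", nrow(clusters))
  for (r in seq_len(nrow(clusters))) {
    s <- if (clusters$sign[r] == "positive") 1 else -1
    above <- array(FALSE, dim = dim(z))
    above[stat$mask] <- (s * z[stat$mask]) > z_thr
    labels <- label_components(above, connectivity)
    ijk <- clusters$peak_ijk[[r]]
    out[[r]] <- labels == labels[ijk[1], ijk[2], ijk[3]]
  }
  names(out) <- paste0("cluster_", clusters$cluster)
  out
}
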