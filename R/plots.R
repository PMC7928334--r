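#' Plot an axial slice of a dALFF or t map
#'
#' @param object A `dalff_map` or `stat_map`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot dalff_map
#' @export
autoplot.dalff_map <- function(object, slice = NULL, ...) {
  slice_plot(object$map, object$mask, slice,
             fill_name = if (object$standardized) "z-dALFF" else "dALFF")
}

#' @rdname autoplot.dalff_map
#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slice = NULL, ...) {
  slice_plot(object$map, object$mask, slice, fill_name = "t") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", name = "t")
}

slice_plot <- function(arr, mask, slice, fill_name) {
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  msl <- mask[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  df$value[!as.vector(msl)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = fill_name, na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Axial slice ", slice)) +
    ggplot2::theme_minimal()
}

#' Framewise-displacement trace plot
#'
#' FD per volume with the scrubbing threshold and dropped volumes marked.
#'
#' @param fd Output of [compute_fd()].
#' @param retention Optional output of [scrub()]; dropped volumes shaded.
#' @param threshold FD threshold line (defaults to the series' attribute).
#' @return A ggplot object.
#' @export
plot_fd <- function(fd, retention = NULL, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(fd, "threshold") %||% 0.5
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$volume, y = .data$fd)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "Volume", y = "FD (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(retention) && any(!retention$keep)) {
    dropped <- retention[!retention$keep, ]
    p <- p + ggplot2::geom_vline(xintercept = dropped$volume,
                                 alpha = 0.15, color = "firebrick")
  }
  p
}

#' Plot classification metrics
#'
#' Bar chart of LOOCV accuracy, sensitivity and specificity.
#'
#' @param object A `classification_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classification_result
#' @export
autoplot.classification_result <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(c("accuracy", "sensitivity", "specificity"),
                    levels = c("accuracy", "sensitivity", "specificity")),
    value = c(object$accuracy, object$sensitivity, object$specificity)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "Percent",
                  title = sprintf("LOOCV linear SVM (C = %g)", object$svm_c)) +
    ggplot2::theme_minimal()
}

#' Plot a feature-covariate correlation
#'
#' Scatter of cluster-mean z-dALFF against a clinical covariate with the
#' least-squares line.
#'
#' @param features,covariate Paired numeric vectors.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_correlation <- function(features, covariate,
                             xlab = "cluster mean z-dALFF",
                             ylab = "covariate") {
  df <- tibble::tibble(x = features, y = covariate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
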