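#' Extract cluster-mean dALFF features
#'
#' Builds the subjects-by-clusters feature matrix: entry (i, j) is the mean
#' of subject i's z-dALFF map over cluster mask j.
#'
#' @param dalff_maps Named list of `dalff_map` objects (one per subject).
#' @param cluster_masks Named list of logical 3D arrays.
#' @param labels Character vector of group labels aligned with
#'   `dalff_maps` (`"patient"` / `"control"`).
#' @return A tibble with `id`, `group`, one numeric column per cluster.
#' @export
extract_features <- function(dalff_maps, cluster_masks, labels) {
  if (length(cluster_masks) == 0L) {
    stop("No cluster masks supplied.", call. = FALSE)
  }
  for (nm in names(cluster_masks)) {
    if (!any(cluster_masks[[nm]])) {
      stop("Cluster mask \"", nm, "\" is empty.", call. = FALSE)
    }
  }
  feats <- vapply(dalff_maps, function(m) {
    arr <- if (inherits(m, "dalff_map")) m$map else m
    vapply(cluster_masks, function(msk) {
      if (!all(dim(msk) == dim(arr))) {
        stop("Cluster mask grid does not match map grid.", call. = FALSE)
      }
      mean(arr[msk])
    }, numeric(1))
  }, numeric(length(cluster_masks)))
  feats <- if (length(cluster_masks) == 1L) matrix(feats, ncol = 1L) else t(feats)
  colnames(feats) <- names(cluster_masks)
  ids <- names(dalff_maps) %||% sprintf("sub_%02d", seq_along(dalff_maps))
  dplyr::bind_cols(tibble::tibble(id = ids, group = labels),
                   tibble::as_tibble(feats))
}

#' Leave-one-out cross-validated linear SVM
#'
#' For each subject, the remaining N - 1 subjects form the training fold:
#' feature columns are standardized with the training fold's mean and SD
#' (never the held-out subject's), a linear soft-margin SVM with cost `c`
#' is fitted, and the held-out subject is predicted. The N held-out
#' predictions give accuracy, sensitivity and specificity, with patients
#' as the positive class.
#'
#' @param features Tibble from [extract_features()] (`id`, `group`, then
#'   numeric feature columns).
#' @param c Soft-margin cost constant (default 1).
#' @return A `classification_result`: `predictions` tibble (id, group,
#'   predicted), `accuracy`, `sensitivity`, `specificity` (percent),
#'   `svm_c`.
#' @export
loocv_linear_svm <- function(features, c = 1) {
  x <- as.matrix(features[, setdiff(names(features), c("id", "group"))])
  y <- factor(features$group, levels = c("control", "patient"))
  n <- nrow(x)
  if (min(table(y)) < 2L) {
    stop("Need >= 2 subjects per class for leave-one-out.", call. = FALSE)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      stop("Training fold for subject ", i, " has a single class.",
           call. = FALSE)
    }
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xs, ytr, kernel = "linear", cost = c, scale = FALSE)
    xte <- sweep(sweep(x[i, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred[i] <- as.character(stats::predict(fit, xte))
  }
  counts <- prediction_counts(as.character(y), pred)
  metrics <- metrics_from_counts(counts$tp, counts$fn, counts$tn, counts$fp)
  structure(
    list(
      predictions = tibble::tibble(id = features$id,
                                   group = as.character(y),
                                   predicted = pred),
      accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
      specificity = metrics$specificity, svm_c = c,
      counts = counts
    ),
    class = "classification_result"
  )
}

prediction_counts <- function(truth, pred) {
  list(
    tp = sum(truth == "patient" & pred == "patient"),
    fn = sum(truth == "patient" & pred == "control"),
    tn = sum(truth == "control" & pred == "control"),
    fp = sum(truth == "control" & pred == "patient")
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / N, sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), all as percentages; patients are the
#' positive class.
#'
#' @param tp,fn,tn,fp Confusion counts (patients positive).
#' @return A list with `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  if (tp + fn == 0) stop("No positive-class subjects (tp + fn = 0).",
                         call. = FALSE)
  if (tn + fp == 0) stop("No negative-class subjects (tn + fp = 0).",
                         call. = FALSE)
  list(
    accuracy = 100 * (tp + tn) / sum(counts),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp)
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> LOOCV linear SVM (C = %g), n = %d\n  accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    x$svm_c, nrow(x$predictions), x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy classification_result
#' @export
tidy.classification_result <- function(x, ...) {
  x$predictions
}

#' @method glance classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, svm_c = x$svm_c,
    n = nrow(x$predictions)
  )
}
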