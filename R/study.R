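#' Analysis configuration
#'
#' All tunable pipeline parameters in one validated object. The defaults
#' reproduce the study settings this package implements: 10 discarded
#' volumes, 6-mm smoothing, 0.01-0.08 Hz band, FD < 0.5 mm scrubbing with
#' a 2-before / 1-after neighborhood, 50-TR windows stepped by 5 TR with
#' 30- and 70-TR validation runs, GRF cluster correction at alpha 0.05
#' (voxel-level cluster-forming p 0.01), Bonferroni alpha 0.05 for the
#' clinical correlations, and a LOOCV linear SVM with C = 1.
#'
#' @param band_hz Analysis band (Hz).
#' @param window_length_tr Primary window length (TR).
#' @param window_step_tr Window step (TR).
#' @param validation_lengths_tr Additional window lengths re-run for
#'   robustness.
#' @param n_discard Leading volumes dropped.
#' @param fd_threshold_mm Scrubbing FD threshold (mm).
#' @param scrub_before,scrub_after Scrub neighborhood sizes.
#' @param scrub_mode `"delete"` or `"interpolate"`.
#' @param max_trans_mm,max_rot_deg Subject-level motion exclusion limits.
#' @param fwhm_mm Smoothing kernel FWHM (mm).
#' @param cluster_forming_p One-sided voxel-level threshold for clusters.
#' @param cluster_alpha Cluster-level significance (two-sided).
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param bonferroni_alpha Family-wise alpha for clinical correlations.
#' @param svm_c SVM cost constant.
#' @param seed Seed for any stochastic stage.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(band_hz = c(0.01, 0.08),
                            window_length_tr = 50,
                            window_step_tr = 5,
                            validation_lengths_tr = c(30, 70),
                            n_discard = 10,
                            fd_threshold_mm = 0.5,
                            scrub_before = 2,
                            scrub_after = 1,
                            scrub_mode = c("delete", "interpolate"),
                            max_trans_mm = 3,
                            max_rot_deg = 3,
                            fwhm_mm = 6,
                            cluster_forming_p = 0.01,
                            cluster_alpha = 0.05,
                            connectivity = 26,
                            bonferroni_alpha = 0.05,
                            svm_c = 1,
                            seed = 1L) {
  scrub_mode <- match.arg(scrub_mode)
  stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[2] > band_hz[1],
            window_length_tr >= 2, window_step_tr >= 1,
            n_discard >= 0, fd_threshold_mm > 0,
            scrub_before >= 0, scrub_after >= 0,
            fwhm_mm > 0, cluster_forming_p > 0, cluster_forming_p <= 0.05,
            cluster_alpha > 0, cluster_alpha < 1,
            connectivity %in% c(6, 18, 26),
            bonferroni_alpha > 0, bonferroni_alpha < 1, svm_c > 0)
  structure(
    list(band_hz = band_hz, window_length_tr = window_length_tr,
         window_step_tr = window_step_tr,
         validation_lengths_tr = validation_lengths_tr,
         n_discard = n_discard, fd_threshold_mm = fd_threshold_mm,
         scrub_before = scrub_before, scrub_after = scrub_after,
         scrub_mode = scrub_mode, max_trans_mm = max_trans_mm,
         max_rot_deg = max_rot_deg, fwhm_mm = fwhm_mm,
         cluster_forming_p = cluster_forming_p,
         cluster_alpha = cluster_alpha, connectivity = connectivity,
         bonferroni_alpha = bonferroni_alpha, svm_c = svm_c,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Write a cohort to disk
#'
#' Per subject: 4D BOLD NIfTI, 3D tissue-mask NIfTIs, a whitespace-
#' delimited 6-column motion file. Cohort-level: covariates TSV, a manifest
#' TSV of relative paths, and a ground-truth JSON (ROI voxel lists, effect
#' directions, covariate target).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    bold_p <- file.path(dir, paste0(s$id, "_bold.nii.gz"))
    write_nifti_vol(s$bold, bold_p)
    motion_p <- file.path(dir, paste0(s$id, "_motion.txt"))
    utils::write.table(as.matrix(s$motion), motion_p, row.names = FALSE,
                       col.names = FALSE)
    mask_ps <- vapply(c("brain", "wm", "csf"), function(m) {
      p <- file.path(dir, paste0(s$id, "_", m, ".nii.gz"))
      write_nifti_vol(s$masks[[m]], p, affine = s$bold$affine)
      p
    }, character(1))
    tibble::tibble(
      id = s$id, group = s$group,
      bold = basename(bold_p), motion = basename(motion_p),
      brain_mask = basename(mask_ps["brain"]),
      wm_mask = basename(mask_ps["wm"]), csf_mask = basename(mask_ps["csf"])
    )
  })
  manifest <- dplyr::left_join(dplyr::bind_rows(rows),
                               cohort$covariates[, c("id", "age", "sex", "vas",
                                                     "duration_months")],
                               by = "id")
  manifest_p <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(
      roi_voxels = lapply(gt$roi_masks, function(m) which(m)),
      true_group_effect = gt$true_group_effect,
      true_covariate_r = gt$true_covariate_r,
      tr_s = cohort$params$tr_s, grid_shape = cohort$params$grid_shape
    ),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest_p)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest TSV written by [write_cohort()] (or prepared by hand
#' for real data): per-subject NIfTI/motion paths plus covariates. All
#' files must exist, ids must be unique, and all grids must agree.
#'
#' @param manifest Path to the manifest TSV.
#' @param tr_s Repetition time; `NULL` reads it from the NIfTI headers.
#' @return A list of `subject_record` objects.
#' @export
load_cohort <- function(manifest, tr_s = NULL) {
  dir <- dirname(manifest)
  tab <- utils::read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(tab$id)) {
    stop("Duplicate subject id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  grid <- NULL
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    paths <- file.path(dir, c(row$bold, row$motion, row$brain_mask,
                              row$wm_mask, row$csf_mask))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("Subject ", row$id, ": missing file(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bold <- read_bold(paths[1], tr_s = tr_s)
    if (is.null(grid)) grid <<- dim(bold$data)[1:3]
    if (!all(dim(bold$data)[1:3] == grid)) {
      stop("Subject ", row$id, ": grid ",
           paste(dim(bold$data)[1:3], collapse = "x"),
           " does not match cohort grid ", paste(grid, collapse = "x"),
           call. = FALSE)
    }
    motion <- utils::read.table(paths[2])
    names(motion) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    structure(
      list(id = row$id, group = row$group, bold = bold,
           motion = tibble::as_tibble(motion),
           masks = list(brain = read_mask(paths[3]), wm = read_mask(paths[4]),
                        csf = read_mask(paths[5])),
           covariates = tibble::tibble(
             id = row$id, group = row$group, age = row$age, sex = row$sex,
             vas = row$vas, duration_months = row$duration_months
           )),
      class = "subject_record"
    )
  })
  subjects
}

#' Run the full dALFF group study
#'
#' Orchestrates the pipeline end to end on a cohort: motion QC and
#' per-subject preprocessing, z-dALFF maps at the primary window length
#' (and each validation length), the voxel-wise two-sample t-map with GRF
#' cluster correction, clinical correlations of cluster-mean dALFF with
#' VAS and disease duration (Bonferroni over clusters x measures), and
#' LOOCV linear-SVM classification on cluster-mean features.
#'
#' @param cohort A `synthetic_cohort` or a list of `subject_record`s.
#' @param config An [analysis_config()].
#' @param gm_mask Optional analysis mask; defaults to each subject's brain
#'   mask minus WM and CSF (grey-matter shell).
#' @return A `study_report`: `qc`, `demographics`, `clusters` (primary
#'   window), `validation_clusters` (named by window length),
#'   `correlations`, `classification`, `config`, `log`.
#' @export
run_study <- function(cohort, config = analysis_config(), gm_mask = NULL) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  log <- character()

  pre <- lapply(subjects, preprocess_subject, config = config)
  qc <- dplyr::bind_rows(lapply(pre, `[[`, "qc"))
  keep <- !qc$exclude
  log <- c(log, sprintf("QC: %d / %d subjects retained", sum(keep),
                        length(keep)))
  pre <- pre[keep]
  subjects <- subjects[keep]
  groups <- vapply(subjects, `[[`, character(1), "group")
  if (sum(groups == "patient") < 2L || sum(groups == "control") < 2L) {
    stop("Fewer than 2 subjects per group after QC exclusion.",
         call. = FALSE)
  }

  if (is.null(gm_mask)) {
    m <- subjects[[1]]$masks
    gm_mask <- m$brain & !m$wm & !m$csf
  }
  affine <- subjects[[1]]$bold$affine
  vs <- voxel_size_mm(affine)

  covariates <- dplyr::bind_rows(lapply(subjects, `[[`, "covariates"))
  demographics <- demographics_table(covariates)

  window_result <- function(length_tr) {
    win <- suppressWarnings(
      window_spec(length_tr, config$window_step_tr,
                  tr_s = subjects[[1]]$bold$tr_s,
                  f_min_hz = config$band_hz[1])
    )
    maps <- lapply(pre, function(p) {
      zscore_map(dalff(p$bold, win, gm_mask, band = config$band_hz))
    })
    names(maps) <- vapply(subjects, `[[`, character(1), "id")
    tmap <- two_sample_t_map(maps[groups == "patient"],
                             maps[groups == "control"], gm_mask,
                             contrast = "patient - control")
    resid <- group_residual_maps(maps, groups, gm_mask)
    smooth <- estimate_smoothness(resid, gm_mask, vs)
    clusters <- grf_cluster_inference(
      tmap, smooth, cluster_forming_p = config$cluster_forming_p,
      cluster_alpha = config$cluster_alpha,
      connectivity = config$connectivity, affine = affine
    )
    list(maps = maps, tmap = tmap, smooth = smooth, clusters = clusters)
  }

  primary <- window_result(config$window_length_tr)
  log <- c(log, sprintf("primary window %d TR: %d significant cluster(s)",
                        config$window_length_tr, nrow(primary$clusters)))

  validation <- list()
  for (l in config$validation_lengths_tr) {
    validation[[paste0("window_", l, "tr")]] <- window_result(l)$clusters
  }

  correlations <- tibble::tibble()
  classification <- NULL
  if (nrow(primary$clusters) > 0L) {
    masks <- cluster_masks(primary$clusters, primary$tmap,
                           connectivity = config$connectivity)
    features <- extract_features(primary$maps, masks, groups)
    # Clinical correlations in patients only; family = clusters x measures.
    pat <- features[features$group == "patient", ]
    pat_cov <- covariates[covariates$group == "patient", ]
    measures <- c("vas", "duration_months")
    n_tests <- length(masks) * length(measures)
    corr_rows <- list()
    for (cl in names(masks)) {
      for (msr in measures) {
        cv <- pat_cov[[msr]]
        if (all(!is.finite(cv)) || stats::sd(cv, na.rm = TRUE) == 0) next
        res <- correlate_clinical(pat[[cl]], cv, n_tests = n_tests,
                                  alpha = config$bonferroni_alpha)
        corr_rows[[paste(cl, msr)]] <-
          dplyr::bind_cols(tibble::tibble(cluster = cl, measure = msr), res)
      }
    }
    correlations <- dplyr::bind_rows(corr_rows)
    classification <- loocv_linear_svm(features, c = config$svm_c)
    log <- c(log, sprintf("classification: accuracy %.2f%%",
                          classification$accuracy))
  } else {
    log <- c(log, "no significant clusters; correlation and classification skipped")
  }

  structure(
    list(qc = qc, demographics = demographics,
         clusters = primary$clusters, validation_clusters = validation,
         correlations = correlations, classification = classification,
         smoothness = primary$smooth, stat_map = primary$tmap,
         dalff_maps = primary$maps,
         config = config, log = log),
    class = "study_report"
  )
}

# Per-subject deviations from their own group mean map (t-test residuals).
group_residual_maps <- function(maps, groups, mask) {
  arrs <- lapply(maps, function(m) m$map)
  out <- vector("list", length(arrs))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    gm <- Reduce(`+`, arrs[idx]) / length(idx)
    for (i in idx) out[[i]] <- arrs[[i]] - gm
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  QC: ", sum(!x$qc$exclude), "/", nrow(x$qc), " subjects retained\n",
      sep = "")
  cat("  significant clusters (primary window): ", nrow(x$clusters), "\n",
      sep = "")
  if (!is.null(x$classification)) {
    cat(sprintf("  LOOCV accuracy: %.2f%%\n", x$classification$accuracy))
  }
  invisible(x)
}

#' Cluster table in reporting form
#'
#' The significant-cluster table with peak mm coordinates, signed peak t,
#' extent and corrected p — the columns of a standard cluster report.
#'
#' @param report A `study_report`.
#' @return Tibble: `cluster`, `peak_x`, `peak_y`, `peak_z`, `peak_t`,
#'   `extent_voxels`, `corrected_p`.
#' @export
cluster_report <- function(report) {
  cl <- report$clusters
  tibble::as_tibble(cl[, c("cluster", "peak_x", "peak_y", "peak_z",
                           "peak_t", "extent_voxels", "corrected_p")])
}

#' Write the study report to a directory
#'
#' QC and cluster tables as TSV, correlations and classification metrics
#' (with provenance: config and seed) as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$qc, file.path(dir, "qc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cl <- cluster_report(report)
  utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  out <- list(
    demographics = report$demographics,
    correlations = report$correlations,
    classification = if (!is.null(report$classification))
      glance(report$classification),
    config = unclass(report$config),
    log = report$log
  )
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
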