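#' Pipeline configuration
#'
#' Bundles the tunables of the per-animal pipeline: byte window,
#' landmark detector, biopsy placement parameters, histogram binning
#' and HU calibration.
#'
#' @param window a [byte_window()].
#' @param detector a [landmark_detector()].
#' @param k_offset,k_radius biopsy placement parameters (see
#'   [place_biopsy_rois()]).
#' @param side_flip swap anatomical left/right naming.
#' @param thresholds a [seg_thresholds()] for rule-based segmentation.
#' @param calib a [voxel_calibration()].
#' @param bin_width,hist_lo,hist_hi histogram binning.
#' @export
pipeline_config <- function(window = byte_window(),
                            detector = landmark_detector(),
                            k_offset = 0.55, k_radius = 0.28,
                            side_flip = FALSE,
                            thresholds = seg_thresholds(),
                            calib = voxel_calibration(),
                            bin_width = 10, hist_lo = 0, hist_hi = 4100) {
  structure(list(window = window, detector = detector, k_offset = k_offset,
                 k_radius = k_radius, side_flip = side_flip,
                 thresholds = thresholds, calib = calib,
                 bin_width = bin_width, hist_lo = hist_lo,
                 hist_hi = hist_hi),
            class = "pipeline_config")
}

#' Run the full per-animal pipeline
#'
#' Classify slices, select the middle-part run, detect breastbone and
#' spine landmarks on those slices, estimate the chest frame, place the
#' two biopsy ROIs, segment the stack, exclude airway voxels and
#' compute densitometric features for all four scopes. Stage failures
#' that can be worked around (landmarks missing on individual slices)
#' are recorded as QC flags; the run fails hard only when no middle
#' slices exist or no landmarks are found in any middle slice.
#'
#' @param stack an [image_stack()].
#' @param classifier a `lung_part_classifier` or [oracle_classifier()].
#' @param segmenter an [oracle_segmenter()], `lung_segmenter`, or
#'   `NULL` for the rule-based reference.
#' @param config a [pipeline_config()].
#' @param animal_id identifier copied into the record.
#' @param covariates optional named list (e.g. `ashcroft`, `mli`,
#'   `fvc`) carried into the record for correlation analyses.
#' @return An object of class `cohort_record`: `animal_id`, `features`
#'   (data.frame, one row per scope), `covariates`, `qc` flags,
#'   `labels`, `middle_run`, `frame`, `rois`, and the pooled-biopsy
#'   `histogram`.
#' @export
run_pipeline <- function(stack, classifier, segmenter = NULL,
                         config = pipeline_config(), animal_id = "animal",
                         covariates = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  qc <- list(landmark_fallback = FALSE, fwhm_edge = FALSE,
             empty_roi_warning = FALSE, roi_radius_reduced = FALSE)
  labels <- classify_stack(stack, classifier)
  run <- select_middle_run(labels)   # hard "no middle part found" error

  boxes <- vector("list", length(run))
  for (i in seq_along(run)) {
    boxes[[i]] <- tryCatch(
      detect_landmarks(stack$voxels[, , run[i]], config$detector),
      error = function(e) NULL)
  }
  if (all(vapply(boxes, is.null, TRUE)))
    stop("landmarks not found in any middle slice")
  if (any(vapply(boxes, is.null, TRUE))) qc$landmark_fallback <- TRUE
  frame <- estimate_chest_frame(boxes)

  rois <- withCallingHandlers(
    place_biopsy_rois(frame, run, dim(stack$voxels)[1:2],
                      k_offset = config$k_offset, k_radius = config$k_radius,
                      side_flip = config$side_flip),
    warning = function(w) {
      qc$roi_radius_reduced <<- TRUE
      invokeRestart("muffleWarning")
    })

  seg <- segment_stack(stack, segmenter, config$thresholds)
  features <- withCallingHandlers(
    compute_all(stack, rois, seg, config$calib, config$bin_width,
                config$hist_lo, config$hist_hi),
    warning = function(w) {
      qc$empty_roi_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  qc$fwhm_edge <- any(features$fwhm_edge_flag)

  airway <- array(unclass(seg) == label_code("airways"), dim(seg))
  pooled <- c(stack$voxels[roi_voxels(rois$left, airway)],
              stack$voxels[roi_voxels(rois$right, airway)])
  hist <- build_histogram(pooled, config$bin_width, config$hist_lo,
                          config$hist_hi)

  structure(list(animal_id = animal_id, features = features,
                 covariates = covariates, qc = qc, labels = labels,
                 middle_run = run, frame = frame, rois = rois,
                 histogram = hist,
                 config_hash = config_hash(config)),
            class = "cohort_record")
}

#' Pearson correlation of a feature against a covariate
#'
#' Pairs with a missing value on either side are dropped (pairwise
#' deletion) and the remaining count reported. The p-value is the
#' two-sided t-transform p from `cor.test` and is reported
#' descriptively, without multiple-testing correction.
#'
#' @param records list of `cohort_record`s.
#' @param feature feature column name (e.g. `"mean_raw"`,
#'   `"auc_ratio"`).
#' @param scope one of `"left_roi"`, `"right_roi"`, `"both_rois"`,
#'   `"whole_lung"`.
#' @param covariate covariate name in each record's `covariates`.
#' @return List `r`, `p`, `n`, `dropped`.
#' @export
correlate <- function(records, feature, scope, covariate) {
  x <- vapply(records, function(rec) {
    row <- rec$features[rec$features$scope == scope, ]
    if (nrow(row) != 1) return(NA_real_)
    as.numeric(row[[feature]])
  }, 0)
  y <- vapply(records, function(rec)
    as.numeric(rec$covariates[[covariate]] %||% NA_real_), 0)
  ok <- is.finite(x) & is.finite(y)
  dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in feature or covariate")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       dropped = dropped)
}

#' Write cohort results to disk
#'
#' Writes `features.csv` (all records, all scopes),
#' `correlations.csv` for the requested feature/covariate pairs,
#' per-animal pooled-biopsy histogram CSVs under `histograms/`, and a
#' `run_log.json` with the config hash and package version.
#'
#' @param records list of `cohort_record`s.
#' @param out_dir output directory (created if needed).
#' @param pairs optional data.frame with columns `feature`, `scope`,
#'   `covariate` naming the correlations to compute.
#' @return Invisibly, the paths written.
#' @export
report_cohort <- function(records, out_dir, pairs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "histograms"), showWarnings = FALSE)
  feats <- do.call(rbind, lapply(records, function(rec)
    cbind(animal_id = rec$animal_id, rec$features)))
  fpath <- file.path(out_dir, "features.csv")
  write.csv(feats, fpath, row.names = FALSE)
  paths <- fpath
  if (!is.null(pairs) && nrow(pairs)) {
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      res <- correlate(records, pairs$feature[i], pairs$scope[i],
                       pairs$covariate[i])
      data.frame(feature = pairs$feature[i], scope = pairs$scope[i],
                 covariate = pairs$covariate[i], r = res$r, p = res$p,
                 n = res$n)
    })
    cpath <- file.path(out_dir, "correlations.csv")
    write.csv(do.call(rbind, rows), cpath, row.names = FALSE)
    paths <- c(paths, cpath)
  }
  for (rec in records) {
    hp <- file.path(out_dir, "histograms",
                    paste0(rec$animal_id, ".csv"))
    write.csv(data.frame(bin_center = rec$histogram$centers,
                         count = rec$histogram$counts),
              hp, row.names = FALSE)
    paths <- c(paths, hp)
  }
  log <- list(package = "lungbiopsy",
              version = as.character(packageVersion("lungbiopsy")),
              n_records = length(records),
              config_hash = records[[1]]$config_hash %||% NA,
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  lpath <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, lpath, auto_unbox = TRUE)
  invisible(c(paths, lpath))
}
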