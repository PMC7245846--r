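#' Collect raw intensities from a voxel set
#'
#' Returns the raw scanner intensities at the given voxels after
#' removing any that fall in the airway mask. Densitometry operates on
#' raw values only; byte-converted stacks are rejected.
#'
#' @param stack an [image_stack()].
#' @param voxel_set linear voxel indices or a logical voxel grid.
#' @param airway_mask optional logical voxel grid of airway voxels to
#'   exclude.
#' @return Numeric vector of intensities with attribute `excluded_n`.
#' @export
collect_intensities <- function(stack, voxel_set, airway_mask = NULL) {
  if (is_byte(stack))
    stop("densitometry requires raw intensities, not byte-converted data")
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (is.logical(voxel_set)) {
    if (!identical(dim(voxel_set), d)) stop("voxel set dims mismatch")
    voxel_set <- which(voxel_set)
  }
  if (!length(voxel_set)) stop("voxel set is empty")
  excluded <- 0L
  if (!is.null(airway_mask)) {
    if (!identical(dim(airway_mask), d)) stop("airway mask dims mismatch")
    drop <- airway_mask[voxel_set]
    excluded <- sum(drop)
    voxel_set <- voxel_set[!drop]
  }
  if (!length(voxel_set)) stop("voxel set is empty after airway exclusion")
  out <- as.numeric(stack$voxels[voxel_set])
  attr(out, "excluded_n") <- excluded
  out
}

#' Build an intensity histogram
#'
#' Uniform half-open bins `[edge_i, edge_{i+1})`; values outside
#' `[lo, hi)` are clipped into the first/last bin with a warning. The
#' default binning (width 10 over `[0, 4100)`) is fine enough that mode
#' and FWHM discretization error is below the width of anatomical
#' intensity peaks.
#'
#' @param sample numeric intensity sample (nonempty).
#' @param bin_width bin width in raw-intensity units.
#' @param lo,hi histogram range.
#' @return An object of class `intensity_histogram` with `breaks`,
#'   `centers`, `counts`, `total`, `clipped_n`.
#' @export
build_histogram <- function(sample, bin_width = 10, lo = 0, hi = 4100) {
  if (!length(sample)) stop("empty sample")
  breaks <- seq(lo, hi, by = bin_width)
  nb <- length(breaks) - 1L
  clipped <- sum(sample < lo | sample >= hi)
  if (clipped > 0)
    warning(sprintf("%d values outside [%g, %g) clipped into edge bins",
                    clipped, lo, hi))
  idx <- clamp(findInterval(sample, breaks), 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(breaks = breaks, centers = breaks[-length(breaks)] +
                   bin_width / 2,
                 counts = counts, total = length(sample),
                 clipped_n = clipped),
            class = "intensity_histogram")
}

#' Mean, median and mode of an intensity sample
#'
#' Mean and median are computed on the raw sample (not bin
#' approximations); the mode is the centre of the maximal-count bin,
#' ties broken toward lower intensity.
#'
#' @param sample numeric intensity sample.
#' @param hist an [build_histogram()] result (built from `sample` by
#'   default).
#' @return List `mean`, `median`, `mode`.
#' @export
feature_mean_median_mode <- function(sample,
                                     hist = build_histogram(sample)) {
  if (!length(sample)) stop("empty sample")
  list(mean = mean(sample), median = median(sample),
       mode = hist$centers[which.max(hist$counts)])
}

#' Full width at half maximum of the histogram peak
#'
#' The global peak bin is located (ties broken toward lower intensity,
#' with a flag); the half-height crossings on each side are found by
#' linear interpolation between adjacent bin centres, moving outward
#' from the peak. If a side never falls below half height, the
#' histogram edge is used on that side and `edge_flag` is set.
#'
#' @param hist an `intensity_histogram`.
#' @return List `fwhm`, `peak_center`, `edge_flag`, `tie_flag`.
#' @export
feature_fwhm <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  y <- hist$counts; x <- hist$centers
  if (max(y) <= 0) stop("histogram has no positive maximum")
  peak <- which.max(y)
  tie_flag <- sum(y == y[peak]) > 1
  half <- y[peak] / 2
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(peak - 1)) else
      (peak + 1):length(y)
    if (peak + side < 1 || peak + side > length(y)) idx <- integer(0)
    prev <- peak
    for (i in idx) {
      if (y[i] < half) {
        # interpolate between centres of the bracketing bins
        return(x[prev] + (half - y[prev]) / (y[i] - y[prev]) *
                 (x[i] - x[prev]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- if (peak > 1) cross(-1) else NA_real_
  right <- if (peak < length(y)) cross(1) else NA_real_
  edge_flag <- FALSE
  if (is.na(left)) { left <- hist$breaks[1]; edge_flag <- TRUE }
  if (is.na(right)) { right <- hist$breaks[length(hist$breaks)]; edge_flag <- TRUE }
  # degenerate single-occupied-bin case: never wider than one bin
  width <- right - left
  if (edge_flag && sum(y > 0) == 1)
    width <- min(width, diff(hist$breaks[1:2]))
  list(fwhm = width, peak_center = x[peak], edge_flag = edge_flag,
       tie_flag = tie_flag)
}

#' Skewness and excess kurtosis of an intensity sample
#'
#' Population-moment definitions: `skew = m3 / m2^1.5`,
#' `kurt = m4 / m2^2 - 3` with central moments `m_k`; a Gaussian sample
#' has skewness 0 and kurtosis 0.
#'
#' @param sample numeric sample, `n >= 3`, nonconstant.
#' @return List `skewness`, `kurtosis`.
#' @export
feature_skew_kurt <- function(sample) {
  n <- length(sample)
  if (n < 3) stop("need at least 3 values")
  m <- mean(sample)
  m2 <- mean((sample - m)^2)
  if (m2 == 0) stop("sample is constant (zero variance)")
  list(skewness = mean((sample - m)^3) / m2^1.5,
       kurtosis = mean((sample - m)^4) / m2^2 - 3)
}

#' AUC fractions and ratio for normal vs fibrotic intensity ranges
#'
#' `auc_normal` and `auc_fibrotic` are the fractions of sample voxels
#' with intensity in the closed normal-tissue (1000-1500) and
#' highly-fibrotic (2000-2500) ranges; the ratio `normal / fibrotic`
#' decreases with fibrosis. A zero fibrotic fraction yields `Inf` with
#' `infinite_flag` set.
#'
#' @param sample numeric intensity sample.
#' @param normal_range,fibrotic_range closed intensity ranges.
#' @return List `auc_normal`, `auc_fibrotic`, `auc_ratio`,
#'   `infinite_flag`.
#' @export
feature_auc_ratio <- function(sample, normal_range = c(1000, 1500),
                              fibrotic_range = c(2000, 2500)) {
  if (!length(sample)) stop("empty sample")
  frac <- function(r) mean(sample >= r[1] & sample <= r[2])
  an <- frac(normal_range); af <- frac(fibrotic_range)
  list(auc_normal = an, auc_fibrotic = af,
       auc_ratio = if (af == 0) Inf else an / af,
       infinite_flag = af == 0)
}

# one row of densitometric features for a scope
densitometry_row <- function(sample, scope, calib = voxel_calibration(),
                             bin_width = 10, lo = 0, hi = 4100) {
  h <- build_histogram(sample, bin_width, lo, hi)
  mmm <- feature_mean_median_mode(sample, h)
  fw <- feature_fwhm(h)
  sk <- feature_skew_kurt(sample)
  auc <- feature_auc_ratio(sample)
  data.frame(scope = scope, n_voxels = length(sample),
             mean_raw = mmm$mean, mean_hu = intensity_to_hu(mmm$mean, calib),
             median = mmm$median, mode = mmm$mode,
             fwhm = fw$fwhm, fwhm_edge_flag = fw$edge_flag,
             skewness = sk$skewness, kurtosis = sk$kurtosis,
             auc_normal = auc$auc_normal, auc_fibrotic = auc$auc_fibrotic,
             auc_ratio = auc$auc_ratio,
             airway_excluded_n = attr(sample, "excluded_n") %||% 0L,
             stringsAsFactors = FALSE)
}

#' Densitometric features for all analysis scopes
#'
#' Computes the feature set for the left biopsy, the right biopsy, both
#' biopsies pooled (features of the pooled voxel sample, not averaged
#' per-side features) and the whole segmented lung (all voxels the
#' segmentation labels as tissue). Airway-labeled voxels are excluded
#' from every scope.
#'
#' @param stack an [image_stack()].
#' @param rois list with `left` and `right` `biopsy_roi`s.
#' @param seg a `label_mask` for the same stack.
#' @param calib a [voxel_calibration()] for the HU-converted mean.
#' @param bin_width,lo,hi histogram binning.
#' @return A data.frame with one row per scope (`left_roi`,
#'   `right_roi`, `both_rois`, `whole_lung`).
#' @export
compute_all <- function(stack, rois, seg, calib = voxel_calibration(),
                        bin_width = 10, lo = 0, hi = 4100) {
  stopifnot(inherits(seg, "label_mask"))
  d <- dim(stack$voxels)
  if (!identical(dim(seg), d)) stop("segmentation dims mismatch")
  airway <- array(unclass(seg) == label_code("airways"), d)
  lidx <- roi_voxels(rois$left, airway)
  ridx <- roi_voxels(rois$right, airway)
  samp <- function(idx) {
    s <- as.numeric(stack$voxels[idx])
    attr(s, "excluded_n") <- attr(idx, "excluded_n") %||% 0L
    s
  }
  left <- samp(lidx); right <- samp(ridx)
  both <- c(left, right)
  attr(both, "excluded_n") <- attr(left, "excluded_n") +
    attr(right, "excluded_n")
  lung_idx <- which(unclass(seg) == label_code("tissue"))
  if (!length(lung_idx)) stop("segmentation contains no tissue voxels")
  whole <- as.numeric(stack$voxels[lung_idx])
  attr(whole, "excluded_n") <- 0L
  rbind(densitometry_row(left, "left_roi", calib, bin_width, lo, hi),
        densitometry_row(right, "right_roi", calib, bin_width, lo, hi),
        densitometry_row(both, "both_rois", calib, bin_width, lo, hi),
        densitometry_row(whole, "whole_lung", calib, bin_width, lo, hi))
}
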