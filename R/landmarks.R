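#' Landmark boxes and box geometry
#'
#' Axis-aligned rectangles in slice coordinates locating the breastbone
#' (sternum, anterior) and the spine (vertebral column, posterior).
#' Boxes are 0-based, half-open `[r0, r1) x [c0, c1)`; the breastbone
#' centre must be anterior (smaller row) to the spine centre.
#'
#' @param breastbone,spine length-4 numeric `c(r0, c0, r1, c1)`.
#' @export
landmark_boxes <- function(breastbone, spine) {
  chk <- function(b) {
    if (length(b) != 4 || b[3] <= b[1] || b[4] <= b[2])
      stop("box must be c(r0, c0, r1, c1) with r1 > r0, c1 > c0")
    b
  }
  bb <- chk(breastbone); sp <- chk(spine)
  if (box_center(bb)[1] >= box_center(sp)[1])
    stop("breastbone centre must be anterior to spine centre")
  structure(list(breastbone = bb, spine = sp), class = "landmark_boxes")
}

# centre of a half-open pixel box in 0-based pixel-centre coordinates
box_center <- function(box) c((box[1] + box[3] - 1) / 2,
                              (box[2] + box[4] - 1) / 2)

box_iou <- function(a, b) {
  ir <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ic <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ir * ic
  area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
  inter / (area(a) + area(b) - inter)
}

#' Reference landmark detector configuration
#'
#' Rule-based detector: threshold at the bone intensity, morphological
#' opening, connected components above a minimum area, then anatomical
#' assignment (most anterior centroid = breastbone; most posterior
#' near-midline component = spine). `min_area` defaults to 20 voxels at
#' 512 x 512 and scales with slice area. A trained object-detection
#' network can be plugged in behind the same [detect_landmarks()]
#' contract.
#'
#' @param bone_lo raw-intensity bone threshold.
#' @param open_radius opening radius in pixels.
#' @param min_area minimum component area (`NULL` = auto-scale).
#' @export
landmark_detector <- function(bone_lo = 2900, open_radius = 1L,
                              min_area = NULL) {
  structure(list(bone_lo = bone_lo, open_radius = as.integer(open_radius),
                 min_area = min_area),
            class = "landmark_detector")
}

#' Detect breastbone and spine boxes on one slice
#'
#' @param slice 2D raw-intensity matrix.
#' @param detector a [landmark_detector()].
#' @return A [landmark_boxes()] object.
#' @export
detect_landmarks <- function(slice, detector = landmark_detector()) {
  stopifnot(inherits(detector, "landmark_detector"))
  nr <- nrow(slice); nc <- ncol(slice)
  min_area <- detector$min_area %||% max(4, round(20 * nr * nc / 512^2))
  bw <- slice >= detector$bone_lo
  if (detector$open_radius > 0) {
    brush <- EBImage::makeBrush(2L * detector$open_radius + 1L, "disc")
    bw <- EBImage::opening(bw, brush)
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  if (length(keep) < 2) stop("landmarks not found")
  cent <- t(vapply(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  bb_i <- which.min(cent[, 1])
  rest <- setdiff(seq_along(keep), bb_i)
  # spine: most posterior component near the sagittal line through the
  # breastbone (robust under in-plane rotation/translation of the chest)
  midline <- abs(cent[rest, 2] - cent[bb_i, 2]) <= 0.3 * nc
  if (!any(midline)) stop("landmarks not found")
  sp_i <- rest[midline][which.max(cent[rest[midline], 1])]
  tight <- function(k) {
    w <- which(lab == keep[k], arr.ind = TRUE)
    c(min(w[, 1]) - 1, min(w[, 2]) - 1, max(w[, 1]), max(w[, 2]))
  }
  landmark_boxes(breastbone = tight(bb_i), spine = tight(sp_i))
}

#' Estimate the chest frame from landmark boxes
#'
#' Per-slice frames (midpoint of the two box centres; angle of the
#' spine-to-breastbone vector against the image anterior axis, in
#' degrees; distance between the centres) are aggregated by
#' component-wise median over the supplied slices for robustness.
#'
#' @param boxes_per_slice list of [landmark_boxes()] (NULL entries are
#'   skipped).
#' @return An object of class `chest_frame` with fields `center`
#'   (row, col; 0-based), `axis_angle_deg`, `chest_scale`.
#' @export
estimate_chest_frame <- function(boxes_per_slice) {
  if (inherits(boxes_per_slice, "landmark_boxes"))
    boxes_per_slice <- list(boxes_per_slice)
  boxes_per_slice <- Filter(Negate(is.null), boxes_per_slice)
  if (!length(boxes_per_slice)) stop("no landmark boxes supplied")
  per <- t(vapply(boxes_per_slice, function(b) {
    bc <- box_center(b$breastbone); sc <- box_center(b$spine)
    v <- bc - sc                       # spine -> breastbone
    # angle against the anterior axis, signed like the in-plane pose
    # rotation (positive = chest rotated toward the animal's left)
    c(center = (bc + sc) / 2,
      angle = atan2(-v[2], -v[1]) * 180 / pi,
      scale = sqrt(sum(v^2)))
  }, numeric(4)))
  structure(list(center = c(median(per[, 1]), median(per[, 2])),
                 axis_angle_deg = median(per[, 3]),
                 chest_scale = median(per[, 4])),
            class = "chest_frame")
}

#' Place the two biopsy ROIs
#'
#' Each ROI is a cylinder over the middle-part slice run: the same disk
#' on every slice, centred at `frame$center` offset by
#' `k_offset * chest_scale` along the axis perpendicular to the
#' spine-to-breastbone axis, with radius `k_radius * chest_scale`. The
#' defaults are fixed so that the two biopsies jointly cover about 14%
#' of the lung volume on the default phantom geometry. If a disk would
#' exit the slice its radius is reduced to fit, with a warning. Sides
#' follow the animal's anatomy under the slice-orientation convention
#' (image left = animal right); set `side_flip = TRUE` to reverse.
#'
#' @param frame a `chest_frame`.
#' @param middle_run integer vector of consecutive slice indices.
#' @param slice_shape length-2 integer (rows, cols).
#' @param k_offset,k_radius dimensionless placement parameters.
#' @param side_flip swap the left/right naming.
#' @return List with elements `left` and `right`, each of class
#'   `biopsy_roi` (`side`, `center`, `radius`, `slices`, `shape`,
#'   `pixels` = in-slice linear indices).
#' @export
place_biopsy_rois <- function(frame, middle_run, slice_shape,
                              k_offset = 0.55, k_radius = 0.28,
                              side_flip = FALSE) {
  stopifnot(inherits(frame, "chest_frame"))
  if (!length(middle_run)) stop("middle run is empty")
  if (!(frame$chest_scale > 0)) stop("chest_scale must be positive")
  nr <- slice_shape[1]; nc <- slice_shape[2]
  th <- frame$axis_angle_deg * pi / 180
  off <- k_offset * frame$chest_scale
  # animal-left direction: +col at angle 0, rotating with the frame
  dir_left <- c(row = -sin(th), col = cos(th))
  mk <- function(sign, side) {
    ctr <- frame$center + sign * off * dir_left
    r <- k_radius * frame$chest_scale
    rmax <- min(ctr[1], nr - 1 - ctr[1], ctr[2], nc - 1 - ctr[2])
    if (rmax <= 0) stop("ROI centre outside the slice")
    if (r > rmax) {
      warning(sprintf("%s ROI radius reduced from %.1f to %.1f to fit slice",
                      side, r, rmax))
      r <- rmax
    }
    rows <- matrix(rep(0:(nr - 1), nc), nr, nc)
    cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
    pix <- which((rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2)
    structure(list(side = side, center = unname(ctr), radius = r,
                   slices = middle_run, shape = c(nr, nc), pixels = pix),
              class = "biopsy_roi")
  }
  if (side_flip)
    list(left = mk(-1, "left"), right = mk(1, "right"))
  else
    list(left = mk(1, "left"), right = mk(-1, "right"))
}

#' Linear 3D voxel indices of a biopsy ROI
#'
#' @param roi a `biopsy_roi`.
#' @param dims stack dimensions.
#' @export
roi_voxel_indices <- function(roi, dims) {
  stopifnot(inherits(roi, "biopsy_roi"))
  if (any(dims[1:2] != roi$shape)) stop("slice shape mismatch")
  npx <- dims[1] * dims[2]
  as.vector(outer(roi$pixels, (roi$slices - 1) * npx, `+`))
}

#' ROI voxels after airway exclusion
#'
#' @param roi a `biopsy_roi`.
#' @param airway_mask logical voxel grid (or `NULL` for no exclusion);
#'   dimensions must match the stack the ROI was placed on.
#' @param dims stack dimensions (defaults to the mask's).
#' @return Integer vector of linear voxel indices with attribute
#'   `excluded_n`, the number of airway voxels removed.
#' @export
roi_voxels <- function(roi, airway_mask = NULL, dims = dim(airway_mask)) {
  if (is.null(airway_mask) && is.null(dims))
    stop("supply airway_mask or dims")
  idx <- roi_voxel_indices(roi, dims)
  if (is.null(airway_mask)) {
    attr(idx, "excluded_n") <- 0L
    return(idx)
  }
  if (length(dim(airway_mask)) != 3) stop("airway mask must be 3D")
  drop <- airway_mask[idx]
  out <- idx[!drop]
  if (!length(out)) warning("ROI is empty after airway exclusion")
  attr(out, "excluded_n") <- sum(drop)
  out
}
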