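#' The five segmentation label classes
#' @export
label_mask_levels <- function() {
  c("tissue", "airways", "bone", "background", "ignore")
}

label_code <- function(name) match(name, label_mask_levels())

new_label_mask <- function(codes, dims) {
  structure(array(as.integer(codes), dims), class = "label_mask",
            levels = label_mask_levels())
}

#' Segmentation thresholds for the rule-based reference segmenter
#'
#' The numeric values follow the phantom intensity model (airway lumen
#' below ~700, body soft tissue above ~800, bone above ~2900) and are
#' config-exposed for real scanners.
#'
#' @param air_hi upper raw intensity of airway lumen.
#' @param body_lo raw intensity separating body from background air.
#' @param bone_lo raw intensity of bone.
#' @param close_radius morphological closing radius for the body
#'   silhouette.
#' @param min_airway minimum in-plane airway component area (`NULL` =
#'   auto-scale, 20 voxels at 512 x 512).
#' @export
seg_thresholds <- function(air_hi = 700, body_lo = 800, bone_lo = 2900,
                           close_radius = 2L, min_airway = NULL) {
  structure(list(air_hi = air_hi, body_lo = body_lo, bone_lo = bone_lo,
                 close_radius = as.integer(close_radius),
                 min_airway = min_airway),
            class = "seg_thresholds")
}

# body silhouette of one slice: closing of the supra-threshold mask,
# largest connected component, holes filled
body_outline <- function(m, thresholds) {
  bw <- m >= thresholds$body_lo
  if (!any(bw)) return(bw)
  if (thresholds$close_radius > 0) {
    brush <- EBImage::makeBrush(2L * thresholds$close_radius + 1L, "disc")
    bw <- EBImage::closing(bw, brush)
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab)
  EBImage::fillHull(lab == which.max(sizes)) > 0
}

#' Rule-based reference segmentation
#'
#' Deterministic slice-by-slice five-class segmentation: bone above the
#' bone threshold; background outside the body outline; airways =
#' sub-threshold voxels inside the body forming components of at least
#' the minimum area; tissue = all remaining in-body voxels. The
#' reference never emits `ignore` (reserved for trainable variants).
#'
#' @param stack an [image_stack()].
#' @param thresholds a [seg_thresholds()].
#' @return A `label_mask` (integer array, levels
#'   [label_mask_levels()]).
#' @export
segment_stack_reference <- function(stack, thresholds = seg_thresholds()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  min_air <- thresholds$min_airway %||% max(4, round(20 * d[1] * d[2] / 512^2))
  out <- array(label_code("background"), d)
  for (z in seq_len(d[3])) {
    m <- stack$voxels[, , z]
    body <- body_outline(m, thresholds)
    if (!any(body)) next
    cls <- matrix(label_code("background"), d[1], d[2])
    cls[body] <- label_code("tissue")
    aircand <- body & m < thresholds$air_hi
    if (any(aircand)) {
      lab <- EBImage::bwlabel(aircand)
      sizes <- tabulate(lab)
      ok <- lab > 0 & sizes[pmax(lab, 1)] >= min_air
      cls[ok] <- label_code("airways")
    }
    cls[m >= thresholds$bone_lo] <- label_code("bone")
    out[, , z] <- cls
  }
  new_label_mask(out, d)
}

#' Oracle segmenter backed by phantom ground truth
#'
#' Maps the truth masks directly onto the five label classes (lung as
#' tissue); everything outside lung, airway and bone is background.
#'
#' @param truth a `phantom_truth`.
#' @export
oracle_segmenter <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  structure(list(truth = truth), class = "oracle_segmenter")
}

#' Segment a stack with a fitted, oracle or reference segmenter
#'
#' @param stack an [image_stack()].
#' @param segmenter an [oracle_segmenter()], a trained `lung_segmenter`
#'   (see [train_segmenter()]) or `NULL` for the rule-based reference.
#' @param thresholds passed to [segment_stack_reference()] when
#'   `segmenter` is `NULL`.
#' @return A `label_mask`.
#' @export
segment_stack <- function(stack, segmenter = NULL,
                          thresholds = seg_thresholds()) {
  if (is.null(segmenter))
    return(segment_stack_reference(stack, thresholds))
  if (inherits(segmenter, "oracle_segmenter")) {
    tr <- segmenter$truth
    d <- dim(stack$voxels)
    if (any(dim(tr$lung_mask) != d)) stop("truth dims do not match stack")
    codes <- array(label_code("background"), d)
    codes[tr$lung_mask] <- label_code("tissue")
    codes[tr$airway_mask] <- label_code("airways")
    codes[tr$bone_mask] <- label_code("bone")
    return(new_label_mask(codes, d))
  }
  if (inherits(segmenter, "lung_segmenter"))
    return(segment_stack_dl(stack, segmenter))
  stop("unknown segmenter")
}

#' Training configuration for the trainable segmenter
#'
#' Mirrors [classifier_config()] for the slice-wise semantic segmenter:
#' full-resolution input, gentler augmentation and a longer schedule.
#' The schedule fields are recorded for gradient-trained variants; the
#' built-in decision-tree segmenter uses only `rng_seed` and
#' `max_train_px`.
#'
#' @param input_size kept at full slice resolution by default.
#' @param rotation_deg,shift_px,brightness_frac augmentation bounds.
#' @param momentum,weight_decay,lr_start,lr_end,epochs recorded
#'   schedule.
#' @param max_train_px voxels subsampled for fitting.
#' @param rng_seed training seed.
#' @export
seg_train_config <- function(input_size = c(512L, 512L), rotation_deg = 5,
                             shift_px = 10L, brightness_frac = 0.05,
                             momentum = 0.99, weight_decay = 0.001,
                             lr_start = 0.0005, lr_end = 0.00003,
                             epochs = 2500L, max_train_px = 50000L,
                             rng_seed = 1L) {
  if (!(lr_start > lr_end && lr_end > 0)) stop("need lr_start > lr_end > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 rotation_deg = rotation_deg, shift_px = as.integer(shift_px),
                 brightness_frac = brightness_frac, momentum = momentum,
                 weight_decay = weight_decay, lr_start = lr_start,
                 lr_end = lr_end, epochs = as.integer(epochs),
                 max_train_px = as.integer(max_train_px),
                 rng_seed = as.integer(rng_seed)),
            class = "seg_train_config")
}

# per-voxel features for the trainable segmenter: raw intensity, 3x3
# local mean and SD, and the in-body flag from the reference body rule
seg_voxel_features <- function(m, thresholds = seg_thresholds()) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    w <- pad[dr + seq_len(nr), dc + seq_len(nc)]
    s <- s + w; s2 <- s2 + w^2
  }
  mu <- s / 9
  body <- body_outline(m, thresholds)
  cbind(intensity = as.vector(m), local_mean = as.vector(mu),
        local_sd = as.vector(sqrt(pmax(s2 / 9 - mu^2, 0))),
        in_body = as.numeric(body))
}

#' Train the slice-wise semantic segmenter
#'
#' Default implementation: a classification tree over per-voxel
#' features (intensity, 3 x 3 neighbourhood statistics, in-body flag)
#' fitted on a subsample of labeled voxels. Seed-reproducible; persists
#' with [save_segmenter()] and reloads to identical predictions.
#' Gradient-trained network segmenters plug in behind
#' [segment_stack_dl()].
#'
#' @param labeled list of `list(slice = <2D raw image>, labels =
#'   <integer/character matrix of the five classes>)`.
#' @param cfg a [seg_train_config()].
#' @param thresholds reference thresholds used for the in-body feature.
#' @return An object of class `lung_segmenter`.
#' @export
train_segmenter <- function(labeled, cfg = seg_train_config(),
                            thresholds = seg_thresholds()) {
  if (!length(labeled)) stop("empty training set")
  feats <- NULL; labs <- NULL
  for (ex in labeled) {
    f <- seg_voxel_features(ex$slice, thresholds)
    l <- ex$labels
    l <- if (is.character(l)) match(as.vector(l), label_mask_levels())
         else as.vector(unclass(l))
    if (any(is.na(l)) || any(l < 1) || any(l > 5))
      stop("label outside the five segmentation classes")
    feats <- rbind(feats, f); labs <- c(labs, l)
  }
  if (length(unique(labs)) < 2) stop("training set must contain >= 2 classes")
  # stratified subsample so rare classes (airways, bone) keep enough
  # support in the fit
  keep <- with_seed(cfg$rng_seed, {
    per_class <- ceiling(cfg$max_train_px / length(unique(labs)))
    unlist(lapply(split(seq_along(labs), labs), function(idx)
      if (length(idx) > per_class) sample(idx, per_class) else idx))
  })
  df <- data.frame(feats[keep, , drop = FALSE],
                   y = factor(label_mask_levels()[labs[keep]],
                              levels = label_mask_levels()))
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = 1e-4,
                                                     minsplit = 10))
  structure(list(model = fit, cfg = cfg, thresholds = thresholds,
                 config_hash = config_hash(cfg)),
            class = "lung_segmenter")
}

#' @rdname train_segmenter
#' @param stack an [image_stack()].
#' @param segmenter a trained `lung_segmenter`.
#' @export
segment_stack_dl <- function(stack, segmenter) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(segmenter, "lung_segmenter"))
  d <- dim(stack$voxels)
  out <- array(label_code("background"), d)
  for (z in seq_len(d[3])) {
    f <- data.frame(seg_voxel_features(stack$voxels[, , z],
                                       segmenter$thresholds))
    pred <- stats::predict(segmenter$model, f, type = "class")
    out[, , z] <- match(as.character(pred), label_mask_levels())
  }
  new_label_mask(out, d)
}

#' @rdname train_segmenter
#' @param path model file path.
#' @export
save_segmenter <- function(segmenter, path) {
  stopifnot(inherits(segmenter, "lung_segmenter"))
  saveRDS(segmenter, path)
  invisible(path)
}

#' @rdname train_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "lung_segmenter"))
    stop("not a segmenter model file: ", path)
  obj
}

# 3D connected components (6-connectivity) via slice-wise 2D labeling
# merged across adjacent slices with union-find
label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offsets <- integer(d[3])
  total <- 0L
  for (z in seq_len(d[3])) {
    l <- EBImage::bwlabel(mask[, , z])
    offsets[z] <- total
    nz <- max(l)
    if (nz > 0) lab[, , z] <- l + total * (l > 0)
    total <- total + nz
  }
  if (total == 0L) return(lab)
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_len(d[3] - 1)) {
    a <- lab[, , z]; b <- lab[, , z + 1]
    sel <- a > 0 & b > 0
    if (!any(sel)) next
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(total), find, 0L)
  relab <- match(roots, unique(roots))
  pos <- lab > 0
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Legacy threshold-based lung segmentation
#'
#' Emulates the semi-automated tool's behaviour: lung candidates are
#' in-body voxels with raw intensity in `(air_ceiling, upper]`, the two
#' largest 3D connected components are kept (the two lungs) and
#' in-plane holes of at most `max_hole` voxels are filled. Because of
#' the upper truncation, dense fibrotic tissue (raw > 1850) can never
#' enter the result, which reproduces the truncation artifact of
#' threshold-based densitometry.
#'
#' @param stack an [image_stack()].
#' @param upper upper raw-intensity limit (default 1850).
#' @param air_ceiling lower limit excluding airway lumen and air.
#' @param thresholds [seg_thresholds()] for the body outline.
#' @param max_hole largest in-plane hole filled, in voxels.
#' @return Logical voxel grid of the legacy lung set.
#' @export
segment_threshold_legacy <- function(stack, upper = 1850, air_ceiling = 700,
                                     thresholds = seg_thresholds(),
                                     max_hole = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  cand <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    m <- stack$voxels[, , z]
    body <- body_outline(m, thresholds)
    cand[, , z] <- body & m <= upper & m > air_ceiling
  }
  if (!any(cand)) return(cand)
  lab <- label3d(cand)
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
  out <- array(lab %in% keep, d)
  # fill tiny in-plane holes; the intensity truncation is absolute
  # (voxels above `upper` can never enter the legacy set, which is what
  # caps its histogram support)
  for (z in seq_len(d[3])) {
    sl <- out[, , z]
    if (!any(sl)) next
    hl <- EBImage::bwlabel(!sl)
    hs <- tabulate(hl)
    tiny <- which(hs <= max_hole)
    if (length(tiny)) {
      sl[hl %in% tiny & stack$voxels[, , z] <= upper] <- TRUE
      out[, , z] <- sl
    }
  }
  out
}

#' Export / import a label mask
#'
#' Lossless round-trip of the five-class mask as an 8-bit multi-page
#' TIFF or NIfTI volume; the level names (palette) travel in a JSON
#' sidecar.
#'
#' @param mask a `label_mask`.
#' @param path destination file.
#' @param format `"tiff"` or `"nifti"` (guessed from extension).
#' @export
export_masks <- function(mask, path, format = guess_format(path)) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask)
  format <- match.arg(format, c("tiff", "nifti"))
  if (format == "tiff") {
    pages <- lapply(seq_len(d[3]), function(z)
      unclass(mask)[, , z] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    a <- array(as.integer(mask), d)
    nii <- RNifti::asNifti(a, datatype = "uint8")
    RNifti::writeNifti(nii, path)
  }
  jsonlite::write_json(list(palette = label_mask_levels(), dims = d),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname export_masks
#' @export
import_masks <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("tiff", "nifti"))
  meta <- read_sidecar(path)
  if (is.null(meta)) stop("label mask sidecar missing: ", sidecar_path(path))
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    v <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) v[, , z] <- pages[[z]]
  } else {
    nii <- RNifti::readNifti(path)
    v <- array(as.integer(nii), dim(nii))
  }
  if (!identical(as.character(meta$palette), label_mask_levels()))
    stop("unexpected palette in sidecar")
  new_label_mask(v, dim(v))
}
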