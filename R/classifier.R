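#' Slice-classifier configuration
#'
#' Preprocessing, augmentation and training hyperparameters for the
#' lung-part slice classifier. Slices are byte-converted and reduced to
#' `input_size` before classification; training-time augmentation draws
#' a rotation in +/-10 degrees about the image centre, an integer shift
#' of up to 4 pixels per axis and a brightness factor within +/-5%. The
#' momentum / weight-decay / learning-rate / epoch fields document the
#' schedule a gradient-trained convolutional variant would use; the
#' built-in engineered-feature random-forest classifier does not consume
#' them but stores them in its config hash so model files are
#' self-describing.
#'
#' @param input_size length-2 integer, default 224 x 224.
#' @param rotation_deg,shift_px,brightness_frac augmentation bounds.
#' @param momentum,weight_decay,lr_start,lr_end,epochs training schedule
#'   (recorded; used by pluggable gradient-trained variants).
#' @param window [byte_window()] used for byte conversion.
#' @param rng_seed integer seed for training reproducibility.
#' @export
classifier_config <- function(input_size = c(224L, 224L), rotation_deg = 10,
                              shift_px = 4L, brightness_frac = 0.05,
                              momentum = 0.9, weight_decay = 0.001,
                              lr_start = 0.001, lr_end = 0.00001,
                              epochs = 150L, window = byte_window(),
                              rng_seed = 1L) {
  if (!(lr_start > lr_end && lr_end > 0)) stop("need lr_start > lr_end > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 rotation_deg = rotation_deg, shift_px = as.integer(shift_px),
                 brightness_frac = brightness_frac, momentum = momentum,
                 weight_decay = weight_decay, lr_start = lr_start,
                 lr_end = lr_end, epochs = as.integer(epochs),
                 window = window, rng_seed = as.integer(rng_seed)),
            class = "classifier_config")
}

# exact area-weighted 1D resampling weights: out bin i covers
# [i-1, i) * n_in/n_out of the input axis; W[i, j] is the fraction of
# input pixel j covered by output pixel i
area_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1)) / scale
    }
  }
  W
}

#' Preprocess a slice for classification
#'
#' Byte conversion (skipped when the input is already a byte image)
#' followed by area-style downscaling to `cfg$input_size`. Deterministic
#' and idempotent on an already-preprocessed input.
#'
#' @param slice 2D raw-intensity matrix or `byte_image`.
#' @param cfg a [classifier_config()].
#' @return A `byte_image` matrix of size `cfg$input_size`.
#' @export
preprocess_slice <- function(slice, cfg = classifier_config()) {
  if (is.null(dim(slice)) || any(dim(slice) == 0))
    stop("slice must be a nonempty 2D image")
  b <- if (is_byte(slice)) unclass(slice) else unclass(to_byte(slice, cfg$window))
  out <- area_weights(nrow(b), cfg$input_size[1]) %*% b %*%
    t(area_weights(ncol(b), cfg$input_size[2]))
  structure(array(as.integer(clamp(round_half_up(out), 0L, 255L)),
                  dim(out)),
            class = "byte_image")
}

# nearest-neighbour rotation about the image centre; out-of-range -> 0
rotate_nn <- function(m, angle_deg) {
  if (angle_deg == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  th <- -angle_deg * pi / 180  # inverse mapping
  r <- matrix(rep(0:(nr - 1), nc), nr, nc) - ctr[1]
  cl <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - ctr[2]
  sr <- round_half_up(cos(th) * r - sin(th) * cl + ctr[1]) + 1
  sc <- round_half_up(sin(th) * r + cos(th) * cl + ctr[2]) + 1
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- matrix(0L, nr, nc)
  out[ok] <- m[cbind(sr[ok], sc[ok])]
  out
}

shift_int <- function(m, dr, dc) {
  if (dr == 0 && dc == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  okr <- src_r >= 1 & src_r <= nr; okc <- src_c >= 1 & src_c <= nc
  out[okr, okc] <- m[src_r[okr], src_c[okc]]
  out
}

#' Augment a byte slice for training
#'
#' Draws a rotation angle U(-rot, rot) about the image centre, integer
#' shifts U(-s, s) per axis and a brightness multiplier within the
#' configured fraction, reproducibly from `rng_state`.
#'
#' @param slice a `byte_image` matrix.
#' @param cfg a [classifier_config()] (or any list with `rotation_deg`,
#'   `shift_px`, `brightness_frac`).
#' @param rng_state integer seed controlling the draws.
#' @export
augment_slice <- function(slice, cfg = classifier_config(), rng_state = 1L) {
  stopifnot(is_byte(slice))
  shifts <- seq(-cfg$shift_px, cfg$shift_px)
  draws <- with_seed(rng_state, list(
    angle = runif(1, -cfg$rotation_deg, cfg$rotation_deg),
    shift = shifts[sample.int(length(shifts), 2, replace = TRUE)],
    bright = runif(1, 1 - cfg$brightness_frac, 1 + cfg$brightness_frac)))
  m <- rotate_nn(unclass(slice), draws$angle)
  m <- shift_int(m, draws$shift[1], draws$shift[2])
  m <- as.integer(clamp(round_half_up(m * draws$bright), 0L, 255L))
  structure(array(m, dim(slice)), class = "byte_image")
}

# engineered per-slice features used by the default classifier: tissue
# compartments are located by byte-domain thresholds derived from the
# raw thresholds via the byte window
slice_features <- function(byte_img, window = byte_window()) {
  b <- function(raw) round_half_up(255 * (raw - window$lo) /
                                     (window$hi - window$lo))
  m <- unclass(byte_img)
  npx <- length(m)
  body <- EBImage::fillHull(m >= b(800))
  aer <- body & m >= b(700) & m <= b(1850)
  airlike <- body & m < b(700)
  bone <- m >= b(2900)
  sep <- 0; row_mean <- 0.5; col_sd <- 0
  if (sum(aer) >= 20) {
    w <- which(aer, arr.ind = TRUE)
    mid <- median(w[, 2])
    lft <- w[, 2] <= mid; rgt <- !lft
    if (any(lft) && any(rgt))
      sep <- (mean(w[rgt, 2]) - mean(w[lft, 2])) / ncol(m)
    row_mean <- mean(w[, 1]) / nrow(m)
    col_sd <- stats::sd(w[, 2]) / ncol(m)
  }
  c(aer_frac = sum(aer) / npx, air_frac = sum(airlike) / npx,
    bone_frac = sum(bone) / npx, body_frac = sum(body) / npx,
    sep = sep, row_mean = row_mean, col_sd = col_sd)
}

#' Train the lung-part slice classifier
#'
#' The default implementation is a random forest over engineered
#' per-slice features (compartment area fractions and aerated-tissue
#' geometry), which trains in seconds on a phantom-derived set and is
#' fully seed-reproducible. Gradient-trained convolutional classifiers
#' can be plugged in behind the same [classify_stack()] contract.
#'
#' @param labeled list of `list(slice = <2D image>, label = <class>)`
#'   with labels from [slice_class_levels()]; at least two classes must
#'   be present.
#' @param cfg a [classifier_config()].
#' @return An object of class `lung_part_classifier`.
#' @export
train_classifier <- function(labeled, cfg = classifier_config()) {
  labs <- vapply(labeled, function(x) as.character(x$label), "")
  if (!all(labs %in% slice_class_levels()))
    stop("label outside the five slice classes")
  if (length(unique(labs)) < 2) stop("training set must contain >= 2 classes")
  feats <- t(vapply(labeled, function(x)
    slice_features(preprocess_slice(x$slice, cfg), cfg$window),
    numeric(7)))
  y <- factor(labs, levels = slice_class_levels())
  fit <- with_seed(cfg$rng_seed,
                   randomForest::randomForest(feats, y, ntree = 300))
  structure(list(model = fit, cfg = cfg,
                 config_hash = config_hash(cfg)),
            class = "lung_part_classifier")
}

#' Persist / restore a trained classifier
#'
#' The model file is self-describing: it carries the training config and
#' its hash, and reloads to bit-identical predictions.
#'
#' @param classifier a `lung_part_classifier`.
#' @param path destination file.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "lung_part_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "lung_part_classifier"))
    stop("not a classifier model file: ", path)
  obj
}

#' Oracle classifier backed by phantom ground truth
#'
#' Returns the true per-slice classes of a phantom; used to make
#' downstream stages deterministic in tests and validation runs.
#'
#' @param truth a `phantom_truth`.
#' @export
oracle_classifier <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  structure(list(labels = truth$slice_classes), class = "oracle_classifier")
}

#' Classify every slice of a stack
#'
#' @param stack an [image_stack()].
#' @param classifier a trained `lung_part_classifier` or an
#'   [oracle_classifier()].
#' @return Factor vector of length `n_slices` with levels
#'   [slice_class_levels()], in slice order.
#' @export
classify_stack <- function(stack, classifier) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$voxels)[3]
  if (inherits(classifier, "oracle_classifier")) {
    if (length(classifier$labels) != nz)
      stop("oracle labels do not match slice count")
    return(classifier$labels)
  }
  if (!inherits(classifier, "lung_part_classifier"))
    stop("classifier is not fitted")
  cfg <- classifier$cfg
  feats <- t(vapply(seq_len(nz), function(z)
    slice_features(preprocess_slice(stack$voxels[, , z], cfg), cfg$window),
    numeric(7)))
  factor(as.character(stats::predict(classifier$model, feats)),
         levels = slice_class_levels())
}

# majority smoothing with window 5; ties keep the original centre label
smooth_labels <- function(labels, window = 5L) {
  n <- length(labels)
  half <- window %/% 2L
  out <- labels
  chr <- as.character(labels)
  for (i in seq_len(n)) {
    win <- chr[max(1, i - half):min(n, i + half)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (chr[i] %in% top) chr[i] else top[1]
  }
  out
}

#' Select the middle-part slice run
#'
#' Applies majority smoothing (window 5) to the per-slice labels, then
#' returns the longest contiguous run of `"middle"` labels; ties are
#' broken toward the run nearer the stack centre.
#'
#' @param labels per-slice label vector (factor or character).
#' @return Integer vector of consecutive slice indices.
#' @export
select_middle_run <- function(labels) {
  if (!length(labels)) stop("empty label list")
  sm <- smooth_labels(labels)
  r <- rle(as.character(sm) == "middle")
  if (!any(r$values)) stop("no middle part found")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  len <- r$lengths[cand]
  best <- cand[len == max(len)]
  if (length(best) > 1) {
    mid <- (length(labels) + 1) / 2
    d <- abs((starts[best] + ends[best]) / 2 - mid)
    best <- best[which.min(d)]
  }
  seq(starts[best], ends[best])
}

#' Confusion matrix of slice classifications
#'
#' @param pred,truth equal-length label vectors over
#'   [slice_class_levels()].
#' @return 5 x 5 table, rows = truth, cols = predicted.
#' @export
confusion_matrix <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  lv <- slice_class_levels()
  if (!all(as.character(pred) %in% lv) || !all(as.character(truth) %in% lv))
    stop("label outside the five slice classes")
  table(truth = factor(truth, levels = lv),
        pred = factor(pred, levels = lv))
}

#' Build a labeled training set from phantoms
#'
#' Pools slices from a list of generated phantoms and subsamples at most
#' `per_class` slices per class, reproducibly.
#'
#' @param phantoms list of `list(stack=, truth=)` as returned by
#'   [generate_phantom()] / [generate_cohort()].
#' @param per_class maximum slices per class.
#' @param seed subsampling seed.
#' @export
phantom_training_slices <- function(phantoms, per_class = 100L, seed = 1L) {
  pool <- list()
  for (ph in phantoms) {
    nz <- dim(ph$stack$voxels)[3]
    for (z in seq_len(nz))
      pool[[length(pool) + 1L]] <- list(slice = ph$stack$voxels[, , z],
                                        label = ph$truth$slice_classes[z])
  }
  labs <- vapply(pool, function(x) as.character(x$label), "")
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_along(labs), labs), function(idx)
      if (length(idx) > per_class) sample(idx, per_class) else idx))
  })
  pool[sort(keep)]
}
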