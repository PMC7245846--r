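#' Construct a micro-CT image stack
#'
#' An `image_stack` holds raw scanner intensities (dimensionless,
#' nonnegative integer counts in the 16-bit range) on a regular voxel
#' grid. The array is indexed `[row, col, slice]`: the slice index runs
#' cranial to caudal, and within a slice rows run anterior (top) to
#' posterior (bottom). Densitometry always operates on these raw values;
#' byte-converted images (see [to_byte()]) are a separate type used only
#' by the image-analysis stages.
#'
#' @param voxels 3D numeric/integer array of raw intensities, all >= 0.
#' @param voxel_size_mm length-3 positive numeric, mm per voxel edge
#'   (default 0.04 isotropic).
#' @param slice_order either `"cranial_caudal"` (default) or
#'   `"caudal_cranial"`; the latter flips page order on read.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_mm = c(0.04, 0.04, 0.04),
                        slice_order = "cranial_caudal") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all three dimensions must be >= 1")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive values")
  if (min(voxels, na.rm = TRUE) < 0) stop("intensities must be >= 0")
  slice_order <- match.arg(slice_order, c("cranial_caudal", "caudal_cranial"))
  structure(list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
                 slice_order = slice_order),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], x$slice_order))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Raw-intensity to Hounsfield-unit calibration
#'
#' Linear calibration anchored at two raw intensities: the value imaged
#' for air (-1000 HU) and for water (0 HU). The default (air = 0,
#' water = 2330) is the unique pair that satisfies the universal air
#' anchor together with the scanner's conversion of raw 1850 to -206 HU;
#' it should be overridden per scanner when the true anchors are known.
#'
#' @param intensity_air raw intensity mapped to -1000 HU.
#' @param intensity_water raw intensity mapped to 0 HU; must exceed
#'   `intensity_air`.
#' @return An object of class `voxel_calibration`.
#' @export
voxel_calibration <- function(intensity_air = 0, intensity_water = 2330) {
  if (!(intensity_water > intensity_air))
    stop("intensity_water must be greater than intensity_air")
  structure(list(intensity_air = intensity_air,
                 intensity_water = intensity_water),
            class = "voxel_calibration")
}

#' Convert raw intensity to Hounsfield units
#'
#' `HU = 1000 * (i - water) / (water - air)`. [hu_to_intensity()] is the
#' exact inverse.
#'
#' @param i raw intensity (vectorized).
#' @param calib a [voxel_calibration()].
#' @return HU values.
#' @export
intensity_to_hu <- function(i, calib = voxel_calibration()) {
  stopifnot(inherits(calib, "voxel_calibration"))
  1000 * (i - calib$intensity_water) /
    (calib$intensity_water - calib$intensity_air)
}

#' @rdname intensity_to_hu
#' @param hu Hounsfield-unit values.
#' @export
hu_to_intensity <- function(hu, calib = voxel_calibration()) {
  stopifnot(inherits(calib, "voxel_calibration"))
  calib$intensity_water +
    hu * (calib$intensity_water - calib$intensity_air) / 1000
}

#' Byte-conversion window
#'
#' Raw intensities `lo` and `hi` map linearly to byte values 0 and 255.
#' The default (0, 4095) assumes a 12-bit effective intensity range.
#'
#' @param lo,hi raw intensities; `hi > lo`.
#' @export
byte_window <- function(lo = 0, hi = 4095) {
  if (!(hi > lo)) stop("byte window requires hi > lo")
  structure(list(lo = lo, hi = hi), class = "byte_window")
}

#' Convert raw intensities to 8-bit
#'
#' Linear map `lo -> 0`, `hi -> 255`, clipped outside the window and
#' rounded half up. The result carries class `byte_image` (matrix) or
#' `byte_stack` so that downstream densitometry, which must only ever see
#' raw values, can refuse it.
#'
#' @param x an [image_stack()], or a numeric matrix/array of raw values.
#' @param window a [byte_window()].
#' @return integer data in 0..255 with class `byte_image`/`byte_stack`.
#' @export
to_byte <- function(x, window = byte_window()) {
  stopifnot(inherits(window, "byte_window"))
  conv <- function(v) {
    b <- round_half_up(255 * (v - window$lo) / (window$hi - window$lo))
    array(as.integer(clamp(b, 0L, 255L)), dim(v) %||% length(v))
  }
  if (inherits(x, "image_stack")) {
    structure(list(voxels = conv(x$voxels), voxel_size_mm = x$voxel_size_mm,
                   slice_order = x$slice_order, window = window),
              class = "byte_stack")
  } else if (inherits(x, c("byte_image", "byte_stack"))) {
    x
  } else {
    structure(conv(x), class = "byte_image")
  }
}

is_byte <- function(x) inherits(x, c("byte_image", "byte_stack"))

guess_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.(raw|bin)$", path, ignore.case = TRUE)) "raw"
  else stop("cannot guess format from extension of ", path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(stack, path) {
  meta <- list(dims = dim(stack$voxels), dtype = "uint16",
               voxel_size_mm = stack$voxel_size_mm,
               slice_order = stack$slice_order)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a stack to disk
#'
#' Lossless for integer intensities in 0..65535. Formats: multi-page
#' 16-bit TIFF (voxel size kept in a JSON sidecar), NIfTI-1 (`.nii` /
#' `.nii.gz`, voxel size in the header), or raw little-endian uint16 with
#' a JSON sidecar carrying `dims`, `dtype`, `voxel_size_mm` and
#' `slice_order`.
#'
#' @param stack an [image_stack()].
#' @param path destination file.
#' @param format `"tiff"`, `"nifti"` or `"raw"`; guessed from the
#'   extension by default.
#' @export
write_stack <- function(stack, path, format = guess_format(path)) {
  stopifnot(inherits(stack, "image_stack"))
  format <- match.arg(format, c("tiff", "nifti", "raw"))
  v <- stack$voxels
  if (max(v) > 65535) stop("intensities exceed uint16 range")
  if (format == "tiff") {
    pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    write_sidecar(stack, path)
  } else if (format == "nifti") {
    a <- array(as.integer(v), dim(v))
    a <- RNifti::`pixdim<-`(a, stack$voxel_size_mm)
    nii <- RNifti::asNifti(a, datatype = "uint16")
    RNifti::writeNifti(nii, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(v), con, size = 2L, endian = "little")
    write_sidecar(stack, path)
  }
  invisible(path)
}

#' Read a stack from disk
#'
#' Inverse of [write_stack()]; round-trips bit-exactly for integer
#' intensities. For TIFF and raw payloads the JSON sidecar written by
#' [write_stack()] restores voxel size and slice order; if a TIFF has no
#' sidecar the default 0.04 mm voxel size is assumed with a message.
#'
#' @inheritParams write_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("tiff", "nifti", "raw"))
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    v <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) v[, , z] <- pages[[z]]
    meta <- read_sidecar(path)
    if (is.null(meta)) {
      message("no sidecar for ", path, "; assuming 0.04 mm voxels")
      meta <- list(voxel_size_mm = c(0.04, 0.04, 0.04),
                   slice_order = "cranial_caudal")
    }
    stack <- image_stack(v, meta$voxel_size_mm, meta$slice_order)
  } else if (format == "nifti") {
    nii <- RNifti::readNifti(path)
    v <- array(as.integer(nii), dim(nii))
    stack <- image_stack(v, RNifti::pixdim(nii))
  } else {
    meta <- read_sidecar(path)
    if (is.null(meta)) stop("raw stack requires a JSON sidecar: ",
                            sidecar_path(path))
    if (!identical(meta$dtype, "uint16"))
      stop("unsupported dtype in sidecar: ", meta$dtype)
    n_expected <- prod(meta$dims)
    payload <- file.info(path)$size
    if (payload != 2 * n_expected)
      stop(sprintf("sidecar dims %s imply %d bytes but payload has %d",
                   paste(meta$dims, collapse = "x"), 2 * n_expected, payload))
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "integer", n = n_expected, size = 2L,
                 signed = FALSE, endian = "little")
    stack <- image_stack(array(v, meta$dims), meta$voxel_size_mm,
                         meta$slice_order)
  }
  if (stack$slice_order == "caudal_cranial") {
    stack$voxels <- stack$voxels[, , rev(seq_len(dim(stack$voxels)[3])),
                                 drop = FALSE]
    stack$slice_order <- "cranial_caudal"
  }
  stack
}
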