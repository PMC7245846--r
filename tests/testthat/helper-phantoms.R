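# shared phantom fixtures, generated once per test run; geometry is
# proportional to the default, at a size small enough to keep the suite
# fast (96 slices of 128 x 128)
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, generate_phantom(spec), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

small_spec <- function(seed = 1, disease = "control", severity = 0, ...) {
  phantom_spec(n_slices = 96L, slice_shape = c(128L, 128L),
               disease = disease, severity = severity, rng_seed = seed, ...)
}

small_phantom <- function(seed = 1, disease = "control", severity = 0) {
  cached_phantom(sprintf("small_%s_%s_%s", seed, disease, severity),
                 small_spec(seed, disease, severity))
}

# one phantom with a known fixed pose, shared by landmark tests
posed_phantom <- function() {
  cached_phantom("posed",
                 small_spec(3, rotation_deg = 10, shift_px = c(4, -6)))
}

unposed_phantom <- function() {
  cached_phantom("unposed", small_spec(3, rotation_deg = 0,
                                       shift_px = c(0, 0)))
}

lung_coverage_pct <- function(rois, truth) {
  dims <- dim(truth$lung_mask)
  idx <- c(roi_voxel_indices(rois$left, dims),
           roi_voxel_indices(rois$right, dims))
  100 * sum(truth$lung_mask[idx]) / sum(truth$lung_mask)
}
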