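test_that("every feature matches the from-definition oracle on small samples", {
  set.seed(21)
  samples <- list(
    runif(100, 0, 4000),
    rnorm(50, 1250, 120),
    c(rnorm(40, 1250, 100), rnorm(30, 2250, 100)),
    sample(c(1000, 1850, 2500), 25, replace = TRUE) + runif(25))
  for (s in samples) {
    o <- oracle_features(s)
    h <- build_histogram(s)
    mmm <- feature_mean_median_mode(s, h)
    sk <- feature_skew_kurt(s)
    auc <- feature_auc_ratio(s)
    expect_equal(mmm$mean, o$mean, tolerance = 1e-9)
    expect_equal(mmm$median, o$median, tolerance = 1e-9)
    expect_equal(mmm$mode, o$mode, tolerance = 1e-9)
    expect_equal(sk$skewness, o$skewness, tolerance = 1e-9)
    expect_equal(sk$kurtosis, o$kurtosis, tolerance = 1e-9)
    expect_equal(auc$auc_normal, o$auc_normal, tolerance = 1e-9)
    expect_equal(auc$auc_fibrotic, o$auc_fibrotic, tolerance = 1e-9)
    expect_equal(auc$auc_ratio, o$auc_ratio, tolerance = 1e-9)
  }
})

test_that("histograms conserve counts and use half-open bins", {
  set.seed(5)
  s <- runif(500, 0, 4099)
  h <- build_histogram(s)
  expect_equal(sum(h$counts), 500)
  expect_equal(h$total, 500)
  # value 1850 falls in [1850, 1860)
  h2 <- build_histogram(1850)
  expect_equal(h2$centers[h2$counts == 1], 1855)
  # single value occupies exactly one bin
  h3 <- build_histogram(rep(1234, 7))
  expect_equal(sum(h3$counts > 0), 1)
  expect_warning(build_histogram(c(100, 5000)), "clipped")
  expect_error(build_histogram(numeric(0)), "empty")
})

test_that("mean/median/mode on hand-computed samples", {
  r <- feature_mean_median_mode(c(1000, 1000, 4000))
  expect_equal(r$mean, 2000)
  expect_equal(r$median, 1000)
  expect_equal(r$mode, 1005)
  sym <- c(800, 900, 1000, 1100, 1200)
  r2 <- feature_mean_median_mode(sym)
  expect_equal(r2$mean, r2$median)
  # large Gaussian sample mean within the CLT bound
  set.seed(77)
  g <- rnorm(1e5, 1250, 120)
  expect_lt(abs(feature_mean_median_mode(g)$mean - 1250), 2)
})

test_that("FWHM of a seeded Gaussian sample is within 5% of 2.3548 sigma", {
  set.seed(99)
  g <- rnorm(1e5, 1250, 120)
  h <- build_histogram(g)
  fw <- feature_fwhm(h)
  expect_false(fw$edge_flag)
  expect_lt(abs(fw$fwhm - 2.3548 * 120), 0.05 * 2.3548 * 120)
})

test_that("FWHM degenerate and tie cases follow the stated rules", {
  # histogram that is a single bin wide
  h1 <- build_histogram(rep(50, 10), bin_width = 10, lo = 45, hi = 55)
  fw1 <- feature_fwhm(h1)
  expect_true(fw1$edge_flag)
  expect_equal(fw1$fwhm, 10)
  # two equal peaks: the lower-intensity peak is used, with a flag
  s <- c(rep(1005, 10), rep(2005, 10))
  fw2 <- feature_fwhm(build_histogram(s))
  expect_true(fw2$tie_flag)
  expect_equal(fw2$peak_center, 1005)
  expect_error(feature_fwhm(build_histogram(0)$counts), "intensity_histogram")
})

test_that("skewness and kurtosis follow the population-moment definitions", {
  expect_equal(feature_skew_kurt(c(800, 900, 1000, 1100, 1200))$skewness, 0)
  # {0,0,0,1}: m2 = 3/16, m3 = 3/32 -> skew = (3/32) / (3/16)^1.5
  r <- feature_skew_kurt(c(0, 0, 0, 1))
  expect_equal(r$skewness, (3 / 32) / (3 / 16)^1.5, tolerance = 1e-12)
  expect_equal(r$skewness, 1.1547005, tolerance = 1e-6)
  set.seed(42)
  expect_lt(abs(feature_skew_kurt(rnorm(2e5))$kurtosis), 0.05)
  expect_error(feature_skew_kurt(c(1, 2)), "at least 3")
  expect_error(feature_skew_kurt(rep(7, 10)), "zero variance")
})

test_that("AUC fractions count closed ranges and orient the ratio", {
  s <- c(runif(60, 1000, 1500), runif(30, 2000, 2500), runif(10, 300, 600))
  r <- feature_auc_ratio(s)
  expect_equal(r$auc_normal, 0.6)
  expect_equal(r$auc_fibrotic, 0.3)
  expect_equal(r$auc_ratio, 2)
  all_normal <- runif(50, 1000, 1500)
  r2 <- feature_auc_ratio(all_normal)
  expect_equal(r2$auc_normal, 1)
  expect_equal(r2$auc_fibrotic, 0)
  expect_true(is.infinite(r2$auc_ratio) && r2$infinite_flag)
})

test_that("the AUC ratio decreases strictly with fibrosis severity", {
  ratios <- vapply(c(0.2, 0.6, 1.0), function(s) {
    ph <- generate_phantom(small_spec(31, "fibrosis", s))
    feature_auc_ratio(ph$stack$voxels[ph$truth$lung_mask])$auc_ratio
  }, 0)
  expect_true(all(diff(ratios) < 0))
})

test_that("collect_intensities is order-independent and airway-invariant", {
  ph <- small_phantom(1)
  dims <- dim(ph$stack$voxels)
  set.seed(3)
  idx <- sample(which(ph$truth$lung_mask), 2000)
  a <- collect_intensities(ph$stack, idx)
  b <- collect_intensities(ph$stack, rev(idx))
  expect_equal(sort(a), sort(b))
  expect_equal(length(a), 2000)
  # adding airway voxels to the set changes nothing after exclusion
  aw_idx <- which(ph$truth$airway_mask)
  expect_gt(length(aw_idx), 50)
  c1 <- collect_intensities(ph$stack, c(idx, aw_idx),
                            ph$truth$airway_mask)
  expect_equal(sort(c1), sort(a))
  expect_equal(attr(c1, "excluded_n"), length(aw_idx))
  expect_error(collect_intensities(ph$stack, integer(0)), "empty")
  expect_error(collect_intensities(ph$stack, aw_idx,
                                   ph$truth$airway_mask),
               "after airway exclusion")
})

test_that("compute_all pools both biopsies and reports per-scope sizes", {
  ph <- small_phantom(1)
  rec <- run_pipeline(ph$stack, oracle_classifier(ph$truth),
                      oracle_segmenter(ph$truth))
  f <- rec$features
  expect_setequal(f$scope, c("left_roi", "right_roi", "both_rois",
                             "whole_lung"))
  expect_equal(f$n_voxels[f$scope == "both_rois"],
               f$n_voxels[f$scope == "left_roi"] +
                 f$n_voxels[f$scope == "right_roi"])
  # pooled mean is the voxel-weighted mean, not the average of features
  nl <- f$n_voxels[f$scope == "left_roi"]
  nr <- f$n_voxels[f$scope == "right_roi"]
  expect_equal(f$mean_raw[f$scope == "both_rois"],
               (f$mean_raw[f$scope == "left_roi"] * nl +
                  f$mean_raw[f$scope == "right_roi"] * nr) / (nl + nr),
               tolerance = 1e-9)
  # whole-lung mode of a control phantom sits in the aerated range
  expect_true(f$mode[f$scope == "whole_lung"] >= 1000 &&
                f$mode[f$scope == "whole_lung"] <= 1500)
  # HU-converted mean is consistent with the calibration
  expect_equal(f$mean_hu, intensity_to_hu(f$mean_raw), tolerance = 1e-9)
})
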