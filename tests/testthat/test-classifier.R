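test_that("preprocessing byte-converts and downscales to the input size", {
  cfg <- classifier_config()
  out <- preprocess_slice(matrix(2000L, 512, 512), cfg)
  expect_equal(dim(out), c(224, 224))
  # constant image stays constant at its byte value
  expect_true(all(out == as.integer(to_byte(matrix(2000L), cfg$window))))
  # arbitrary input dims still land on 224 x 224
  expect_equal(dim(preprocess_slice(matrix(100L, 317, 101), cfg)),
               c(224, 224))
  expect_error(preprocess_slice(numeric(0), cfg), "nonempty")
})

test_that("preprocessing is deterministic and idempotent", {
  set.seed(3)
  sl <- matrix(sample.int(4096, 300 * 300, replace = TRUE) - 1L, 300, 300)
  a <- preprocess_slice(sl)
  b <- preprocess_slice(sl)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(preprocess_slice(a)), unclass(a))
})

test_that("augmentation draws are reproducible and bounded transforms behave", {
  set.seed(8)
  sl <- structure(matrix(sample.int(256, 64 * 64, replace = TRUE) - 1L,
                         64, 64), class = "byte_image")
  cfg <- classifier_config()
  expect_identical(unclass(augment_slice(sl, cfg, 42L)),
                   unclass(augment_slice(sl, cfg, 42L)))
  # zero-width augmentation bounds give the identity
  cfg0 <- classifier_config(rotation_deg = 0, shift_px = 0L,
                            brightness_frac = 0)
  expect_identical(unclass(augment_slice(sl, cfg0, 7L)), unclass(sl))
  # brightness-only: constant image scales by the drawn factor
  cfgb <- classifier_config(rotation_deg = 0, shift_px = 0L,
                            brightness_frac = 0.05)
  const <- structure(matrix(200L, 16, 16), class = "byte_image")
  out <- augment_slice(const, cfgb, 11L)
  bright <- lungbiopsy:::with_seed(11L, {
    runif(1, 0, 0)
    sample.int(1, 2, replace = TRUE)
    runif(1, 0.95, 1.05)
  })
  expect_true(all(out == min(255L, floor(200 * bright + 0.5))))
  # 5% brightening of a constant-200 image gives constant 210
  expect_equal(floor(200 * 1.05 + 0.5), 210)
})

test_that("the trained classifier reaches 90% on held-out phantoms and persists", {
  train_ph <- lapply(1:6, function(i)
    generate_phantom(small_spec(100 + i)))
  labeled <- phantom_training_slices(train_ph, per_class = 100, seed = 1)
  clf <- train_classifier(labeled, classifier_config(rng_seed = 1))
  heldout <- lapply(c(201, 202), function(s) small_phantom(s))
  acc <- vapply(heldout, function(ph)
    mean(classify_stack(ph$stack, clf) == ph$truth$slice_classes), 0)
  expect_true(all(acc >= 0.90))

  path <- tempfile(fileext = ".rds")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  ph <- heldout[[1]]
  expect_identical(classify_stack(ph$stack, clf2),
                   classify_stack(ph$stack, clf))
  expect_equal(clf2$config_hash, clf$config_hash)
  unlink(path)

  one_class <- labeled[vapply(labeled, function(x)
    as.character(x$label) == "middle", TRUE)]
  expect_error(train_classifier(one_class), ">= 2 classes")
  bad <- list(list(slice = matrix(0, 4, 4), label = "lung"))
  expect_error(train_classifier(bad), "outside")
})

test_that("oracle classification reproduces the truth labels", {
  ph <- small_phantom(1)
  labels <- classify_stack(ph$stack, oracle_classifier(ph$truth))
  expect_identical(labels, ph$truth$slice_classes)
  expect_length(labels, dim(ph$stack$voxels)[3])
  n_mid <- sum(labels == "middle")
  expect_true(n_mid >= round(60 * 96 / 512) && n_mid <= round(100 * 96 / 512))
})

test_that("middle-run selection smooths, takes the longest run and breaks ties centrally", {
  lv <- slice_class_levels()
  mk <- function(x) factor(x, levels = lv)
  labs <- mk(c(rep("not_lung", 10), rep("top_front", 5), rep("middle", 80),
               rep("bottom_rear", 5)))
  expect_equal(select_middle_run(labs), 16:95)
  # longest of two runs wins
  labs2 <- mk(c(rep("middle", 10), rep("not_lung", 10), rep("middle", 70),
                rep("not_lung", 10)))
  expect_equal(select_middle_run(labs2), 21:90)
  # an isolated misclassification inside the run is smoothed over
  x <- c(rep("top_front", 10), rep("middle", 30), rep("bottom_rear", 10))
  x[25] <- "not_lung"
  expect_equal(select_middle_run(mk(x)), 11:40)
  expect_error(select_middle_run(mk(rep("not_lung", 20))), "no middle part")
  expect_error(select_middle_run(factor(character(0), levels = lv)),
               "empty")
  # equal-length runs: the one nearer the stack centre is chosen
  labs3 <- mk(c(rep("middle", 10), rep("not_lung", 30), rep("middle", 10),
                rep("not_lung", 6)))
  expect_equal(select_middle_run(labs3), 41:50)
})

test_that("confusion matrices count correctly", {
  lv <- slice_class_levels()
  truth <- factor(sample(lv, 50, replace = TRUE), levels = lv)
  cm <- confusion_matrix(truth, truth)
  expect_equal(sum(diag(cm)), 50)
  expect_equal(sum(cm), 50)
  cm2 <- confusion_matrix(pred = c("middle", "top_front"),
                          truth = c("middle", "middle"))
  expect_equal(cm2["middle", "middle"], 1)
  expect_equal(cm2["middle", "top_front"], 1)
  expect_error(confusion_matrix(c("middle"), c("middle", "middle")),
               "length")
  expect_error(confusion_matrix(c("lung"), c("middle")), "outside")
})
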