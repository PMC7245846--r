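# box with an 11 x 11 pixel footprint whose centre is exactly (r, c)
box_at <- function(r, c) c(r - 5, c - 5, r + 6, c + 6)

test_that("chest frame geometry from box centres", {
  b <- landmark_boxes(breastbone = box_at(100, 256), spine = box_at(300, 256))
  fr <- estimate_chest_frame(list(b))
  expect_equal(fr$center, c(200, 256))
  expect_equal(fr$axis_angle_deg, 0)
  expect_equal(fr$chest_scale, 200)
  # translation equivariance
  b2 <- landmark_boxes(box_at(110, 271), box_at(310, 271))
  fr2 <- estimate_chest_frame(list(b2))
  expect_equal(fr2$center, c(210, 271))
  expect_equal(fr2$axis_angle_deg, 0)
  expect_equal(fr2$chest_scale, 200)
  expect_error(estimate_chest_frame(list()), "no landmark boxes")
  expect_error(landmark_boxes(box_at(300, 256), box_at(100, 256)),
               "anterior")
})

test_that("biopsy ROI placement follows the stated arithmetic", {
  fr <- structure(list(center = c(200, 256), axis_angle_deg = 0,
                       chest_scale = 200), class = "chest_frame")
  rois <- place_biopsy_rois(fr, 10:20, c(512, 512))
  expect_equal(rois$left$center, c(200, 256 + 110))
  expect_equal(rois$right$center, c(200, 256 - 110))
  expect_equal(rois$left$radius, 56)
  expect_equal(rois$left$slices, 10:20)
  # disjoint disks
  expect_length(intersect(rois$left$pixels, rois$right$pixels), 0)
  expect_error(place_biopsy_rois(fr, integer(0), c(512, 512)), "empty")
  fr0 <- structure(list(center = c(200, 256), axis_angle_deg = 0,
                        chest_scale = -1), class = "chest_frame")
  expect_error(place_biopsy_rois(fr0, 1:2, c(512, 512)), "positive")
})

test_that("a disk that would exit the slice is shrunk with a warning", {
  fr <- structure(list(center = c(64, 64), axis_angle_deg = 0,
                       chest_scale = 100), class = "chest_frame")
  w <- capture_warnings(rois <- place_biopsy_rois(fr, 1:4, c(128, 128)))
  expect_true(all(grepl("reduced", w)) && length(w) >= 1)
  expect_lt(rois$left$radius, 28)
  # all pixels inside bounds
  expect_true(all(rois$left$pixels >= 1 & rois$left$pixels <= 128 * 128))
})

test_that("rotating the frame rotates ROI centres about the frame centre", {
  mk <- function(angle) structure(list(center = c(200, 250),
                                       axis_angle_deg = angle,
                                       chest_scale = 150),
                                  class = "chest_frame")
  r0 <- place_biopsy_rois(mk(0), 1:2, c(512, 512))
  for (th in c(-10, 8, 25)) {
    r1 <- place_biopsy_rois(mk(th), 1:2, c(512, 512))
    v0 <- r0$left$center - c(200, 250)
    rad <- th * pi / 180
    expected <- c(200, 250) +
      c(cos(rad) * v0[1] - sin(rad) * v0[2],
        sin(rad) * v0[1] + cos(rad) * v0[2])
    expect_equal(r1$left$center, expected, tolerance = 1e-9)
  }
})

test_that("landmarks are detected on phantom slices and match truth boxes", {
  ph <- unposed_phantom()
  z <- 48
  det <- detect_landmarks(ph$stack$voxels[, , z])
  tb <- ph$truth$landmark_boxes[[z]]
  iou <- function(a, b) {
    ir <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ic <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    ir * ic / ((a[3] - a[1]) * (a[4] - a[2]) +
                 (b[3] - b[1]) * (b[4] - b[2]) - ir * ic)
  }
  expect_gte(iou(det$breastbone, tb$breastbone), 0.5)
  expect_gte(iou(det$spine, tb$spine), 0.5)
  # breastbone is anterior to spine
  expect_lt(det$breastbone[1], det$spine[1])
})

test_that("pure-air slices raise a landmarks-not-found error", {
  set.seed(1)
  air <- matrix(as.integer(pmax(rnorm(128 * 128, 300, 50), 0)), 128, 128)
  expect_error(detect_landmarks(air), "landmarks not found")
})

test_that("anterior/posterior assignment is unchanged under rotation", {
  posed <- posed_phantom()   # rotated +10 degrees
  z <- 48
  det <- detect_landmarks(posed$stack$voxels[, , z])
  tb <- posed$truth$landmark_boxes[[z]]
  ctr <- function(b) c((b[1] + b[3] - 1) / 2, (b[2] + b[4] - 1) / 2)
  expect_lt(sqrt(sum((ctr(det$breastbone) - ctr(tb$breastbone))^2)), 4)
  expect_lt(sqrt(sum((ctr(det$spine) - ctr(tb$spine))^2)), 4)
})

test_that("chest frame recovers the phantom pose angle within 2 degrees", {
  posed <- posed_phantom()
  run <- which(posed$truth$slice_classes == "middle")
  boxes <- lapply(run, function(z)
    tryCatch(detect_landmarks(posed$stack$voxels[, , z]),
             error = function(e) NULL))
  fr <- estimate_chest_frame(boxes)
  expect_lt(abs(fr$axis_angle_deg - posed$truth$pose$rotation_deg), 2)
})

test_that("roi_voxels excludes airway voxels with an exact count", {
  ph <- small_phantom(1)
  rec_dims <- dim(ph$stack$voxels)
  run <- which(ph$truth$slice_classes == "middle")
  fr <- estimate_chest_frame(ph$truth$landmark_boxes[run])
  rois <- place_biopsy_rois(fr, run, rec_dims[1:2])
  empty <- array(FALSE, rec_dims)
  v0 <- roi_voxels(rois$left, empty)
  expect_equal(length(v0), length(roi_voxel_indices(rois$left, rec_dims)))
  expect_equal(attr(v0, "excluded_n"), 0L)
  # mask covering the whole ROI empties it
  full <- array(TRUE, rec_dims)
  expect_warning(v1 <- roi_voxels(rois$left, full), "empty")
  expect_length(v1, 0)
  # exclusion count equals the set intersection with the truth airways
  idx <- roi_voxel_indices(rois$left, rec_dims)
  v2 <- roi_voxels(rois$left, ph$truth$airway_mask)
  expect_equal(attr(v2, "excluded_n"), sum(ph$truth$airway_mask[idx]))
  expect_equal(length(v2) + attr(v2, "excluded_n"), length(idx))
})

test_that("left and right ROIs sit inside their lungs on default phantoms", {
  ph <- small_phantom(1)
  rec <- run_pipeline(ph$stack, oracle_classifier(ph$truth),
                      oracle_segmenter(ph$truth))
  dims <- dim(ph$stack$voxels)
  li <- roi_voxel_indices(rec$rois$left, dims)
  ri <- roi_voxel_indices(rec$rois$right, dims)
  expect_length(intersect(li, ri), 0)
  expect_gte(mean(ph$truth$lung_mask[li]), 0.8)
  expect_gte(mean(ph$truth$lung_mask[ri]), 0.8)
})
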