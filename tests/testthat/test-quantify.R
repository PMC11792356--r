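test_that("middle-slice selection uses the floor tie-break", {
  expect_equal(select_middle_slices(24, 10), 8:17)
  expect_equal(select_middle_slices(10, 10), 1:10)
  expect_equal(select_middle_slices(5, 1), 3L)
  expect_error(select_middle_slices(5, 6), "exceeds")
  expect_error(select_middle_slices(5, 0), "positive")
})

test_that("a constant slice yields an empty fat map", {
  m <- matrix(100, 40, 40)
  expect_false(any(adaptive_threshold(m, threshold_config())))
})

test_that("a single bright pixel on dark background is classified fat", {
  m <- matrix(0, 64, 64)
  m[30, 33] <- 255
  fat <- adaptive_threshold(m, threshold_config(block_size_px = 55))
  expect_true(fat[30, 33])
  expect_equal(sum(fat), 1)
})

test_that("adaptive threshold matches the brute-force definition", {
  set.seed(7)
  for (block in c(3, 5, 9)) {
    m <- matrix(runif(16 * 16, 0, 255), 16, 16)
    cfg <- threshold_config(block_size_px = block, offset = 3)
    mine <- adaptive_threshold(m, cfg)
    oracle <- adaptive_threshold_brute_force(m, block, cfg$gaussian_sigma_px, 3)
    expect_identical(mine, oracle)
  }
})

test_that("oversized blocks are rejected, maximal legal blocks are not", {
  m <- matrix(runif(64), 8, 8)
  expect_silent(adaptive_threshold(m, threshold_config(block_size_px = 15)))
  expect_error(adaptive_threshold(m, threshold_config(block_size_px = 17)),
               "too large")
})

test_that("segment_fat intersects with the ROIs and stays disjoint", {
  ph <- generate_phantom(small_spec(seed = 41, noise_sigma = 0,
                                    bias_amplitude = 0))
  rm <- derive_regions(ph$labels)
  img <- preprocess_volume(ph$image, body_mask = ph$labels$data > 0L)
  fat <- segment_fat(img, rm, threshold_config())
  expect_false(any(fat$intramat & fat$intermat))
  expect_true(all(rm$intramat_roi[fat$intramat]))
  expect_true(all(rm$intermat_roi[fat$intermat]))
  # empty interMAT ROI forces an empty interMAT fat mask
  rm0 <- rm
  rm0$intermat_roi[] <- FALSE
  fat0 <- segment_fat(img, rm0, threshold_config())
  expect_false(any(fat0$intermat))
})

test_that("grid mismatch between image and masks is an error", {
  ph <- generate_phantom(small_spec(seed = 43))
  rm <- derive_regions(ph$labels)
  small <- image_volume(ph$image$data[1:10, 1:10, , drop = FALSE])
  expect_error(segment_fat(small, rm), "different grids")
})

test_that("inverted polarity destroys recovery on a fat-bright phantom", {
  ph <- generate_phantom(small_spec(seed = 47, noise_sigma = 0,
                                    bias_amplitude = 0))
  rm <- derive_regions(ph$labels)
  img <- preprocess_volume(ph$image, body_mask = ph$labels$data > 0L)
  fat <- segment_fat(img, rm, threshold_config(polarity = "below"))
  expect_lte(f1_score(fat$intramat, ph$truth_intramat_mask), 0.05)
})

test_that("volumes follow voxel-count arithmetic and normalization", {
  d <- c(20, 20, 5)
  roi <- array(TRUE, d)
  masks <- structure(list(fascia_interior = roi,
                          intramat_roi = roi, intermat_roi = array(FALSE, d),
                          femur = array(FALSE, d),
                          pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3),
                     class = "region_masks")
  fat_mask <- array(FALSE, d)
  fat_mask[seq_len(1000)] <- TRUE  # exactly 1000 voxels at 1x1x3 mm
  fat <- list(intramat = fat_mask, intermat = array(FALSE, d),
              slice_range = 1:5)
  img <- image_volume(array(0, d), c(1, 1), 3)
  rep <- compute_volumes(fat, masks, img, subject_id = "toy")
  expect_equal(rep$intramat_cm3, 3.0)
  expect_equal(rep$roi_extent_mm, 15)
  expect_equal(rep$n_slices_used, 5L)
  # fat mask equal to the fascia interior gives normalized volume 1
  fat2 <- list(intramat = roi, intermat = array(FALSE, d), slice_range = 1:5)
  expect_equal(compute_volumes(fat2, masks, img)$intramat_norm, 1.0)
  # doubling pixel spacing quadruples in-plane area hence volume
  img2 <- image_volume(array(0, d), c(2, 2), 3)
  expect_equal(compute_volumes(fat, masks, img2)$intramat_cm3, 12.0)
})

test_that("zero fascia volume is an error", {
  d <- c(4, 4, 2)
  masks <- structure(list(fascia_interior = array(FALSE, d),
                          intramat_roi = array(FALSE, d),
                          intermat_roi = array(FALSE, d),
                          femur = array(FALSE, d),
                          pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3),
                     class = "region_masks")
  fat <- list(intramat = array(FALSE, d), intermat = array(FALSE, d),
              slice_range = 1:2)
  expect_error(compute_volumes(fat, masks, image_volume(array(0, d))), "fascia")
})

test_that("measured intraMAT volume is monotone in the fat fraction", {
  # block scaled to the miniature test thigh (the 55 px default suits
  # acquisition-scale 512 px slices)
  thr <- threshold_config(block_size_px = 15)
  vols <- vapply(c(0.02, 0.06, 0.12), function(f) {
    ph <- generate_phantom(small_spec(seed = 53, intramat_fraction = f,
                                      noise_sigma = 0, bias_amplitude = 0))
    quantify_subject(ph$image, ph$labels, thr_cfg = thr,
                     n_keep_slices = 4L)$intramat_cm3
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("offset calibration picks a sensible offset on a noisy phantom", {
  ph <- generate_phantom(small_spec(seed = 59))
  cfg <- calibrate_offset(ph, offsets = c(0, 10, 20), n_keep_slices = 4L)
  f1 <- attr(cfg, "calibration_f1")
  expect_length(f1, 3L)
  expect_equal(cfg$offset, as.numeric(names(which.max(f1))))
  # with Rician noise present, zero offset is never the best choice
  expect_gt(cfg$offset, 0)
})
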