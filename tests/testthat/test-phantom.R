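test_that("identical spec and seed give a bit-identical phantom", {
  sp <- small_spec(seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$truth_intramat_mask, b$truth_intramat_mask)
})

test_that("zero fat fractions produce zero truth volumes", {
  sp <- small_spec(intramat_fraction = 0, intermat_fraction = 0,
                   noise_sigma = 0, bias_amplitude = 0, seed = 2)
  ph <- generate_phantom(sp)
  expect_identical(ph$truth_intramat_cm3, 0)
  expect_identical(ph$truth_intermat_cm3, 0)
  expect_false(any(ph$truth_intramat_mask))
})

test_that("noise-free, bias-free phantom is the pure tissue rendering", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0, seed = 5)
  ph <- generate_phantom(sp)
  im <- sp$intensity_model
  expect_true(all(ph$image$data %in% im))
  # all non-fat muscle voxels render at the muscle intensity
  muscle <- ph$labels$data >= 10L & !ph$truth_intramat_mask
  expect_true(all(ph$image$data[muscle] == im[["muscle"]]))
  # all ground-truth fat voxels render at the fat intensity
  expect_true(all(ph$image$data[ph$truth_intramat_mask] == im[["fat"]]))
  expect_true(all(ph$image$data[ph$labels$data == 0L] == im[["background"]]))
})

test_that("truth volumes equal mask voxel counts times voxel volume", {
  sp <- small_spec(seed = 7)
  ph <- generate_phantom(sp)
  vv <- prod(sp$pixel_spacing_mm) * sp$slice_thickness_mm / 1000
  expect_equal(ph$truth_intramat_cm3, sum(ph$truth_intramat_mask) * vv)
  expect_equal(ph$truth_intermat_cm3, sum(ph$truth_intermat_mask) * vv)
  expect_gt(ph$truth_fascia_cm3, 0)
  # intraMAT and interMAT voxel sets are disjoint
  expect_false(any(ph$truth_intramat_mask & ph$truth_intermat_mask))
})

test_that("labels partition the grid into known codes", {
  ph <- generate_phantom(small_spec(seed = 3))
  expect_true(all(ph$labels$data %in% label_codes()))
  # 13 muscle compartments present by default
  expect_length(intersect(unique(as.vector(ph$labels$data)), 10:22), 13L)
  # intraMAT truth lies inside muscle compartments, interMAT inside code 2
  expect_true(all(ph$labels$data[ph$truth_intramat_mask] >= 10L))
  expect_true(all(ph$labels$data[ph$truth_intermat_mask] == 2L))
})

test_that("raising intramat_fraction never decreases the truth volume", {
  vols <- vapply(c(0.01, 0.04, 0.08, 0.15), function(f)
    generate_phantom(small_spec(intramat_fraction = f, seed = 9))$truth_intramat_cm3,
    numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("impossible geometry is rejected", {
  expect_error(small_spec(femur_radius_mm = 30), "femur")
  expect_error(small_spec(fascia_radius_mm = 40), "fit")
  expect_error(small_spec(intramat_fraction = 0.95), "intramat_fraction")
  expect_error(phantom_spec(profile = "test",
                            intensity_model = c(fat = 80, muscle = 90,
                                                cortical_bone = 30,
                                                marrow = 190, background = 10)),
               "brighter")
})

test_that("cohort returns 2 x n_per_group phantoms with realized targets", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0, seed = 1)
  coh <- generate_cohort(2, c(6.0, 4.0), c(1.0, 0.5), sp, seed = 42)
  expect_length(coh$subjects, 4L)
  expect_equal(table(coh$plan$group),
               table(factor(rep(c("affected", "unaffected"), each = 2))),
               ignore_attr = TRUE)
  realized <- vapply(coh$subjects, function(s) s$phantom$truth_intramat_cm3,
                     numeric(1))
  # speckle placement realizes the drawn target up to voxel quantization
  expect_equal(realized, coh$plan$target_cm3, tolerance = 0.01)
})

test_that("zero-SD cohort degenerates to the group mean", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0, seed = 1)
  coh <- generate_cohort(3, c(5.0, 2.0), c(0, 0), sp, seed = 8)
  realized <- vapply(coh$subjects, function(s) s$phantom$truth_intramat_cm3,
                     numeric(1))
  expect_equal(realized[coh$plan$group == "affected"], rep(5.0, 3),
               tolerance = 0.005)
  expect_equal(realized[coh$plan$group == "unaffected"], rep(2.0, 3),
               tolerance = 0.005)
})

test_that("cohort targets follow the prescribed group distribution", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0)
  coh <- generate_cohort(23, c(9.9, 6.2), c(5.0, 3.5), sp, seed = 1)
  realized <- vapply(coh$subjects, function(s) s$phantom$truth_intramat_cm3,
                     numeric(1))
  m1 <- mean(realized[coh$plan$group == "affected"])
  m2 <- mean(realized[coh$plan$group == "unaffected"])
  # within 3 SE of the design means (zero-truncation shifts them up slightly)
  expect_lt(abs(m1 - 9.9), 3 * 5.0 / sqrt(23))
  expect_lt(abs(m2 - 6.2), 3 * 3.5 / sqrt(23))
})

test_that("unrealizable cohort targets raise an error naming the subject", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0)
  expect_error(cohort_plan(2, c(500, 6.2), c(0, 0), sp, seed = 1),
               "aff_01.*exceeds muscle capacity")
})

test_that("phantom round-trips through NIfTI with its truth sidecar", {
  ph <- generate_phantom(small_spec(seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir, "p1")
  img <- read_image_volume(paths[["image"]])
  lab <- read_label_map(paths[["labels"]])
  expect_equal(img$data, ph$image$data, ignore_attr = TRUE)
  expect_equal(lab$data, ph$labels$data, ignore_attr = TRUE)
  expect_equal(img$pixel_spacing_mm, ph$image$pixel_spacing_mm)
  expect_equal(img$slice_thickness_mm, ph$image$slice_thickness_mm)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$truth_intramat_cm3, ph$truth_intramat_cm3)
  expect_equal(truth$spec$seed, 13L)
})
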