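test_that("NLM maps a constant image to itself", {
  vol <- image_volume(array(42, c(12, 12, 2)))
  out <- nlm_denoise(vol, preprocess_config(nlm_h = 10))
  expect_equal(out$data, vol$data)
  # and with auto-estimated h (zero noise estimate)
  out2 <- nlm_denoise(vol, preprocess_config())
  expect_equal(out2$data, vol$data)
})

test_that("NLM matches the brute-force per-pixel definition", {
  set.seed(101)
  m <- matrix(runif(5 * 5, 0, 255), 5, 5)
  mine <- nlm_denoise(image_volume(m), preprocess_config(
    nlm_patch_radius = 1, nlm_search_radius = 1, nlm_h = 25))$data[, , 1]
  oracle <- nlm_brute_force(m, 1, 1, 25)
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("NLM reduces MSE against the clean rendering of a noisy phantom", {
  clean <- generate_phantom(small_spec(seed = 21, noise_sigma = 0,
                                       bias_amplitude = 0))
  noisy <- generate_phantom(small_spec(seed = 21, noise_sigma = 8,
                                       bias_amplitude = 0))
  # same seed, noise drawn after placement: identical anatomy and fat
  expect_identical(clean$labels$data, noisy$labels$data)
  den <- nlm_denoise(noisy$image)
  k <- 4
  mse_noisy <- mean((noisy$image$data[, , k] - clean$image$data[, , k])^2)
  mse_den <- mean((den$data[, , k] - clean$image$data[, , k])^2)
  expect_lt(mse_den, mse_noisy)
})

test_that("non-finite input is rejected", {
  bad <- array(1, c(4, 4, 1)); bad[2, 2, 1] <- NA
  expect_error(nlm_denoise(image_volume(bad)), "finite")
  expect_error(normalize_intensity(image_volume(bad)), "finite")
})

test_that("bias correction leaves a bias-free flat phantom untouched", {
  arr <- array(10, c(32, 32, 2))
  mask <- array(FALSE, dim(arr))
  ctr <- as.matrix(expand.grid(8:24, 8:24))
  for (k in 1:2) mask[cbind(ctr, k)] <- TRUE
  arr[mask] <- 100
  out <- correct_bias(image_volume(arr), preprocess_config(), mask)
  expect_lt(max(abs(out$data[mask] - arr[mask]) / arr[mask]), 0.005)
})

test_that("bias correction removes a known polynomial field", {
  nr <- 48; nc <- 48
  xn <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  yn <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  field <- 1 + 0.3 * xn - 0.2 * yn + 0.25 * xn^2 - 0.15 * xn * yn
  arr <- array(100 * field, c(nr, nc, 1))
  mask <- array(TRUE, dim(arr))
  out <- correct_bias(image_volume(arr), preprocess_config(), mask)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(out$data[mask]), 0.2 * cv(arr[mask]))
  # mean inside the mask preserved to within 1%
  expect_lt(abs(mean(out$data[mask]) / mean(arr[mask]) - 1), 0.01)
  # near-idempotence: a second pass changes intensities by < 1%
  out2 <- correct_bias(out, preprocess_config(), mask)
  expect_lt(max(abs(out2$data - out$data) / out$data), 0.01)
})

test_that("the smooth bias mode also reduces a known field", {
  nr <- 48
  xn <- matrix(seq(-1, 1, length.out = nr), nr, nr)
  field <- 1 + 0.3 * xn + 0.2 * xn^2
  arr <- array(100 * field, c(nr, nr, 1))
  mask <- array(TRUE, dim(arr))
  out <- correct_bias(image_volume(arr),
                      preprocess_config(bias_mode = "smooth",
                                        bias_smooth_sigma_mm = 15), mask)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(out$data[mask]), cv(arr[mask]))
})

test_that("bias correction rejects degenerate masks", {
  arr <- array(1, c(8, 8, 1))
  expect_error(correct_bias(image_volume(arr), preprocess_config(),
                            array(FALSE, c(8, 8, 1))), "empty")
  expect_error(correct_bias(image_volume(-arr), preprocess_config(),
                            array(TRUE, c(8, 8, 1))), "non-positive")
})

test_that("the corrector seam can swap in an external implementation", {
  arr <- array(runif(8 * 8 * 2, 50, 150), c(8, 8, 2))
  mask <- array(TRUE, dim(arr))
  identity_corrector <- function(sl, m) sl
  out <- correct_bias(image_volume(arr), preprocess_config(), mask,
                      corrector = identity_corrector)
  expect_equal(out$data, arr)
})

test_that("strict min-max normalization maps endpoints to 0 and 255", {
  arr <- array(runif(6 * 6 * 3, 10, 210), c(6, 6, 3))
  arr[1] <- 10; arr[length(arr)] <- 210
  out <- normalize_intensity(image_volume(arr))
  expect_equal(min(out$data), 0)
  expect_equal(max(out$data), 255)
  # idempotence on an already-normalized volume
  out2 <- normalize_intensity(out)
  expect_equal(out2$data, out$data)
  # linearity
  v <- normalize_intensity(image_volume(array(c(0, 50, 100), c(3, 1, 1))))
  expect_equal(as.vector(v$data), c(0, 127.5, 255))
})

test_that("constant volumes normalize to zero with a warning", {
  expect_warning(out <- normalize_intensity(image_volume(array(7, c(4, 4, 2)))),
                 "constant")
  expect_true(all(out$data == 0))
})

test_that("percentile clipping bounds the output and clips hot pixels", {
  arr <- array(runif(20 * 20 * 2, 0, 100), c(20, 20, 2))
  arr[1, 1, 1] <- 1e5
  out <- normalize_intensity(image_volume(arr),
                             preprocess_config(normalization_mode = "percentile_clip"))
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 255)
  expect_equal(out$data[1, 1, 1], 255)
})

test_that("the full chain preserves shape and spacing and lands in [0,255]", {
  ph <- generate_phantom(small_spec(seed = 31))
  out <- preprocess_volume(ph$image, preprocess_config(),
                           body_mask = ph$labels$data > 0L)
  expect_identical(dim(out$data), dim(ph$image$data))
  expect_identical(out$pixel_spacing_mm, ph$image$pixel_spacing_mm)
  expect_identical(out$slice_thickness_mm, ph$image$slice_thickness_mm)
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 255)
})
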