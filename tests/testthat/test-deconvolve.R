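test_that("blind RL keeps intensities non-negative and conserves flux", {
  set.seed(4)
  scene <- make_gaussian_blob(64, 64, c(32, 30), sigma = 3, peak = 400) +
    make_gaussian_blob(64, 64, c(20, 44), sigma = 2, peak = 250)
  obs <- matrix(rpois(64 * 64, scene + 2), 64, 64) * 1.0
  res <- blind_deconvolve(obs, gaussian_psf(4), iterations = 10L)
  expect_true(all(res$image >= 0))
  expect_lt(abs(sum(res$image) - sum(obs)) / sum(obs), 0.01)
  expect_equal(sum(res$psf$kernel), 1, tolerance = 1e-9)
  expect_equal(res$psf$provenance, "refined")
})

test_that("deconvolving a blurred point source sharpens it", {
  blurred <- make_gaussian_blob(61, 61, c(31, 31), sigma = 2.5, peak = 100)
  res <- blind_deconvolve(blurred, gaussian_psf(sigma_to_fwhm_test(2.5)),
                          iterations = 10L)
  expect_gt(max(res$image), max(blurred))        # peak strictly increases
  expect_lt(fwhm_of(res$image), fwhm_of(blurred)) # FWHM strictly decreases
})

test_that("a delta image with a delta PSF is a fixed point", {
  ch <- matrix(0, 21, 21); ch[11, 11] <- 5
  delta <- psf(matrix(1, 1, 1))
  res <- blind_deconvolve(ch, delta, iterations = 10L)
  expect_equal(res$image, ch, tolerance = 1e-9)
  expect_equal(res$psf$kernel, matrix(1, 1, 1), tolerance = 1e-12)
})

test_that("an all-zero channel is returned unchanged with a warning", {
  ch <- matrix(0, 16, 16)
  expect_warning(res <- blind_deconvolve(ch, gaussian_psf(3)), "all-zero")
  expect_identical(res$image, ch)
})

test_that("two-step deconvolution localizes a punctum within one pixel", {
  spec <- sted_scene_spec(puncta = data.frame(offset_nm = 60, azimuth = pi / 4,
                                              peak = 400),
                          noise = FALSE)
  sc <- render_sted_scene(spec)
  prep <- gaussian_prefilter(normalize_image(sc$image))
  dec <- two_step_deconvolve(prep, gaussian_psf(80 / 20 * 1.2),
                             channels = "dyn1xa")
  pk <- detect_puncta(dec$channels$dyn1xa)[1, ]
  expect_lt(sqrt((pk$x - sc$truth$x_px)^2 + (pk$y - sc$truth$y_px)^2), 1)
})

test_that("a delta PSF on an unblurred scene leaves the image unchanged", {
  set.seed(5)
  ch <- matrix(rpois(32 * 32, 20), 32, 32) * 1.0
  img <- sted_image(list(a = ch))
  out <- two_step_deconvolve(img, psf(matrix(1, 1, 1)), channels = "a")
  expect_lt(max(abs(out$channels$a - ch)) / max(ch), 0.01)
})

test_that("two-step is at least as accurate as a single run under PSF misestimation", {
  # median punctum peak-position error over 50 noisy scenes, initial PSF 30% wide
  err_two <- err_one <- numeric(50)
  for (s in 1:50) {
    spec <- sted_scene_spec(image_size_px = c(64L, 64L),
                            az_center_px = c(32, 32),
                            puncta = data.frame(
                              offset_nm = 40,
                              azimuth = (s %% 8) * pi / 4,
                              peak = 400),
                            noise = TRUE, seed = 600L + s)
    sc <- render_sted_scene(spec)
    prep <- gaussian_prefilter(normalize_image(sc$image))
    p0 <- gaussian_psf(80 / 20 * 1.3)
    two <- two_step_deconvolve(prep, p0, channels = "dyn1xa")$channels$dyn1xa
    one <- blind_deconvolve(prep$channels$dyn1xa, p0)$image
    pe <- function(ch) {
      pk <- detect_puncta(ch)[1, ]
      sqrt((pk$x - sc$truth$x_px)^2 + (pk$y - sc$truth$y_px)^2)
    }
    err_two[s] <- pe(two); err_one[s] <- pe(one)
  }
  expect_lte(median(err_two), median(err_one))
})
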