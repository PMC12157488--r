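test_that("min-max normalization maps each channel onto [0, 1]", {
  ch <- matrix(c(12, 100, 112, 212), 2, 2)
  img <- sted_image(list(a = ch), pixel_size_nm = 20)
  out <- normalize_image(img)
  expect_equal(out$channels$a[1, 2], 0.5) # 112 between 12 and 212
  expect_equal(min(out$channels$a), 0)
  expect_equal(max(out$channels$a), 1)

  # arbitrary 16-bit-like channel: exact 0 and 1 at the extremes
  set.seed(1)
  r <- matrix(sample.int(65535, 400), 20, 20)
  out2 <- normalize_image(sted_image(list(a = r)))
  expect_identical(range(out2$channels$a), c(0, 1))

  # idempotence on an already-[0, 1] channel
  out3 <- normalize_image(out2)
  expect_equal(out3$channels$a, out2$channels$a, tolerance = 1e-12)
})

test_that("constant channels make normalization fail with the channel named", {
  img <- sted_image(list(good = matrix(runif(16), 4, 4),
                         flat = matrix(1, 4, 4)))
  expect_error(normalize_image(img), "flat")
})

test_that("the Gaussian pre-filter has unit-sum impulse response and smooths", {
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  img <- sted_image(list(a = imp))
  out <- gaussian_prefilter(img) # default radius 1.2 px as sigma
  expect_equal(sum(out$channels$a), 1, tolerance = 1e-6)
  k <- out$channels$a[13:19, 13:19]
  expect_equal(k / sum(k), gaussian_kernel_for_test(1.2, 3), tolerance = 1e-6)

  set.seed(2)
  noise <- matrix(rpois(64 * 64, 50), 64, 64) * 1.0
  sm <- gaussian_prefilter(sted_image(list(a = noise)))
  expect_lt(stats::var(as.vector(sm$channels$a)),
            stats::var(as.vector(noise)))
})

test_that("pre-filtering conserves total intensity on dark-border images", {
  sc <- render_sted_scene(sted_scene_spec(noise = FALSE,
                                          background_photons = 0))
  img <- normalize_image(sc$image)
  out <- gaussian_prefilter(img)
  for (nm in names(img$channels))
    expect_equal(sum(out$channels[[nm]]), sum(img$channels[[nm]]),
                 tolerance = 1e-6)
})

test_that("PSF estimation recovers a synthetic Gaussian spot", {
  truth <- make_gaussian_blob(41, 41, c(21, 21), sigma = 2)
  est <- estimate_psf(truth, data.frame(x = 21, y = 21), window_px = 15L)
  ref <- gaussian_kernel_for_test(2, 7)
  rms <- sqrt(mean((est$kernel - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rms, 0.01)
  expect_equal(sum(est$kernel), 1, tolerance = 1e-9)
  expect_equal(est$provenance, "measured")
})

test_that("averaging many noisy spots beats a single noisy spot", {
  ref <- gaussian_kernel_for_test(2, 7)
  spots <- expand.grid(x = c(25, 75, 125, 175, 225), y = c(25, 75))
  img <- matrix(0, 100, 250)
  for (i in seq_len(nrow(spots)))
    img <- img + make_gaussian_blob(100, 250, c(spots$x[i], spots$y[i]),
                                    sigma = 2, peak = 300)
  noisy <- with(list(), {
    set.seed(3)
    matrix(rpois(length(img), img + 1), nrow(img), ncol(img)) * 1.0
  })
  rms_to_ref <- function(p) sqrt(mean((p$kernel - ref)^2))
  one <- estimate_psf(noisy, spots[1, ], window_px = 15L)
  ten <- estimate_psf(noisy, spots, window_px = 15L)
  expect_lt(rms_to_ref(ten), rms_to_ref(one))
})

test_that("PSF estimation enforces its preconditions", {
  img <- make_gaussian_blob(41, 41, c(21, 21), sigma = 2)
  expect_error(estimate_psf(img, data.frame(x = numeric(0), y = numeric(0))),
               "at least one spot")
  expect_error(estimate_psf(img, data.frame(x = 21, y = 21), window_px = 14L),
               "odd")
  expect_error(estimate_psf(img, data.frame(x = 2, y = 2), window_px = 15L),
               "does not fit")
})
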