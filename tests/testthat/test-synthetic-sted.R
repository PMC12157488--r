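test_that("rendering is deterministic and photon counts stay non-negative", {
  spec <- sted_scene_spec(puncta = data.frame(offset_nm = c(0, 80),
                                              azimuth = c(0, pi),
                                              peak = 400),
                          noise = TRUE, seed = 11L)
  a <- render_sted_scene(spec)
  b <- render_sted_scene(spec)
  expect_identical(a$image$channels, b$image$channels)
  for (ch in a$image$channels) expect_true(all(ch >= 0))
  expect_identical(a$truth, b$truth)
})

test_that("noise-free render equals a second noise-free render and truth is complete", {
  spec <- sted_scene_spec(puncta = data.frame(offset_nm = c(-40, 60),
                                              azimuth = c(0, pi / 2),
                                              peak = 400),
                          noise = FALSE)
  sc <- render_sted_scene(spec)
  sc2 <- render_sted_scene(spec)
  expect_equal(sc$image$channels, sc2$image$channels, tolerance = 1e-12)
  # one ground-truth row per generated punctum, immutable offsets
  expect_equal(nrow(sc$truth), 2L)
  expect_equal(sc$truth$offset_nm, c(-40, 60))
  expect_setequal(names(sc$image$channels), c("bassoon", "dyn1xa", "psd95"))
})

test_that("a punctum at +100 nm lands ~5 px outside the half-max contour", {
  spec <- sted_scene_spec(puncta = data.frame(offset_nm = 100, azimuth = 0,
                                              peak = 400),
                          noise = FALSE, psf_fwhm_nm = 80)
  sc <- render_sted_scene(spec)
  b <- extract_halfmax_boundary(sc$image$channels$bassoon)[[1]]
  pk <- detect_puncta(sc$image$channels$dyn1xa)
  d <- signed_distance_to_boundary(c(pk$x[1], pk$y[1]), b,
                                   pixel_size_nm = 20)
  expect_gt(d, 100 - 20) # within one 20-nm pixel
  expect_lt(d, 100 + 20)
})

test_that("a punctum at offset 0 measures 0 within one pixel", {
  spec <- sted_scene_spec(puncta = data.frame(offset_nm = 0, azimuth = pi / 3,
                                              peak = 400),
                          noise = FALSE)
  sc <- render_sted_scene(spec)
  b <- extract_halfmax_boundary(sc$image$channels$bassoon)[[1]]
  pk <- detect_puncta(sc$image$channels$dyn1xa)
  d <- signed_distance_to_boundary(c(pk$x[1], pk$y[1]), b, 20)
  expect_lt(abs(d), 20)
})

test_that("puncta placed outside the image are rejected at spec time", {
  expect_error(
    sted_scene_spec(puncta = data.frame(offset_nm = 2000, azimuth = 0,
                                        peak = 400)),
    "outside the image")
})

test_that("marker channel follows the synapse class", {
  sp_e <- sted_scene_spec(marker_channel_kind = "excitatory", noise = FALSE)
  sp_i <- sted_scene_spec(marker_channel_kind = "inhibitory", noise = FALSE)
  expect_true("psd95" %in% names(render_sted_scene(sp_e)$image$channels))
  expect_true("gephyrin" %in% names(render_sted_scene(sp_i)$image$channels))
})

test_that("sted images round-trip through TIFF with metadata", {
  spec <- sted_scene_spec(noise = TRUE, seed = 3L)
  sc <- render_sted_scene(spec, source_id = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_sted_tiff(sc$image, path)
  back <- read_sted_tiff(path)
  expect_equal(back$pixel_size_nm, 20)
  expect_equal(names(back$channels), names(sc$image$channels))
  expect_equal(back$channels$bassoon, sc$image$channels$bassoon,
               tolerance = 1e-6)
})
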