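# Preparation stages of the STED pipeline: per-channel min-max
# normalization, Gaussian pre-filtering against Poisson noise, and PSF
# measurement from nonspecific antibody spots.

#' Min-max normalize every channel of a STED image
#'
#' Each channel is rescaled to \[0, 1\] by its own minimum and maximum, the
#' first preparation step of the pipeline.
#'
#' @param image A [sted_image]; every channel must have `max > min`.
#' @return The normalized [sted_image].
#' @export
normalize_image <- function(image) {
  image$channels <- lapply(stats::setNames(names(image$channels),
                                           names(image$channels)),
                           function(nm) {
    ch <- image$channels[[nm]]
    rng <- range(ch)
    if (rng[2] <= rng[1])
      stop(sprintf("channel '%s' is constant; min-max normalization is degenerate",
                   nm))
    (ch - rng[1]) / (rng[2] - rng[1])
  })
  image
}

#' Gaussian pre-filter
#'
#' Smooths every channel with an isotropic Gaussian to reduce Poisson noise
#' before deconvolution. The default radius of 1.2 px is interpreted as the
#' Gaussian sigma; set `interpret_as = "fwhm"` for the alternative reading.
#' Borders are handled by reflective padding, which conserves total
#' intensity on images whose signal does not touch the border.
#'
#' @param image A [sted_image].
#' @param radius_px Filter radius in pixels (> 0), default 1.2.
#' @param interpret_as `"sigma"` (default) or `"fwhm"`.
#' @return The filtered [sted_image].
#' @export
gaussian_prefilter <- function(image, radius_px = 1.2,
                               interpret_as = c("sigma", "fwhm")) {
  interpret_as <- match.arg(interpret_as)
  stopifnot(radius_px > 0)
  sigma <- if (interpret_as == "sigma") radius_px else fwhm_to_sigma(radius_px)
  k <- gaussian_kernel(sigma)
  image$channels <- lapply(image$channels, function(ch) {
    out <- conv2_same(ch, k, boundary = "reflect")
    out[out < 0] <- 0 # clamp FFT rounding error on non-negative input
    out
  })
  image
}

#' Measure a PSF from nonspecific antibody spots
#'
#' Crops a window around each listed spot, re-centers each crop on its peak
#' pixel, averages the crops, clamps negatives to zero and normalizes the
#' result to unit sum. This mirrors the practice of estimating the initial
#' PSF from isolated nonspecific antibody signals in the images themselves.
#'
#' @param image A [sted_image] or a single channel matrix.
#' @param spots Data frame or matrix with columns `x`, `y` (pixel
#'   coordinates of approximate spot centers); at least one spot.
#' @param window_px Odd window side length (default 15).
#' @param channel Channel name when `image` is a [sted_image].
#' @return A [psf] with provenance `"measured"`.
#' @export
estimate_psf <- function(image, spots, window_px = 15L, channel = NULL) {
  ch <- if (inherits(image, "sted_image")) {
    get_channel(image, channel %||% names(image$channels)[1])
  } else image
  if (window_px %% 2L == 0L) stop("'window_px' must be odd")
  spots <- as.data.frame(spots)
  if (nrow(spots) == 0L) stop("at least one spot location is required")
  r <- (window_px - 1L) %/% 2L
  acc <- matrix(0, window_px, window_px)
  for (i in seq_len(nrow(spots))) {
    cx <- round(spots$x[i]); cy <- round(spots$y[i])
    crop <- crop_window(ch, cx, cy, r,
                        sprintf("spot %d window does not fit inside the image", i))
    # re-center on the crop's peak, then re-crop from the full image
    pk <- which(crop == max(crop), arr.ind = TRUE)[1, ]
    cx <- cx + (pk[2] - (r + 1L)); cy <- cy + (pk[1] - (r + 1L))
    acc <- acc + crop_window(ch, cx, cy, r,
                             sprintf("spot %d window does not fit after re-centering", i))
  }
  avg <- acc / nrow(spots)
  avg <- avg - min(avg)          # remove the background pedestal
  avg[avg < 0] <- 0
  if (sum(avg) <= 0) stop("averaged spot window sums to zero; cannot form a PSF")
  psf(avg, provenance = "measured")
}

crop_window <- function(ch, cx, cy, r, msg) {
  if (cy - r < 1L || cy + r > nrow(ch) || cx - r < 1L || cx + r > ncol(ch))
    stop(msg)
  ch[(cy - r):(cy + r), (cx - r):(cx + r), drop = FALSE]
}
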