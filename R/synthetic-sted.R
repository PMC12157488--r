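# Synthetic STED scene generator. Produces multi-channel images with a known
# active-zone boundary and known punctum offsets so that every stage of the
# analysis pipeline has a recovery test with ground truth.

#' Specification of a synthetic STED scene
#'
#' Describes one presynaptic bouton: an elliptical active zone rendered in
#' the Bassoon channel, endocytic puncta placed at known signed offsets from
#' the active-zone boundary in the Dyn1xA channel, and a synapse-class marker
#' channel (PSD-95 for excitatory, gephyrin for inhibitory). Offsets follow
#' the analysis sign convention: negative = inside the active zone.
#'
#' @param image_size_px Integer (rows, cols) image size.
#' @param pixel_size_nm Pixel size in nm (default 20, the acquisition setting
#'   the pipeline targets).
#' @param az_center_px Numeric (x, y) active-zone center in pixels.
#' @param az_semiaxes_px Numeric (a, b) ellipse semi-axes in pixels. For
#'   `az_kind = "gaussian"` these are the Gaussian sigmas and the nominal
#'   boundary is the half-maximum ellipse with semi-axes `a*sqrt(2*log(2))`.
#' @param az_orientation_rad Ellipse orientation (radians, counter-clockwise).
#' @param az_kind `"plateau"` (ellipse indicator blurred by the PSF; boundary
#'   is the ellipse itself) or `"gaussian"` (elliptical Gaussian blob).
#' @param az_peak_intensity Expected photons at the active-zone peak.
#' @param puncta Data frame with columns `offset_nm` (signed boundary offset
#'   along the outward normal), `azimuth` (radians, position on the
#'   boundary) and `peak` (expected photons at the punctum peak).
#' @param marker_channel_kind `"excitatory"` (PSD-95) or `"inhibitory"`
#'   (gephyrin).
#' @param psf_fwhm_nm PSF full width at half maximum in nm (default 80 nm, a
#'   typical STED lateral resolution).
#' @param background_photons Constant expected background per pixel.
#' @param noise Apply Poisson noise to the expected photon counts?
#' @param seed Integer seed controlling the noise (renders are deterministic
#'   given the spec).
#' @return An object of class `sted_scene_spec`.
#' @export
sted_scene_spec <- function(image_size_px = c(90L, 90L),
                            pixel_size_nm = 20,
                            az_center_px = c(45, 45),
                            az_semiaxes_px = c(8, 8),
                            az_orientation_rad = 0,
                            az_kind = c("plateau", "gaussian"),
                            az_peak_intensity = 800,
                            puncta = data.frame(offset_nm = 0, azimuth = 0,
                                                peak = 400),
                            marker_channel_kind = c("excitatory", "inhibitory"),
                            psf_fwhm_nm = 80,
                            background_photons = 2,
                            noise = TRUE,
                            seed = 1L) {
  az_kind <- match.arg(az_kind)
  marker_channel_kind <- match.arg(marker_channel_kind)
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 16),
            pixel_size_nm > 0, all(az_semiaxes_px > 0), psf_fwhm_nm > 0,
            az_peak_intensity > 0, background_photons >= 0)
  if (!all(c("offset_nm", "azimuth", "peak") %in% names(puncta)))
    stop("'puncta' needs columns offset_nm, azimuth, peak")
  spec <- structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_nm = pixel_size_nm, az_center_px = az_center_px,
         az_semiaxes_px = az_semiaxes_px,
         az_orientation_rad = az_orientation_rad, az_kind = az_kind,
         az_peak_intensity = az_peak_intensity, puncta = puncta,
         marker_channel_kind = marker_channel_kind, psf_fwhm_nm = psf_fwhm_nm,
         background_photons = background_photons, noise = isTRUE(noise),
         seed = as.integer(seed)),
    class = "sted_scene_spec")
  # fail early if any punctum would fall outside the image
  centers <- punctum_centers(spec)
  lo <- 2; hi <- rev(spec$image_size_px) - 1 # (x max = cols, y max = rows)
  bad <- centers$x < lo | centers$x > hi[1] | centers$y < lo | centers$y > hi[2]
  if (any(bad))
    stop(sprintf("punctum %s outside the image (center (%.1f, %.1f) px)",
                 paste(which(bad), collapse = ", "),
                 centers$x[which(bad)[1]], centers$y[which(bad)[1]]))
  spec
}

# Semi-axes of the nominal (ground-truth) active-zone boundary in px.
az_boundary_semiaxes <- function(spec) {
  switch(spec$az_kind,
         plateau = spec$az_semiaxes_px,
         gaussian = spec$az_semiaxes_px * sqrt(2 * log(2)))
}

#' Ground-truth boundary point and outward normal at an azimuth
#'
#' @param spec A [sted_scene_spec].
#' @param azimuth Parametric angle(s) on the boundary ellipse (radians).
#' @return Data frame with boundary point `(bx, by)` and unit outward normal
#'   `(nx, ny)` in pixel coordinates.
#' @export
az_boundary_point <- function(spec, azimuth) {
  ab <- az_boundary_semiaxes(spec)
  phi <- spec$az_orientation_rad
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  local <- rbind(ab[1] * cos(azimuth), ab[2] * sin(azimuth))
  p <- R %*% local
  g <- R %*% rbind(cos(azimuth) / ab[1], sin(azimuth) / ab[2])
  gn <- sqrt(colSums(g^2))
  data.frame(bx = spec$az_center_px[1] + p[1, ], by = spec$az_center_px[2] + p[2, ],
             nx = g[1, ] / gn, ny = g[2, ] / gn)
}

# True punctum centers (px) implied by the spec's offsets and azimuths.
punctum_centers <- function(spec) {
  b <- az_boundary_point(spec, spec$puncta$azimuth)
  off_px <- spec$puncta$offset_nm / spec$pixel_size_nm
  data.frame(x = b$bx + off_px * b$nx, y = b$by + off_px * b$ny)
}

#' Render a synthetic STED scene
#'
#' Produces the Bassoon, Dyn1xA and synapse-marker channels as expected
#' photon-count images (active zone = blurred ellipse indicator or Gaussian
#' blob; puncta = point sources blurred by the PSF, i.e. isotropic Gaussians
#' of FWHM `psf_fwhm_nm`), adds the constant background and finally applies
#' Poisson noise if requested. Rendering is deterministic given the spec.
#'
#' @param spec A [sted_scene_spec].
#' @param source_id Identifier stored on the image.
#' @return List with `image` (a [sted_image]) and `truth`, a data frame with
#'   one row per punctum: true signed offset (nm), azimuth and true center
#'   (px).
#' @export
render_sted_scene <- function(spec, source_id = "synthetic") {
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  sigma_psf <- fwhm_to_sigma(spec$psf_fwhm_nm) / spec$pixel_size_nm

  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # x = column
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)  # y = row

  az <- switch(spec$az_kind,
    plateau = {
      ind <- ellipse_indicator(nr, nc, spec$az_center_px, spec$az_semiaxes_px,
                               spec$az_orientation_rad, supersample = 4L)
      blurred <- conv2_same(ind, gaussian_kernel(sigma_psf), "reflect")
      spec$az_peak_intensity * blurred
    },
    gaussian = {
      phi <- spec$az_orientation_rad
      dx <- xs - spec$az_center_px[1]; dy <- ys - spec$az_center_px[2]
      u <- cos(phi) * dx + sin(phi) * dy
      v <- -sin(phi) * dx + cos(phi) * dy
      spec$az_peak_intensity *
        exp(-0.5 * ((u / spec$az_semiaxes_px[1])^2 + (v / spec$az_semiaxes_px[2])^2))
    })

  centers <- punctum_centers(spec)
  dyn <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    r2 <- (xs - centers$x[i])^2 + (ys - centers$y[i])^2
    dyn <- dyn + spec$puncta$peak[i] * exp(-r2 / (2 * sigma_psf^2))
  }

  marker_off <- c(0, az_boundary_semiaxes(spec)[2] + 6) # displaced postsynaptically
  mx <- spec$az_center_px[1] + marker_off[1]
  my <- spec$az_center_px[2] + marker_off[2]
  marker <- 0.7 * spec$az_peak_intensity *
    exp(-((xs - mx)^2 + (ys - my)^2) / (2 * 3.5^2))
  marker_name <- switch(spec$marker_channel_kind,
                        excitatory = "psd95", inhibitory = "gephyrin")

  chans <- list(bassoon = az + spec$background_photons,
                dyn1xa = dyn + spec$background_photons,
                marker = marker + spec$background_photons)
  names(chans)[3] <- marker_name
  chans <- lapply(chans, function(m) { m[m < 0] <- 0; m }) # FFT rounding
  if (spec$noise)
    chans <- with_seed(spec$seed, lapply(chans, function(m) {
      matrix(stats::rpois(length(m), lambda = m), nrow(m), ncol(m))
    }))

  truth <- data.frame(punctum = seq_len(nrow(centers)),
                      offset_nm = spec$puncta$offset_nm,
                      azimuth = spec$puncta$azimuth,
                      x_px = centers$x, y_px = centers$y)
  list(image = sted_image(chans, pixel_size_nm = spec$pixel_size_nm,
                          source_id = source_id),
       truth = truth)
}

# Supersampled ellipse indicator averaged back to pixel resolution, limiting
# aliasing of the boundary before PSF blur.
ellipse_indicator <- function(nr, nc, center, semiaxes, phi, supersample = 4L) {
  s <- supersample
  # subpixel sample coordinates: pixel i covers [i - 0.5, i + 0.5]
  ysub <- (seq_len(nr * s) - 0.5) / s + 0.5
  xsub <- (seq_len(nc * s) - 0.5) / s + 0.5
  X <- matrix(rep(xsub, each = nr * s), nr * s, nc * s)
  Y <- matrix(rep(ysub, times = nc * s), nr * s, nc * s)
  dx <- X - center[1]; dy <- Y - center[2]
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  ind <- (u / semiaxes[1])^2 + (v / semiaxes[2])^2 <= 1
  # block-average s x s
  m <- matrix(0, nr, nc)
  idx_r <- rep(seq_len(nr), each = s)
  idx_c <- rep(seq_len(nc), each = s)
  m <- rowsum(t(rowsum(ind + 0, idx_r)), idx_c) / s^2
  t(m)
}
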