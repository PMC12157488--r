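#' Multi-channel STED image
#'
#' Container for a 2D multi-channel super-resolution image with a physical
#' pixel size. Channels are named numeric matrices of equal dimensions with
#' non-negative intensities; typical channel names are `"bassoon"` (active
#' zone marker), `"dyn1xa"` (endocytic protein) and `"psd95"` / `"gephyrin"`
#' (synapse-class markers).
#'
#' @param channels Named list of numeric matrices, all of the same dimension.
#' @param pixel_size_nm Physical pixel size in nanometres (> 0); STED
#'   acquisitions quantified here use 20 nm.
#' @param source_id Identifier carried into per-punctum output records.
#' @return An object of class `sted_image`.
#' @export
sted_image <- function(channels, pixel_size_nm = 20, source_id = "image") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named")
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("all channels must be matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must have identical dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a single positive number")
  structure(
    list(channels = channels, pixel_size_nm = pixel_size_nm,
         source_id = as.character(source_id)),
    class = "sted_image")
}

#' @export
print.sted_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("sted_image '%s': %d x %d px, %g nm/px, channels: %s\n",
              x$source_id, d[1], d[2], x$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sted_image <- function(x) dim(x$channels[[1]])

get_channel <- function(image, name) {
  if (!name %in% names(image$channels))
    stop(sprintf("channel '%s' not present in image '%s' (has: %s)",
                 name, image$source_id, paste(names(image$channels), collapse = ", ")))
  image$channels[[name]]
}

#' Point spread function
#'
#' Odd-sized non-negative kernel normalized to unit sum.
#'
#' @param kernel Numeric matrix with odd side lengths; negatives are clamped
#'   to zero and the kernel is renormalized.
#' @param provenance One of `"measured"` (averaged from nonspecific antibody
#'   spots), `"refined"` (returned by blind deconvolution) or `"synthetic"`.
#' @return An object of class `psf`.
#' @export
psf <- function(kernel, provenance = c("synthetic", "measured", "refined")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(kernel) || nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop("PSF kernel must be a matrix with odd side lengths")
  kernel[kernel < 0] <- 0
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel sums to zero")
  structure(list(kernel = kernel / s, provenance = provenance), class = "psf")
}

#' Synthetic Gaussian PSF
#'
#' @param fwhm_px Full width at half maximum in pixels.
#' @param radius_px Kernel half-width (default covers 4 sigma).
#' @return A [psf] with provenance `"synthetic"`.
#' @export
gaussian_psf <- function(fwhm_px, radius_px = ceiling(4 * fwhm_to_sigma(fwhm_px))) {
  psf(gaussian_kernel(fwhm_to_sigma(fwhm_px), radius_px), provenance = "synthetic")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("psf (%s): %d x %d kernel, FWHM ~ %.2f px\n", x$provenance,
              nrow(x$kernel), ncol(x$kernel), kernel_fwhm(x$kernel)))
  invisible(x)
}

# FWHM of a kernel estimated from its central row/column profiles by linear
# interpolation; used for reporting and for the deconvolution contracts.
kernel_fwhm <- function(kernel) {
  profile_fwhm <- function(p) {
    i0 <- which.max(p); half <- p[i0] / 2
    left <- right <- NA_real_
    for (i in seq(i0, 2)) if (p[i - 1] < half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break
    }
    for (i in seq(i0, length(p) - 1)) if (p[i + 1] < half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1]); break
    }
    right - left
  }
  i0 <- which(kernel == max(kernel), arr.ind = TRUE)[1, ]
  mean(c(profile_fwhm(kernel[i0[1], ]), profile_fwhm(kernel[, i0[2]])), na.rm = TRUE)
}

#' Region of interest around one presynaptic bouton
#'
#' A square crop (default 45 x 45 px) taken from a deconvolved image, holding
#' all channels plus bookkeeping used downstream: view class, exclusion state
#' and the audit value behind the view decision.
#'
#' @param pixels Named list of channel crops (square matrices, equal size).
#' @param center_px Integer (x, y) center in the source image.
#' @param source_id Source image identifier.
#' @param view `"top"`, `"side"` or `"unclassified"`.
#' @param excluded Logical; excluded ROIs take no part in distance analysis.
#' @param exclusion_reason Short reason string (e.g. `"crossing"`).
#' @param synapse_class `"excitatory"`, `"inhibitory"` or `NA`.
#' @return An object of class `roi_patch`.
#' @export
roi_patch <- function(pixels, center_px, source_id = "image",
                      view = "unclassified", excluded = FALSE,
                      exclusion_reason = NA_character_,
                      synapse_class = NA_character_) {
  d <- dim(pixels[[1]])
  if (d[1] != d[2]) stop("ROI crops must be square")
  structure(
    list(pixels = pixels, center_px = center_px, source_id = source_id,
         view = view, excluded = excluded, exclusion_reason = exclusion_reason,
         synapse_class = synapse_class, aspect_ratio = NA_real_),
    class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("roi_patch at (%d, %d) [%s]: view=%s%s\n", x$center_px[1],
              x$center_px[2], x$source_id, x$view,
              if (x$excluded) paste0(", excluded (", x$exclusion_reason, ")") else ""))
  invisible(x)
}

#' Write a STED image as a multi-channel TIFF
#'
#' Channels are written as 32-bit float pages scaled to \[0, 1\]; channel
#' names, per-channel scale factors and the pixel size are stored in a JSON
#' sidecar (`<path>.json`) so that [read_sted_tiff()] round-trips the
#' object with its photon-count scale intact.
#'
#' @param image A [sted_image].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sted_tiff <- function(image, path) {
  scales <- vapply(image$channels, function(ch) max(max(ch), 1), numeric(1))
  pages <- unname(Map(function(ch, s) ch / s, image$channels, scales))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_nm = image$pixel_size_nm,
               channels = names(image$channels),
               scales = unname(scales), source_id = image$source_id)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a STED image written by [write_sted_tiff()]
#'
#' @param path TIFF file path; the `<path>.json` sidecar is read when
#'   present.
#' @param channel_names Channel names to use when no sidecar exists.
#' @param pixel_size_nm Fallback pixel size when no sidecar exists.
#' @return A [sted_image].
#' @export
read_sted_tiff <- function(path, channel_names = NULL, pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else NULL
  nm <- channel_names %||% meta$channels %||%
    paste0("channel", seq_along(pages))
  px <- pixel_size_nm %||% meta$pixel_size_nm %||%
    stop("pixel size neither in a TIFF sidecar nor supplied")
  scales <- meta$scales %||% rep(1, length(pages))
  chans <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    attributes(p) <- list(dim = dim(p))
    p * scales[i]
  })
  names(chans) <- nm
  sted_image(chans, pixel_size_nm = px,
             source_id = meta$source_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
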