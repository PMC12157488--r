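# Segmentation stages: local-maxima punctum detection, half-maximum
# active-zone contours, ROI selection and top/side view classification.

#' Detect puncta as pixels of local maxima
#'
#' Candidate pixels are strict 3x3 neighborhood maxima above
#' `min_prominence` times the channel maximum; candidates are then accepted
#' greedily in decreasing intensity order subject to a minimum mutual
#' separation. Puncta are reported as the maxima pixels themselves, not
#' centroids.
#'
#' @param channel Numeric matrix (typically a deconvolved channel).
#' @param min_separation_px Minimum distance between accepted maxima
#'   (default 3 px).
#' @param min_prominence Intensity threshold as a fraction of the channel
#'   maximum (default 0.2).
#' @return Data frame with columns `x`, `y`, `intensity`; zero rows when the
#'   channel is flat or nothing passes the threshold.
#' @export
detect_puncta <- function(channel, min_separation_px = 3, min_prominence = 0.2) {
  empty <- data.frame(x = integer(0), y = integer(0), intensity = numeric(0))
  rng <- range(channel)
  if (rng[2] <= rng[1]) return(empty)
  thr <- min_prominence * rng[2]
  nr <- nrow(channel); nc <- ncol(channel)
  # strict local maxima against the 8-neighborhood (borders excluded)
  core <- channel[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- channel[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(x = idx[, 2] + 1L, y = idx[, 1] + 1L,
                     intensity = core[idx])
  cand <- cand[order(-cand$intensity), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    if (all(d2 >= min_separation_px^2)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Active-zone boundary at half-maximum intensity
#'
#' Closed sub-pixel contour of a marker channel at half the intensity of the
#' local maximum it encloses.
#'
#' @param contour Two-column matrix of (x, y) contour points, closed (first
#'   point equals last).
#' @param peak_px Numeric (x, y) of the enclosed local maximum.
#' @param level Contour intensity level (half the peak intensity).
#' @return An object of class `az_boundary`.
#' @export
az_boundary <- function(contour, peak_px, level) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < 4L || any(abs(contour[1, ] - contour[n, ]) > 1e-6))
    stop("contour must be closed (first point equal to last)")
  contour[n, ] <- contour[1, ] # snap away floating-point closure error
  structure(list(contour = contour, peak_px = peak_px, level = level),
            class = "az_boundary")
}

#' @export
print.az_boundary <- function(x, ...) {
  cat(sprintf("az_boundary: %d vertices, peak (%.1f, %.1f), level %.4g\n",
              nrow(x$contour) - 1L, x$peak_px[1], x$peak_px[2], x$level))
  invisible(x)
}

#' Extract half-maximum boundaries from a marker channel
#'
#' For each detected local maximum, the channel is restricted to that
#' maximum's watershed region and the closed iso-contour at half the
#' maximum's intensity is traced by marching squares with linear
#' interpolation. Maxima whose contour does not close inside the image are
#' skipped with a warning (such regions are flagged as "crossing" at ROI
#' selection and excluded anyway).
#'
#' @param channel Non-negative, non-constant numeric matrix.
#' @param min_separation_px,min_prominence Peak-detection parameters passed
#'   to [detect_puncta()] (defaults 5 px, 0.3: active-zone maxima are larger
#'   and sparser than puncta).
#' @param watershed_tolerance Minimum peak height separating watershed
#'   objects, as a fraction of the channel maximum (default 0.1).
#' @return List of [az_boundary] objects, one per usable maximum.
#' @export
extract_halfmax_boundary <- function(channel, min_separation_px = 5,
                                     min_prominence = 0.3,
                                     watershed_tolerance = 0.1) {
  rng <- range(channel)
  if (rng[2] <= rng[1]) stop("channel is constant; no boundary exists")
  peaks <- detect_puncta(channel, min_separation_px, min_prominence)
  if (nrow(peaks) == 0L) return(list())
  labels <- NULL
  if (nrow(peaks) > 1L) {
    labels <- EBImage::imageData(EBImage::watershed(
      EBImage::Image(t(channel / rng[2])), tolerance = watershed_tolerance))
    labels <- t(labels) # EBImage stores (x, y); back to (row, col)
  }
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    px <- peaks$x[i]; py <- peaks$y[i]
    z <- channel
    if (!is.null(labels)) {
      lab <- labels[py, px]
      if (lab > 0) z <- channel * (labels == lab)
    }
    level <- 0.5 * channel[py, px]
    cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                  z = z, levels = level)
    b <- pick_enclosing_contour(cl, px, py)
    if (is.null(b)) {
      warning(sprintf("half-max contour around maximum (%d, %d) does not close; skipped",
                      px, py))
      next
    }
    out[[length(out) + 1L]] <- az_boundary(b, peak_px = c(px, py), level = level)
  }
  out
}

# contourLines returns $x along rows and $y along columns; convert to the
# package's (x = col, y = row) convention and pick the smallest closed
# contour enclosing the peak.
pick_enclosing_contour <- function(cl, px, py, tol = 1e-8) {
  best <- NULL; best_area <- Inf
  for (cc in cl) {
    pts <- cbind(x = cc$y, y = cc$x)
    closed <- abs(pts[1, 1] - pts[nrow(pts), 1]) < tol &&
      abs(pts[1, 2] - pts[nrow(pts), 2]) < tol
    if (!closed) next
    if (!point_in_polygon(px, py, pts)) next
    a <- abs(polygon_area(pts))
    if (a < best_area) { best <- pts; best_area <- a }
  }
  best
}

#' Select 45x45-pixel ROIs around candidate presynapses
#'
#' One square patch per detection in which both the active-zone and punctum
#' channels carry signal. Detections whose patch does not fit inside the
#' image are dropped; patches whose active-zone half-max region touches the
#' patch border are kept but marked excluded with reason `"crossing"`, and
#' patches missing signal in either required channel are marked excluded
#' with reason `"missing_signal"`.
#'
#' @param image A deconvolved [sted_image].
#' @param detections Data frame with columns `x`, `y` (candidate centers).
#' @param roi_size_px Patch side length (default 45).
#' @param az_channel,puncta_channel Channel names (defaults `"bassoon"`,
#'   `"dyn1xa"`).
#' @param presence_fraction Minimum patch maximum relative to the image-wide
#'   channel maximum for a channel to count as present (default 0.1).
#' @return List of [roi_patch] objects.
#' @export
select_rois <- function(image, detections, roi_size_px = 45L,
                        az_channel = "bassoon", puncta_channel = "dyn1xa",
                        presence_fraction = 0.1) {
  az <- get_channel(image, az_channel)
  pu <- get_channel(image, puncta_channel)
  r <- (roi_size_px - 1L) %/% 2L
  nr <- nrow(az); nc <- ncol(az)
  az_max <- max(az); pu_max <- max(pu)
  out <- list()
  for (i in seq_len(nrow(detections))) {
    cx <- as.integer(round(detections$x[i]))
    cy <- as.integer(round(detections$y[i]))
    if (cy - r < 1L || cy + r > nr || cx - r < 1L || cx + r > nc) next # dropped
    rows <- (cy - r):(cy + r); cols <- (cx - r):(cx + r)
    crops <- lapply(image$channels, function(ch) ch[rows, cols, drop = FALSE])
    roi <- roi_patch(crops, center_px = c(cx, cy), source_id = image$source_id)
    az_crop <- crops[[az_channel]]
    if (max(az_crop) < presence_fraction * az_max ||
        max(crops[[puncta_channel]]) < presence_fraction * pu_max) {
      roi$excluded <- TRUE
      roi$exclusion_reason <- "missing_signal"
    } else if (halfmax_region_touches_border(az_crop)) {
      roi$excluded <- TRUE
      roi$exclusion_reason <- "crossing"
    }
    out[[length(out) + 1L]] <- roi
  }
  out
}

# Connected half-max region of the crop's dominant peak, tested against the
# patch border.
halfmax_region_mask <- function(az_crop) {
  pk <- which(az_crop == max(az_crop), arr.ind = TRUE)[1, ]
  mask <- az_crop >= 0.5 * max(az_crop)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask + 0)))))
  lab == lab[pk[1], pk[2]]
}

halfmax_region_touches_border <- function(az_crop) {
  m <- halfmax_region_mask(az_crop)
  any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
}

#' Classify an ROI as top or side view
#'
#' Fits the second moments of the active-zone half-max region and computes
#' the aspect ratio (major over minor axis of the moment-equivalent
#' ellipse). Ratios at or above `side_threshold` are classified as side
#' views; distance analysis downstream consumes top views only. The decision
#' value is recorded on the ROI (`aspect_ratio`) for audit.
#'
#' @param roi A non-excluded [roi_patch].
#' @param az_channel Active-zone channel name (default `"bassoon"`).
#' @param side_threshold Aspect-ratio threshold (default 1.8).
#' @return The [roi_patch] with `view` set to `"top"`, `"side"` or
#'   `"unclassified"` (no half-max region found).
#' @export
classify_view <- function(roi, az_channel = "bassoon", side_threshold = 1.8) {
  az_crop <- roi$pixels[[az_channel]]
  if (is.null(az_crop)) stop(sprintf("ROI has no channel '%s'", az_channel))
  if (max(az_crop) <= min(az_crop)) {
    roi$view <- "unclassified"
    return(roi)
  }
  m <- halfmax_region_mask(az_crop)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 3L) {
    roi$view <- "unclassified"
    return(roi)
  }
  cov_m <- stats::cov(cbind(idx[, 2], idx[, 1])) + diag(1 / 12, 2) # pixel extent
  ev <- eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(max(ev) / max(min(ev), 1e-12))
  roi$aspect_ratio <- aspect
  roi$view <- if (aspect >= side_threshold) "side" else "top"
  roi
}
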