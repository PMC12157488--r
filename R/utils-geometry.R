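# Low-level geometry and convolution helpers shared by the simulator and the
# analysis pipeline. Points are (x, y) in pixel units, pixel-centered and
# 1-based: pixel [row i, col j] has center (x = j, y = i).

#' Normalized isotropic 2D Gaussian kernel
#'
#' @param sigma_px Standard deviation in pixels (> 0).
#' @param radius_px Kernel half-width; defaults to `ceiling(4 * sigma_px)` so
#'   the truncated tail mass is negligible. The kernel side is `2*radius+1`
#'   (always odd).
#' @return Matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(sigma_px, radius_px = ceiling(4 * sigma_px)) {
  stopifnot(sigma_px > 0, radius_px >= 1)
  g <- exp(-(-radius_px:radius_px)^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

# FFT of a small odd-sized kernel embedded in an nr x nc frame with its
# center at the (1, 1) zero-lag position (wrap-around layout).
kernel_fft <- function(kernel, nr, nc) {
  kr <- (nrow(kernel) - 1L) / 2L
  kc <- (ncol(kernel) - 1L) / 2L
  if (2L * kr + 1L > nr || 2L * kc + 1L > nc)
    stop("kernel larger than image")
  big <- matrix(0, nr, nc)
  ri <- ((-kr:kr) %% nr) + 1L
  ci <- ((-kc:kc) %% nc) + 1L
  big[ri, ci] <- kernel
  stats::fft(big)
}

#' Same-size 2D convolution
#'
#' Circular (periodic) convolution via FFT, or convolution with reflective
#' padding (pad, circular-convolve, crop). The kernel must have odd side
#' lengths so that its center is well defined.
#'
#' @param x Numeric matrix.
#' @param kernel Odd-sized numeric matrix.
#' @param boundary `"circular"` or `"reflect"`.
#' @return Matrix of `dim(x)`.
#' @keywords internal
conv2_same <- function(x, kernel, boundary = c("circular", "reflect")) {
  boundary <- match.arg(boundary)
  if (boundary == "reflect") {
    kr <- (nrow(kernel) - 1L) / 2L
    kc <- (ncol(kernel) - 1L) / 2L
    xp <- pad_reflect(x, kr, kc)
    out <- conv2_same(xp, kernel, "circular")
    return(out[(kr + 1L):(kr + nrow(x)), (kc + 1L):(kc + ncol(x)), drop = FALSE])
  }
  K <- kernel_fft(kernel, nrow(x), ncol(x))
  Re(stats::fft(stats::fft(x) * K, inverse = TRUE)) / length(x)
}

pad_reflect <- function(x, kr, kc) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(kr < nr, kc < nc)
  ri <- c(if (kr > 0) (kr + 1L):2L, 1L:nr, if (kr > 0) (nr - 1L):(nr - kr))
  ci <- c(if (kc > 0) (kc + 1L):2L, 1L:nc, if (kc > 0) (nc - 1L):(nc - kc))
  x[ri, ci, drop = FALSE]
}

# Full cross-correlation of two same-size matrices; result element [1, 1] is
# the zero-lag term, lags wrap around (used by the blind PSF update).
xcorr2_full <- function(a, b) {
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / length(a)
}

rot180 <- function(m) m[nrow(m):1L, ncol(m):1L, drop = FALSE]

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py Coordinates of the query points (vectors).
#' @param poly Two-column matrix of polygon vertices (closed or open; the
#'   closing edge is implied).
#' @return Logical vector: `TRUE` when the point lies strictly inside.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) { # drop duplicated closing vertex
    xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Cumulative arc length along a polyline (two-column matrix); first entry 0.
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(seg))
}

#' Resample a closed polyline at a fixed step
#'
#' Linear interpolation along the closed curve so that consecutive samples
#' are at most `step` apart.
#' @keywords internal
resample_closed <- function(poly, step = 0.25) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  if (!(xs[1] == xs[n] && ys[1] == ys[n])) { # close
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
  }
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(length(xs) - 1L)) {
    len <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
    k <- max(1L, ceiling(len / step))
    t <- (seq_len(k) - 1L) / k
    out_x <- c(out_x, xs[i] + t * (xs[i + 1] - xs[i]))
    out_y <- c(out_y, ys[i] + t * (ys[i + 1] - ys[i]))
  }
  cbind(x = c(out_x, out_x[1]), y = c(out_y, out_y[1]))
}

# Minimum distance from point (px, py) to each segment of a polyline,
# reduced to the overall minimum. Exact point-to-segment projection.
dist_point_polyline <- function(px, py, pts) {
  ax <- pts[-nrow(pts), 1]; ay <- pts[-nrow(pts), 2]
  bx <- pts[-1, 1]; by <- pts[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# Project a point onto a polyline: returns arc-length position of the closest
# point and the perpendicular distance.
project_on_polyline <- function(px, py, pts) {
  ax <- pts[-nrow(pts), 1]; ay <- pts[-nrow(pts), 2]
  bx <- pts[-1, 1]; by <- pts[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  d <- sqrt((px - qx)^2 + (py - qy)^2)
  i <- which.min(d)
  s0 <- polyline_arclength(pts)
  list(arc = s0[i] + t[i] * sqrt(len2[i]), dist = d[i])
}

# Signed area of a polygon (shoelace); zero for degenerate boundaries.
polygon_area <- function(poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L }
  if (n < 3L) return(0)
  0.5 * sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
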