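# Fixture builders shared across tests. Everything is generated in code; no
# stored binary fixtures.

# Isotropic Gaussian blob on zero background, peak 1 at `center` (x, y).
make_gaussian_blob <- function(nr, nc, center, sigma, peak = 1) {
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  peak * exp(-((xs - center[1])^2 + (ys - center[2])^2) / (2 * sigma^2))
}

# Closed circular az_boundary with many vertices (analytic geometry tests).
make_circle_boundary <- function(center, radius, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  az_boundary(cbind(x = center[1] + radius * cos(th),
                    y = center[2] + radius * sin(th)),
              peak_px = center, level = 0.5)
}

# Smooth star-shaped closed boundary r(theta) = r0 + a*sin(k*theta + phase).
make_blob_boundary <- function(center, r0, a, k, phase, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  r <- r0 + a * sin(k * th + phase)
  az_boundary(cbind(x = center[1] + r * cos(th),
                    y = center[2] + r * sin(th)),
              peak_px = center, level = 0.5)
}

# Straight membrane along +x from (0, 0), vertices every `step` nm.
make_straight_profile <- function(id = "p1", condition = "100ms",
                                  length_nm = 1000, step = 100,
                                  az_segment = c(1L, 2L), features = list()) {
  xs <- seq(0, length_nm, by = step)
  profile_annotation(id, condition, cbind(xs, 0), az_segment, features)
}

pit_at <- function(x1, x2, kind = "pit") {
  em_feature(kind, list(type = "segment", edges = rbind(c(x1, 0), c(x2, 0))))
}

circle_feature <- function(diameter, ferritin = FALSE, kind = "vesicle") {
  em_feature(kind, list(type = "circle", center = c(500, 80),
                        diameter_nm = diameter), ferritin_positive = ferritin)
}

# independently-coded Gaussian kernel (impulse-response and PSF references)
gaussian_kernel_for_test <- function(sigma, r) {
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g / sum(g)
}

sigma_to_fwhm_test <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# reference ray-casting point-in-polygon, independent of package internals
point_in_polygon_test <- function(px, py, poly) {
  xs <- head(poly[, 1], -1); ys <- head(poly[, 2], -1)
  n <- length(xs); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

# dense point resampling of a closed polyline (distance oracle)
resample_closed_test <- function(poly, step) {
  out <- NULL
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    k <- max(1, ceiling(sqrt(sum((b - a)^2)) / step))
    t <- (0:(k - 1)) / k
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  out
}

# FWHM through the brightest pixel's row, linear interpolation
fwhm_of <- function(m) {
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  p <- m[pk[1], ]
  half <- max(p) / 2
  i0 <- which.max(p)
  left <- right <- NA_real_
  for (i in seq(i0, 2)) if (p[i - 1] < half) {
    left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break
  }
  for (i in seq(i0, length(p) - 1)) if (p[i + 1] < half) {
    right <- i + (p[i] - half) / (p[i] - p[i + 1]); break
  }
  right - left
}

# Exact two-sample KS null by exhaustive enumeration over all assignments of
# the pooled sample (distinct values assumed): P(D >= observed).
ks_exact_enumeration <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- sort(c(a, b))
  obs <- ks_statistic(a, b)
  idx <- utils::combn(n + m, n)
  ds <- apply(idx, 2, function(ia) {
    ks_statistic(pooled[ia], pooled[-ia])
  })
  mean(ds >= obs - 1e-12)
}

ks_statistic <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  max(abs(Fa - Fb))
}

# Render a batch of single-synapse scenes with one punctum each and run the
# full STED pipeline; returns records joined with the true offsets.
run_recovery_cohort <- function(offsets, azimuths, seed0,
                                config = run_config(),
                                psf_fwhm_scale = 1.1,
                                puncta_per_scene = 1L) {
  stopifnot(length(offsets) == length(azimuths))
  n_scenes <- ceiling(length(offsets) / puncta_per_scene)
  imgs <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    i <- ((s - 1L) * puncta_per_scene + 1L):min(s * puncta_per_scene,
                                                length(offsets))
    spec <- sted_scene_spec(
      puncta = data.frame(offset_nm = offsets[i], azimuth = azimuths[i],
                          peak = 400),
      noise = TRUE, seed = seed0 + s)
    imgs[[s]] <- render_sted_scene(spec, sprintf("scene%04d", s))$image
  }
  p0 <- gaussian_psf(fwhm_px = (80 / 20) * psf_fwhm_scale)
  run_sted_pipeline(imgs, config, p0)
}
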