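# Synthetic electron-micrograph annotation generator: per-condition Poisson
# structure counts, pit placement on a membrane polyline at known arc
# distances from the active zone, and diameters drawn per category within
# the classification thresholds.

#' Specification of a synthetic EM annotation dataset
#'
#' Defaults emulate a zap-and-freeze time course on cultured neurons: three
#' conditions (no stimulation, 100 ms and 1 s after a single stimulus),
#' uncoated pits peaking at 100 ms, and larger ferritin-positive endocytic
#' intermediates (large vesicles, endosomes) accumulating by 1 s. Rates are
#' expected counts per synaptic profile; all coordinates are nm.
#'
#' @param n_profiles_per_condition Profiles per condition.
#' @param conditions Character vector of timepoint labels.
#' @param structure_rates Named list: one numeric vector per condition with
#'   entries `pit`, `coated_pit`, `vesicle`, `large_vesicle`, `endosome`
#'   (expected count per profile; missing entries default to 0).
#' @param ferritin_positive_fraction Probability that a large vesicle or
#'   endosome is ferritin-positive (fluid-phase marker uptake); set to 0 to
#'   emulate slice experiments without ferritin.
#' @param pit_distance_distribution Named distribution for the arc distance
#'   (nm) from a pit's nearest edge to the active-zone edge:
#'   `list(name = "gamma", shape, scale)`, `list(name = "uniform", min,
#'   max)` or `list(name = "normal", mean, sd)` (truncated at 0).
#' @param diameter_distributions Per-category diameter samplers; defaults
#'   keep each category inside its classification window (vesicle <= 60 nm,
#'   large vesicle in (60, 100) nm, endosome >= 100 nm).
#' @param membrane_length_nm Total membrane polyline length (default 1400).
#' @param az_length_nm Active-zone stretch length (default 300, centered).
#' @param pit_width_nm Membrane footprint of a pit (default 40).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `em_scene_spec`.
#' @export
em_scene_spec <- function(n_profiles_per_condition = 100L,
                          conditions = c("no_stim", "100ms", "1s"),
                          structure_rates = list(
                            no_stim = c(pit = 0.02, coated_pit = 0.01,
                                        large_vesicle = 0.05, endosome = 0.03),
                            `100ms` = c(pit = 0.30, coated_pit = 0.01,
                                        large_vesicle = 0.08, endosome = 0.05),
                            `1s` = c(pit = 0.08, coated_pit = 0.01,
                                     large_vesicle = 0.25, endosome = 0.20)),
                          ferritin_positive_fraction = 0.8,
                          pit_distance_distribution = list(name = "gamma",
                                                           shape = 2,
                                                           scale = 20),
                          diameter_distributions = NULL,
                          membrane_length_nm = 1400,
                          az_length_nm = 300,
                          pit_width_nm = 40,
                          seed = 1L) {
  stopifnot(n_profiles_per_condition >= 1L, length(conditions) >= 1L,
            ferritin_positive_fraction >= 0, ferritin_positive_fraction <= 1,
            membrane_length_nm > az_length_nm, az_length_nm > 0,
            pit_width_nm > 0)
  missing_cond <- setdiff(conditions, names(structure_rates))
  if (length(missing_cond))
    stop("no structure_rates for condition(s): ",
         paste(missing_cond, collapse = ", "))
  for (cn in conditions)
    if (any(structure_rates[[cn]] < 0))
      stop(sprintf("negative rate in condition '%s'", cn))
  validate_distribution(pit_distance_distribution)
  if (is.null(diameter_distributions))
    diameter_distributions <- list(
      vesicle = list(name = "normal", mean = 40, sd = 6, min = 25, max = 60),
      large_vesicle = list(name = "uniform", min = 61, max = 99),
      endosome = list(name = "gamma", shape = 2, scale = 25, shift = 100))
  structure(
    list(n_profiles_per_condition = as.integer(n_profiles_per_condition),
         conditions = conditions, structure_rates = structure_rates,
         ferritin_positive_fraction = ferritin_positive_fraction,
         pit_distance_distribution = pit_distance_distribution,
         diameter_distributions = diameter_distributions,
         membrane_length_nm = membrane_length_nm,
         az_length_nm = az_length_nm, pit_width_nm = pit_width_nm,
         seed = as.integer(seed)),
    class = "em_scene_spec")
}

validate_distribution <- function(d) {
  if (is.null(d$name)) stop("distribution needs a 'name'")
  switch(d$name,
    gamma = stopifnot(d$shape > 0, d$scale > 0),
    uniform = stopifnot(d$max >= d$min, d$min >= 0),
    normal = stopifnot(d$sd >= 0),
    stop(sprintf("unknown distribution '%s'", d$name)))
  invisible(d)
}

draw_distribution <- function(d, n) {
  if (n == 0L) return(numeric(0))
  x <- switch(d$name,
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    uniform = stats::runif(n, d$min, d$max),
    normal = abs(stats::rnorm(n, d$mean, d$sd)))
  if (!is.null(d$shift)) x <- x + d$shift
  if (!is.null(d$min) && d$name != "uniform") x <- pmax(x, d$min)
  if (!is.null(d$max) && d$name != "uniform") x <- pmin(x, d$max)
  x
}

#' Simulate an annotated EM dataset with known ground truth
#'
#' Per profile, category counts are Poisson draws at the condition's rates;
#' pits are placed on the membrane polyline with their nearest edge at an
#' arc distance drawn from the pit-distance distribution (clamped to fit on
#' the membrane); vesicular structures receive diameters from their
#' category's distribution. Each profile's membrane is a straight polyline
#' under a random rigid motion, so arc lengths are known exactly.
#'
#' @param spec An [em_scene_spec].
#' @return List with `profiles` (list of [profile_annotation]) and `truth`:
#'   `counts` (per profile, per category, matching [count_structures()]
#'   output) and `pit_distances` (per pit true arc distance in nm).
#' @export
simulate_em_dataset <- function(spec) {
  stopifnot(inherits(spec, "em_scene_spec"))
  with_seed(spec$seed, {
    profiles <- list()
    counts_rows <- list()
    dist_rows <- list()
    n_vertices <- 15L
    for (cond in spec$conditions) {
      rates <- spec$structure_rates[[cond]]
      for (k in seq_len(spec$n_profiles_per_condition)) {
        pid <- sprintf("%s_p%04d", cond, k)
        geom <- random_membrane(spec, n_vertices)
        feats <- list()
        cnt <- stats::setNames(rep(0L, length(em_categories)), em_categories)
        # pits and coated pits: segments on the membrane
        for (kind in c("pit", "coated_pit")) {
          n <- stats::rpois(1L, rate_of(rates, kind))
          for (j in seq_len(n)) {
            d_true <- draw_distribution(spec$pit_distance_distribution, 1L)
            placed <- place_pit(geom, spec, d_true)
            feats[[length(feats) + 1L]] <-
              em_feature(kind, list(type = "segment", edges = placed$edges))
            cnt[kind] <- cnt[kind] + 1L
            if (kind == "pit")
              dist_rows[[length(dist_rows) + 1L]] <-
                data.frame(condition = cond, profile_id = pid,
                           distance_nm = placed$distance_nm)
          }
        }
        # vesicular structures: circles above the membrane
        for (kind in c("vesicle", "large_vesicle", "endosome")) {
          n <- stats::rpois(1L, rate_of(rates, kind))
          if (n == 0L) next
          dia <- draw_distribution(spec$diameter_distributions[[kind]], n)
          for (j in seq_len(n)) {
            fp <- kind %in% c("large_vesicle", "endosome") &&
              stats::runif(1L) < spec$ferritin_positive_fraction
            s <- stats::runif(1L, 0, spec$membrane_length_nm)
            center <- arcpos_to_point(geom$membrane, s) +
              geom$normal * (dia[j] / 2 + stats::runif(1L, 10, 60))
            feats[[length(feats) + 1L]] <-
              em_feature(kind, list(type = "circle", center = center,
                                    diameter_nm = dia[j]),
                         ferritin_positive = fp)
            cat_name <- if (fp) paste0("ferritin_", kind) else kind
            cnt[cat_name] <- cnt[cat_name] + 1L
          }
        }
        profiles[[length(profiles) + 1L]] <-
          profile_annotation(pid, cond, geom$membrane, geom$az_segment, feats)
        counts_rows[[length(counts_rows) + 1L]] <-
          cbind(data.frame(profile_id = pid, condition = cond),
                as.data.frame(as.list(cnt)))
      }
    }
    list(profiles = profiles,
         truth = list(counts = do.call(rbind, counts_rows),
                      pit_distances = if (length(dist_rows))
                        do.call(rbind, dist_rows)
                      else data.frame(condition = character(0),
                                      profile_id = character(0),
                                      distance_nm = numeric(0))))
  })
}

rate_of <- function(rates, kind) if (kind %in% names(rates)) rates[[kind]] else 0

# Straight membrane polyline under a random rigid motion; the active zone is
# the centered stretch of az_length_nm. Returns the polyline, the az vertex
# range, the unit normal, and az arc positions.
random_membrane <- function(spec, n_vertices) {
  L <- spec$membrane_length_nm
  s_vertices <- seq(0, L, length.out = n_vertices)
  az_lo <- (L - spec$az_length_nm) / 2
  az_hi <- (L + spec$az_length_nm) / 2
  # snap two vertices onto the AZ ends so az_segment is an index range
  i_lo <- which.min(abs(s_vertices - az_lo))
  i_hi <- which.min(abs(s_vertices - az_hi))
  s_vertices[i_lo] <- az_lo; s_vertices[i_hi] <- az_hi
  theta <- stats::runif(1L, 0, 2 * pi)
  origin <- stats::runif(2L, 0, 5000)
  dir <- c(cos(theta), sin(theta))
  normal <- c(-sin(theta), cos(theta))
  membrane <- cbind(origin[1] + s_vertices * dir[1],
                    origin[2] + s_vertices * dir[2])
  list(membrane = membrane, az_segment = c(i_lo, i_hi), normal = normal,
       az_arc = c(az_lo, az_hi), length = L)
}

arcpos_to_point <- function(membrane, s) {
  cum <- polyline_arclength(membrane)
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-9))
  if (i == nrow(membrane)) return(membrane[i, ])
  t <- (s - cum[i]) / (cum[i + 1] - cum[i])
  membrane[i, ] + t * (membrane[i + 1, ] - membrane[i, ])
}

# Place a pit with its nearest edge at arc distance d from the nearest
# active-zone edge, on a random side; d is clamped so the pit fits on the
# membrane. Returns the pit edge points and the realized distance.
place_pit <- function(geom, spec, d) {
  w <- spec$pit_width_nm
  tail_len <- (geom$length - diff(geom$az_arc)) / 2
  d <- min(d, tail_len - w - 1)
  d <- max(d, 0)
  side <- sample(c(-1, 1), 1L)
  if (side > 0) {
    s1 <- geom$az_arc[2] + d; s2 <- s1 + w
  } else {
    s1 <- geom$az_arc[1] - d; s2 <- s1 - w
  }
  edges <- rbind(arcpos_to_point(geom$membrane, s1),
                 arcpos_to_point(geom$membrane, s2))
  list(edges = edges, distance_nm = d)
}
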