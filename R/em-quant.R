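# Quantification of annotated electron micrographs: blinding, structure
# classification by diameter thresholds, per-profile counts, and
# pit-to-active-zone distances measured along the membrane.

#' Blind a set of identifiers
#'
#' Deterministic, seeded bijection from identifiers to opaque specimen
#' codes, emulating the randomize-and-blind step of micrograph scoring. The
#' inverse mapping is recoverable only through the stored key.
#'
#' @param ids Unique character identifiers.
#' @param seed Integer seed.
#' @return An object of class `blinding_map` with a `key` data frame
#'   (`id`, `code`).
#' @export
randomize_blind <- function(ids, seed) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  n <- length(ids)
  perm <- with_seed(seed, sample.int(n))
  width <- max(3L, nchar(as.character(n)))
  codes <- sprintf("specimen_%0*d", width, perm)
  structure(list(key = data.frame(id = ids, code = codes)),
            class = "blinding_map")
}

#' @rdname randomize_blind
#' @param map A `blinding_map`.
#' @export
blind_code <- function(map, ids) {
  i <- match(ids, map$key$id)
  if (anyNA(i)) stop("unknown id(s): ", paste(ids[is.na(i)], collapse = ", "))
  map$key$code[i]
}

#' @rdname randomize_blind
#' @param codes Opaque codes to invert through the key.
#' @export
unblind <- function(map, codes) {
  i <- match(codes, map$key$code)
  if (anyNA(i)) stop("unknown code(s): ", paste(codes[is.na(i)], collapse = ", "))
  map$key$id[i]
}

#' @rdname randomize_blind
#' @param path CSV file for the blinding key (kept separate from outputs).
#' @export
write_blinding_key <- function(map, path) {
  utils::write.csv(map$key, path, row.names = FALSE)
  invisible(path)
}

#' Classify an annotated structure
#'
#' Pits, coated pits and omega figures pass through as their annotated
#' kinds. Vesicular structures (circle geometries) are classified by
#' diameter: at most 60 nm, a synaptic vesicle; over 60 nm and under
#' 100 nm, a large endocytic vesicle (LEV); 100 nm or more, an endosome
#' (the lower bound exclusive, the upper inclusive). A ferritin-positive
#' flag promotes large vesicles and endosomes to their ferritin-positive
#' subcategories.
#'
#' @param feature An [em_feature].
#' @return Category string (one of the package's EM categories).
#' @export
classify_structure <- function(feature) {
  if (!inherits(feature, "em_feature")) stop("'feature' must be an em_feature")
  if (feature$kind %in% c("pit", "coated_pit", "omega")) return(feature$kind)
  d <- feature$geometry$diameter_nm
  if (feature$geometry$type != "circle" || is.null(d))
    stop(sprintf("vesicular feature of kind '%s' has no diameter", feature$kind))
  cat_name <- if (d <= 60) "vesicle" else if (d < 100) "large_vesicle" else "endosome"
  if (feature$ferritin_positive && cat_name != "vesicle")
    cat_name <- paste0("ferritin_", cat_name)
  cat_name
}

#' Arc distance from a pit to the active zone
#'
#' Distance from the pit edge nearest the active zone to the nearest end of
#' the active-zone segment, measured along the membrane polyline (the
#' annotation geometry lives on the membrane). Returns 0 when the pit
#' overlaps the active zone. `mode = "euclidean"` instead measures the
#' straight-line distance from the nearest pit edge to the active-zone
#' stretch, for sensitivity checks.
#'
#' @param pit An [em_feature] with segment geometry (edges on the membrane).
#' @param profile The owning [profile_annotation].
#' @param mode `"arc"` (default) or `"euclidean"`.
#' @return Distance in nm (non-negative).
#' @export
pit_az_distance <- function(pit, profile, mode = c("arc", "euclidean")) {
  mode <- match.arg(mode)
  if (!inherits(pit, "em_feature") || pit$geometry$type != "segment")
    stop("'pit' must be an em_feature with segment geometry")
  mem <- profile$membrane
  projections <- lapply(1:2, function(j)
    project_on_polyline(pit$geometry$edges[j, 1], pit$geometry$edges[j, 2], mem))
  off <- vapply(projections, `[[`, numeric(1), "dist")
  if (any(off > 2))
    stop(sprintf("profile '%s': pit edge %.1f nm off the membrane",
                 profile$profile_id, max(off)))
  cum <- polyline_arclength(mem)
  az <- sort(cum[profile$az_segment])
  pit_arc <- sort(vapply(projections, `[[`, numeric(1), "arc"))
  overlap <- pit_arc[1] <= az[2] && pit_arc[2] >= az[1]
  if (overlap) return(0)
  if (mode == "arc")
    return(max(az[1] - pit_arc[2], pit_arc[1] - az[2]))
  az_poly <- mem[profile$az_segment[1]:profile$az_segment[2], , drop = FALSE]
  min(vapply(1:2, function(j)
    dist_point_polyline(pit$geometry$edges[j, 1], pit$geometry$edges[j, 2],
                        az_poly), numeric(1)))
}

#' Per-profile structure counts
#'
#' Counts features per category (via [classify_structure()]) for every
#' non-excluded profile.
#'
#' @param profiles List of [profile_annotation] objects.
#' @return Data frame with `profile_id`, `condition` and one integer column
#'   per category; zero rows for an empty dataset.
#' @export
count_structures <- function(profiles) {
  keep <- Filter(function(p) !p$excluded, profiles)
  if (length(keep) == 0L) {
    cols <- c(list(profile_id = character(0), condition = character(0)),
              stats::setNames(rep(list(integer(0)), length(em_categories)),
                              em_categories))
    return(as.data.frame(cols))
  }
  rows <- lapply(keep, function(p) {
    cnt <- stats::setNames(rep(0L, length(em_categories)), em_categories)
    for (f in p$features) {
      cat_name <- classify_structure(f)
      cnt[cat_name] <- cnt[cat_name] + 1L
    }
    cbind(data.frame(profile_id = p$profile_id, condition = p$condition),
          as.data.frame(as.list(cnt)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean and SEM of structure counts per timepoint
#'
#' Pools profiles across replicates within each condition and reports, per
#' condition and category, the mean count per synaptic profile, the SEM
#' (sample standard deviation over the square root of the number of
#' profiles) and the number of profiles. Conditions with fewer than two
#' profiles get `NA` SEM.
#'
#' @param counts Output of [count_structures()].
#' @param conditions Optional condition ordering/whitelist; unknown
#'   condition labels in `counts` raise an error.
#' @return Long data frame: `condition`, `category`, `mean`, `sem`,
#'   `n_profiles`.
#' @export
summarize_timepoints <- function(counts, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(counts$condition)
  unknown <- setdiff(unique(counts$condition), conditions)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  cats <- intersect(em_categories, names(counts))
  rows <- list()
  for (cond in conditions) {
    sub <- counts[counts$condition == cond, , drop = FALSE]
    n <- nrow(sub)
    for (cat_name in cats) {
      v <- sub[[cat_name]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, category = cat_name,
        mean = if (n > 0) mean(v) else NA_real_,
        sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
        n_profiles = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pit-to-active-zone distances for a dataset
#'
#' Applies [pit_az_distance()] to every feature of the requested kinds
#' (uncoated pits by default) in every non-excluded profile.
#'
#' @param profiles List of [profile_annotation] objects.
#' @param kinds Feature kinds to measure (default `"pit"`).
#' @param mode Passed to [pit_az_distance()].
#' @return Data frame: `condition`, `profile_id`, `distance_nm`.
#' @export
pit_distances <- function(profiles, kinds = "pit", mode = "arc") {
  rows <- list()
  for (p in profiles) {
    if (p$excluded) next
    for (f in p$features) {
      if (!f$kind %in% kinds) next
      rows[[length(rows) + 1L]] <- data.frame(
        condition = p$condition, profile_id = p$profile_id,
        distance_nm = pit_az_distance(f, p, mode = mode))
    }
  }
  if (!length(rows))
    return(data.frame(condition = character(0), profile_id = character(0),
                      distance_nm = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
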