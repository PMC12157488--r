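# Electron-micrograph annotations: domain objects, a versioned JSON schema
# for storage, and validation. Coordinates are in nm throughout.

em_feature_kinds <- c("pit", "coated_pit", "omega", "vesicle",
                      "large_vesicle", "endosome")
em_categories <- c("pit", "coated_pit", "omega", "vesicle", "large_vesicle",
                   "endosome", "ferritin_large_vesicle", "ferritin_endosome")

#' Annotated feature of one synaptic profile
#'
#' @param kind One of `"pit"`, `"coated_pit"`, `"omega"`, `"vesicle"`,
#'   `"large_vesicle"`, `"endosome"`. Vesicular kinds are re-derived from the
#'   diameter by [classify_structure()]; the stored kind is the annotator's
#'   label.
#' @param geometry One of: `list(type = "circle", center = c(x, y),
#'   diameter_nm = d)`, `list(type = "segment", edges = <2x2 matrix>)` (pit
#'   edge points on the membrane), or `list(type = "point", at = c(x, y))`.
#' @param ferritin_positive Logical fluid-phase marker label.
#' @return An object of class `em_feature`.
#' @export
em_feature <- function(kind, geometry, ferritin_positive = FALSE) {
  if (!kind %in% em_feature_kinds)
    stop(sprintf("unknown feature kind '%s'", kind))
  if (!is.list(geometry) || is.null(geometry$type))
    stop("geometry must be a list with a 'type' field")
  if (geometry$type == "circle") {
    d <- geometry$diameter_nm
    if (is.null(d) || !is.numeric(d) || d <= 0)
      stop("circle geometry requires a positive 'diameter_nm'")
  } else if (geometry$type == "segment") {
    e <- geometry$edges
    if (is.null(e) || !is.matrix(e) || !all(dim(e) == c(2L, 2L)))
      stop("segment geometry requires a 2x2 'edges' matrix")
  } else if (geometry$type != "point") {
    stop(sprintf("unknown geometry type '%s'", geometry$type))
  }
  structure(list(kind = kind, geometry = geometry,
                 ferritin_positive = isTRUE(ferritin_positive)),
            class = "em_feature")
}

#' One annotated synaptic profile
#'
#' @param profile_id Unique identifier.
#' @param condition Timepoint label (e.g. `"no_stim"`, `"100ms"`, `"1s"`).
#' @param membrane Two-column matrix of membrane polyline vertices (nm),
#'   at least two points.
#' @param az_segment Integer (first, last) vertex indices of the active-zone
#'   stretch of the membrane.
#' @param features List of [em_feature] objects.
#' @param excluded Profiles flagged for poor morphology are skipped by
#'   [count_structures()]; the flag is always explicit, never inferred.
#' @param pit_edge_tol_nm Maximum allowed distance of pit edge points from
#'   the membrane (default 2 nm).
#' @return An object of class `profile_annotation`.
#' @export
profile_annotation <- function(profile_id, condition, membrane, az_segment,
                               features = list(), excluded = FALSE,
                               pit_edge_tol_nm = 2) {
  membrane <- as.matrix(membrane)
  if (nrow(membrane) < 2L || ncol(membrane) != 2L)
    stop(sprintf("profile '%s': membrane needs at least 2 (x, y) points", profile_id))
  az_segment <- as.integer(az_segment)
  if (length(az_segment) != 2L || az_segment[1] < 1L ||
      az_segment[2] > nrow(membrane) || az_segment[1] >= az_segment[2])
    stop(sprintf("profile '%s': az_segment must be increasing vertex indices within the membrane",
                 profile_id))
  for (i in seq_along(features)) {
    f <- features[[i]]
    if (!inherits(f, "em_feature"))
      stop(sprintf("profile '%s': feature %d is not an em_feature", profile_id, i))
    if (f$geometry$type == "segment") {
      for (j in 1:2) {
        d <- dist_point_polyline(f$geometry$edges[j, 1], f$geometry$edges[j, 2],
                                 membrane)
        if (d > pit_edge_tol_nm)
          stop(sprintf("profile '%s': feature %d pit edge %d is %.1f nm off the membrane (tolerance %g nm)",
                       profile_id, i, j, d, pit_edge_tol_nm))
      }
    }
  }
  structure(list(profile_id = as.character(profile_id),
                 condition = as.character(condition), membrane = membrane,
                 az_segment = az_segment, features = features,
                 excluded = isTRUE(excluded)),
            class = "profile_annotation")
}

#' @export
print.profile_annotation <- function(x, ...) {
  cat(sprintf("profile_annotation '%s' (%s): %d membrane vertices, %d features%s\n",
              x$profile_id, x$condition, nrow(x$membrane), length(x$features),
              if (x$excluded) ", excluded" else ""))
  invisible(x)
}

#' Write profile annotations as JSON
#'
#' Versioned schema: a top-level object with `schema_version` and a
#' `profiles` array; coordinates in nm, vertex indices 1-based.
#'
#' @param profiles List of [profile_annotation] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_em_annotations <- function(profiles, path) {
  obj <- list(
    schema_version = 1L,
    profiles = lapply(profiles, function(p) {
      list(profile_id = p$profile_id, condition = p$condition,
           excluded = p$excluded,
           membrane = unname(p$membrane),
           az_segment = p$az_segment,
           features = lapply(p$features, function(f) {
             g <- f$geometry
             geom <- switch(g$type,
               circle = list(type = "circle", center = unname(g$center),
                             diameter_nm = g$diameter_nm),
               segment = list(type = "segment", edges = unname(g$edges)),
               point = list(type = "point", at = unname(g$at)))
             list(kind = f$kind, ferritin_positive = f$ferritin_positive,
                  geometry = geom)
           }))
    }))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Parse profile annotations from JSON
#'
#' Reads and validates the schema written by [write_em_annotations()];
#' violations raise errors naming the profile and field.
#'
#' @param path JSON file path.
#' @return List of [profile_annotation] objects.
#' @export
parse_annotations <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop(sprintf("%s: unsupported or missing schema_version (expected 1)", path))
  if (is.null(obj$profiles)) stop(sprintf("%s: no 'profiles' array", path))
  lapply(obj$profiles, function(p) {
    for (fld in c("profile_id", "condition", "membrane", "az_segment"))
      if (is.null(p[[fld]]))
        stop(sprintf("%s: profile missing field '%s'", path, fld))
    membrane <- do.call(rbind, lapply(p$membrane, unlist))
    feats <- lapply(seq_along(p$features), function(i) {
      f <- p$features[[i]]
      g <- f$geometry
      if (is.null(g) || is.null(g$type))
        stop(sprintf("profile '%s': feature %d has no geometry type",
                     p$profile_id, i))
      geom <- switch(g$type,
        circle = list(type = "circle", center = unlist(g$center),
                      diameter_nm = g$diameter_nm),
        segment = list(type = "segment",
                       edges = do.call(rbind, lapply(g$edges, unlist))),
        point = list(type = "point", at = unlist(g$at)),
        stop(sprintf("profile '%s': feature %d has unknown geometry type '%s'",
                     p$profile_id, i, g$type)))
      em_feature(f$kind, geom, isTRUE(f$ferritin_positive))
    })
    profile_annotation(p$profile_id, p$condition, membrane,
                       unlist(p$az_segment), feats,
                       excluded = isTRUE(p$excluded))
  })
}
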