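# End-to-end orchestration: configuration with the pipeline's canonical
# defaults, the STED distance pipeline and the EM quantification pipeline.
# Every run can write its records plus a manifest (config, versions, input
# checksums) sufficient to reproduce it.

#' Pipeline configuration
#'
#' Collects every tunable with its canonical default: 20 nm pixels, 1.2 px
#' Gaussian pre-filter radius (read as sigma), 10 deconvolution iterations
#' per blind run, 45 px ROIs, aspect-ratio 1.8 top/side threshold, 3 px /
#' 0.2 punctum detection, the -50..+50 nm periactive band, and the >60 nm /
#' >=100 nm EM diameter thresholds.
#'
#' @param pixel_size_nm Pixel size (nm).
#' @param channel_map Named list with entries `az`, `puncta`,
#'   `excitatory_marker`, `inhibitory_marker` giving channel names.
#' @param prefilter_radius_px,prefilter_interpret Pre-filter radius and its
#'   interpretation (`"sigma"` or `"fwhm"`).
#' @param deconv_iterations Iterations per blind Richardson-Lucy run.
#' @param roi_size_px ROI side length.
#' @param side_aspect_threshold Top/side aspect-ratio threshold.
#' @param puncta_min_separation_px,puncta_min_prominence Punctum detection.
#' @param synapse_min_separation_px Minimum separation when detecting
#'   candidate synapses on the active-zone channel.
#' @param band_nm Periactive band (closed interval, nm).
#' @param n_boot Bootstrap resamples for distance summaries.
#' @param lev_diameter_nm,endosome_diameter_nm EM classification thresholds
#'   (informational; classification uses the canonical >60 / >=100 rule).
#' @param pit_distance_mode `"arc"` or `"euclidean"`.
#' @param seed Seed for the seeded stages (bootstrap, blinding).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size_nm = 20,
                       channel_map = list(az = "bassoon", puncta = "dyn1xa",
                                          excitatory_marker = "psd95",
                                          inhibitory_marker = "gephyrin"),
                       prefilter_radius_px = 1.2,
                       prefilter_interpret = "sigma",
                       deconv_iterations = 10L,
                       roi_size_px = 45L,
                       side_aspect_threshold = 1.8,
                       puncta_min_separation_px = 3,
                       puncta_min_prominence = 0.2,
                       synapse_min_separation_px = 15,
                       band_nm = c(-50, 50),
                       n_boot = 10000L,
                       lev_diameter_nm = 60,
                       endosome_diameter_nm = 100,
                       pit_distance_mode = "arc",
                       seed = 1L) {
  cfg <- list(config_version = 1L, pixel_size_nm = pixel_size_nm,
              channel_map = channel_map,
              prefilter_radius_px = prefilter_radius_px,
              prefilter_interpret = prefilter_interpret,
              deconv_iterations = as.integer(deconv_iterations),
              roi_size_px = as.integer(roi_size_px),
              side_aspect_threshold = side_aspect_threshold,
              puncta_min_separation_px = puncta_min_separation_px,
              puncta_min_prominence = puncta_min_prominence,
              synapse_min_separation_px = synapse_min_separation_px,
              band_nm = band_nm, n_boot = as.integer(n_boot),
              lev_diameter_nm = lev_diameter_nm,
              endosome_diameter_nm = endosome_diameter_nm,
              pit_distance_mode = pit_distance_mode, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  need <- c("az", "puncta", "excitatory_marker", "inhibitory_marker")
  missing <- setdiff(need, names(cfg$channel_map))
  if (length(missing))
    stop("channel_map missing entries: ", paste(missing, collapse = ", "))
  stopifnot(cfg$pixel_size_nm > 0, cfg$prefilter_radius_px > 0,
            cfg$deconv_iterations >= 1L, cfg$roi_size_px >= 9L,
            cfg$roi_size_px %% 2L == 1L, cfg$side_aspect_threshold >= 1,
            length(cfg$band_nm) == 2L, cfg$band_nm[1] <= cfg$band_nm[2],
            cfg$n_boot >= 1L,
            cfg$pit_distance_mode %in% c("arc", "euclidean"))
  invisible(cfg)
}

#' Run the STED distance pipeline
#'
#' Full composition on a batch of images: min-max normalization, Gaussian
#' pre-filter, two-step blind deconvolution of the active-zone and punctum
#' channels, candidate-synapse detection on the deconvolved active-zone
#' channel, ROI selection, top/side classification, synapse-class call from
#' the marker channels, and per-punctum signed distances, summarized per
#' synapse class. Deterministic given identical config and inputs.
#'
#' @param images List of [sted_image] objects, or character paths to TIFFs
#'   written by [write_sted_tiff()].
#' @param config A [run_config].
#' @param initial_psf A [psf] (or named per-channel list) seeding the blind
#'   deconvolution.
#' @param output_dir Optional directory: writes `punctum_records.csv`,
#'   `roi_audit.csv`, `summary.json` and `manifest.json`.
#' @return List with `records` (one row per punctum), `summaries` (per
#'   synapse class [summarize_distances()] result), `roi_audit` and
#'   `manifest`.
#' @export
run_sted_pipeline <- function(images, config, initial_psf, output_dir = NULL) {
  validate_run_config(config)
  input_paths <- NULL
  if (is.character(images)) {
    input_paths <- images
    images <- lapply(images, read_sted_tiff)
  }
  cm <- config$channel_map
  for (img in images) {
    missing <- setdiff(c(cm$az, cm$puncta), names(img$channels))
    if (length(missing))
      stop(sprintf("image '%s' is missing mapped channel(s): %s",
                   img$source_id, paste(missing, collapse = ", ")))
  }
  records <- list()
  audit <- list()
  for (img in images) {
    prepared <- gaussian_prefilter(normalize_image(img),
                                   config$prefilter_radius_px,
                                   config$prefilter_interpret)
    dec <- two_step_deconvolve(prepared, initial_psf,
                               config$deconv_iterations,
                               channels = c(cm$az, cm$puncta))
    cands <- detect_puncta(dec$channels[[cm$az]],
                           min_separation_px = config$synapse_min_separation_px,
                           min_prominence = 0.25)
    rois <- select_rois(dec, cands, config$roi_size_px,
                        az_channel = cm$az, puncta_channel = cm$puncta)
    for (roi in rois) {
      if (!roi$excluded)
        roi <- classify_view(roi, az_channel = cm$az,
                             side_threshold = config$side_aspect_threshold)
      roi$synapse_class <- call_synapse_class(roi, cm)
      audit[[length(audit) + 1L]] <- data.frame(
        source_id = roi$source_id, x_px = roi$center_px[1],
        y_px = roi$center_px[2], view = roi$view,
        aspect_ratio = roi$aspect_ratio, excluded = roi$excluded,
        exclusion_reason = roi$exclusion_reason,
        synapse_class = roi$synapse_class)
      rec <- analyze_synapse(roi, config$pixel_size_nm,
                             az_channel = cm$az, puncta_channel = cm$puncta,
                             min_separation_px = config$puncta_min_separation_px,
                             min_prominence = config$puncta_min_prominence)
      if (nrow(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(synapse_id = character(0), synapse_class = character(0),
               view = character(0), x_px = numeric(0), y_px = numeric(0),
               signed_distance_nm = numeric(0))
  rownames(records) <- NULL
  audit <- if (length(audit)) do.call(rbind, audit) else data.frame()
  summaries <- list()
  for (cls in unique(records$synapse_class)) {
    v <- records$signed_distance_nm[records$synapse_class == cls]
    summaries[[cls]] <- summarize_distances(v, band = config$band_nm,
                                            n_boot = config$n_boot,
                                            seed = config$seed)
  }
  manifest <- build_manifest(config, input_paths,
                             if (is.null(input_paths))
                               vapply(images, `[[`, character(1), "source_id")
                             else NULL)
  out <- list(records = records, summaries = summaries, roi_audit = audit,
              manifest = manifest)
  if (!is.null(output_dir)) write_sted_outputs(out, output_dir)
  out
}

call_synapse_class <- function(roi, channel_map) {
  ex <- roi$pixels[[channel_map$excitatory_marker]]
  ih <- roi$pixels[[channel_map$inhibitory_marker]]
  if (is.null(ex) && is.null(ih)) return(NA_character_)
  if (is.null(ih) || (!is.null(ex) && max(ex) >= max(ih))) "excitatory"
  else "inhibitory"
}

#' Run the EM quantification pipeline
#'
#' Parses annotations (or takes them in memory), counts structures per
#' profile, summarizes counts per condition (mean +/- SEM), measures
#' pit-to-active-zone distances and summarizes them per condition. Blinding
#' of profile identifiers never changes the numeric results.
#'
#' @param annotations Path to an annotation JSON file or a list of
#'   [profile_annotation] objects.
#' @param config A [run_config].
#' @param conditions Optional condition whitelist/ordering; unknown labels
#'   raise an error.
#' @param output_dir Optional directory: writes `structure_counts.csv`,
#'   `timepoint_summary.csv`, `pit_distances.csv` and `manifest.json`.
#' @return List with `counts`, `timepoint_summary`, `pit_distances`,
#'   `pit_distance_summaries` (per condition) and `manifest`.
#' @export
run_em_pipeline <- function(annotations, config, conditions = NULL,
                            output_dir = NULL) {
  validate_run_config(config)
  input_path <- NULL
  if (is.character(annotations)) {
    input_path <- annotations
    annotations <- parse_annotations(annotations)
  }
  counts <- count_structures(annotations)
  summary_tab <- summarize_timepoints(counts, conditions)
  dists <- pit_distances(annotations, mode = config$pit_distance_mode)
  dist_summaries <- list()
  for (cond in unique(dists$condition)) {
    v <- dists$distance_nm[dists$condition == cond]
    dist_summaries[[cond]] <- summarize_distances(v, band = config$band_nm,
                                                  n_boot = config$n_boot,
                                                  seed = config$seed)
  }
  manifest <- build_manifest(config, input_path,
                             if (is.null(input_path))
                               vapply(annotations, `[[`, character(1),
                                      "profile_id") else NULL)
  out <- list(counts = counts, timepoint_summary = summary_tab,
              pit_distances = dists, pit_distance_summaries = dist_summaries,
              manifest = manifest)
  if (!is.null(output_dir)) write_em_outputs(out, output_dir)
  out
}

build_manifest <- function(config, input_paths, input_ids) {
  inputs <- if (!is.null(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else as.list(stats::setNames(rep("in-memory", length(input_ids)), input_ids))
  list(config = unclass(config),
       package_version = as.character(utils::packageVersion("azdist")),
       inputs = inputs)
}

write_sted_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$records, file.path(dir, "punctum_records.csv"),
                   row.names = FALSE)
  utils::write.csv(out$roi_audit, file.path(dir, "roi_audit.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(lapply(out$summaries, summary_to_list),
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "summary.json"))
  writeLines(jsonlite::toJSON(out$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

write_em_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$counts, file.path(dir, "structure_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(out$timepoint_summary,
                   file.path(dir, "timepoint_summary.csv"), row.names = FALSE)
  utils::write.csv(out$pit_distances, file.path(dir, "pit_distances.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(out$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

summary_to_list <- function(s) {
  list(n = s$n, median = s$median, ci95 = s$ci95,
       fraction_periactive = s$fraction_periactive, band = s$band)
}
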