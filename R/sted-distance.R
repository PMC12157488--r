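# Signed punctum-to-boundary distances and the per-ROI distance analysis.

#' Signed distance from a punctum to the active-zone boundary
#'
#' The magnitude is the minimum Euclidean distance from the punctum to the
#' closed contour, evaluated exactly on the segments of the contour after
#' dense resampling (step at most 0.25 px). The sign follows the plotting
#' convention: negative inside the active zone, positive outside, zero on
#' the contour.
#'
#' @param punctum_px Numeric (x, y) punctum location in pixels.
#' @param boundary An [az_boundary].
#' @param pixel_size_nm Pixel size used to convert to nm.
#' @param resample_step_px Maximum spacing of contour samples (default 0.25).
#' @return Signed distance in nm.
#' @export
signed_distance_to_boundary <- function(punctum_px, boundary, pixel_size_nm,
                                        resample_step_px = 0.25) {
  if (!inherits(boundary, "az_boundary")) stop("'boundary' must be an az_boundary")
  if (abs(polygon_area(boundary$contour)) < 1e-9)
    stop("degenerate (zero-area) boundary")
  dense <- resample_closed(boundary$contour, step = resample_step_px)
  d_px <- dist_point_polyline(punctum_px[1], punctum_px[2], dense)
  inside <- point_in_polygon(punctum_px[1], punctum_px[2], dense)
  sign <- if (d_px < 1e-9) 0 else if (inside) -1 else 1
  sign * d_px * pixel_size_nm
}

#' Punctum distance records for one ROI
#'
#' Full per-synapse analysis: extracts half-max active-zone boundaries and
#' punctum local maxima from the ROI and returns one record per punctum with
#' its signed distance (nm) to the nearest boundary (minimum absolute
#' distance when several active-zone maxima yield several boundaries).
#' Side-view, unclassified and excluded ROIs yield no records: distance
#' analysis is meaningful in top view only, because in side view puncta
#' project onto the middle of the synapse.
#'
#' @param roi A classified [roi_patch].
#' @param pixel_size_nm Pixel size in nm.
#' @param az_channel,puncta_channel Channel names.
#' @param min_separation_px,min_prominence Punctum-detection parameters (see
#'   [detect_puncta()]).
#' @return Data frame with columns `synapse_id`, `synapse_class`, `view`,
#'   `x_px`, `y_px`, `signed_distance_nm` (zero rows for skipped ROIs).
#' @export
analyze_synapse <- function(roi, pixel_size_nm, az_channel = "bassoon",
                            puncta_channel = "dyn1xa",
                            min_separation_px = 3, min_prominence = 0.2) {
  empty <- data.frame(synapse_id = character(0), synapse_class = character(0),
                      view = character(0), x_px = numeric(0), y_px = numeric(0),
                      signed_distance_nm = numeric(0))
  if (roi$excluded || !identical(roi$view, "top")) return(empty)
  boundaries <- extract_halfmax_boundary(roi$pixels[[az_channel]])
  if (length(boundaries) == 0L) return(empty)
  puncta <- detect_puncta(roi$pixels[[puncta_channel]],
                          min_separation_px, min_prominence)
  if (nrow(puncta) == 0L) return(empty)
  synapse_id <- sprintf("%s_x%d_y%d", roi$source_id,
                        roi$center_px[1], roi$center_px[2])
  dist_nm <- vapply(seq_len(nrow(puncta)), function(i) {
    ds <- vapply(boundaries, function(b) {
      signed_distance_to_boundary(c(puncta$x[i], puncta$y[i]), b, pixel_size_nm)
    }, numeric(1))
    ds[which.min(abs(ds))]
  }, numeric(1))
  data.frame(synapse_id = synapse_id,
             synapse_class = roi$synapse_class,
             view = roi$view,
             x_px = puncta$x, y_px = puncta$y,
             signed_distance_nm = dist_nm)
}
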