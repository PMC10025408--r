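## Plant detection: a pluggable detector contract plus a classical
## reference detector for synthetic imagery. A detector is a function
## (clip, params) -> data.frame(x_min, y_min, x_max, y_max, confidence)
## with boxes inside the clip and confidences in [0, 1].

.detector_registry <- new.env(parent = emptyenv())

#' Register a plant detector
#'
#' Detectors are injected by name so a learned model can replace the
#' classical reference without code changes. A detector takes a
#' \code{\link{pf_raster}} clip and a parameter list, and returns a
#' data.frame of pixel boxes (\code{x_min, y_min, x_max, y_max}) with a
#' \code{confidence} column in [0, 1].
#'
#' @param name detector name.
#' @param fn detector function \code{function(clip, params)}.
#' @export
register_detector <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .detector_registry)
  invisible(name)
}

#' Look up a registered detector
#' @param name detector name ("reference" is built in).
#' @return the detector function.
#' @export
get_detector <- function(name) {
  if (!exists(name, envir = .detector_registry))
    stop_invalid("unknown detector: ", name)
  get(name, envir = .detector_registry)
}

#' Classical reference plant detector
#'
#' Stand-in for a learned object detector: thresholds a greenness index
#' (2G - R - B) for 3-band input, or raw intensity for single-band input,
#' labels 8-connected foreground components, and returns the tight
#' bounding box of every component with at least \code{min_area_px}
#' pixels. Confidence is the component's mean foreground score scaled to
#' (0, 1].
#'
#' @param clip a \code{\link{pf_raster}}.
#' @param min_area_px minimum component area in pixels.
#' @param intensity_threshold numeric threshold on the foreground index,
#'   or \code{"otsu"} for automatic thresholding.
#' @return data.frame of pixel boxes with columns \code{x_min, y_min,
#'   x_max, y_max, confidence, label}; 0-based pixel coordinates, box
#'   edges on pixel borders (max edges exclusive-of-center + 1).
#' @export
detect_plants_reference <- function(clip, min_area_px = 25,
                                    intensity_threshold = "otsu") {
  stopifnot(inherits(clip, "pf_raster"))
  v <- clip$values
  if (prod(dim(v)) == 0) stop_invalid("empty raster")
  score <- if (dim(v)[3] >= 3) 2 * v[, , 2] - v[, , 1] - v[, , 3] else v[, , 1]
  score[!is.finite(score)] <- min(score[is.finite(score)], 0)
  if (identical(intensity_threshold, "otsu")) {
    rng <- range(score)
    if (rng[2] <= rng[1]) return(empty_boxes())
    norm <- (score - rng[1]) / (rng[2] - rng[1])
    thr_n <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1))
    fg <- norm > thr_n
  } else {
    fg <- score > intensity_threshold
  }
  if (!any(fg)) return(empty_boxes())
  lab <- EBImage::bwlabel(EBImage::Image(t(fg)))  # EBImage is x-major
  labm <- t(EBImage::imageData(lab))
  ids <- setdiff(unique(as.vector(labm)), 0)
  out <- empty_boxes()
  for (id in ids) {
    w <- which(labm == id, arr.ind = TRUE)
    if (nrow(w) < min_area_px) next
    ## rows are y, cols are x; 0-based boxes spanning whole pixels
    out <- rbind(out, data.frame(
      x_min = min(w[, 2]) - 1, y_min = min(w[, 1]) - 1,
      x_max = max(w[, 2]), y_max = max(w[, 1]),
      confidence = min(1, nrow(w) / (nrow(w) + min_area_px) + 0.5),
      label = "plant", stringsAsFactors = FALSE))
  }
  out[order(out$y_min, out$x_min), , drop = FALSE]
}

empty_boxes <- function() {
  data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
             y_max = numeric(), confidence = numeric(), label = character(),
             stringsAsFactors = FALSE)
}

#' Convert pixel-box detections to georeferenced records
#'
#' Each box is mapped through the clip geotransform to a geographic
#' bounding box, its corners are projected to UTM, the plant bounding area
#' is the UTM box area, and the plant center is the midpoint of the box
#' corners in lon/lat.
#'
#' @param boxes data.frame of pixel boxes (as from
#'   \code{\link{detect_plants_reference}}).
#' @param gt the clip \code{\link{geotransform}}.
#' @param date collection date (character or Date).
#' @param sensor "rgb" or "thermal".
#' @param plot_id plot identifier.
#' @param utm_zone optional forced UTM zone.
#' @return data.frame of detection records with geographic box corners,
#'   center lon/lat, bounding area (m^2) and confidence; order and
#'   confidences preserved.
#' @export
detections_to_geo <- function(boxes, gt, date, sensor, plot_id,
                              utm_zone = NULL) {
  stopifnot(inherits(gt, "geotransform"))
  n <- nrow(boxes)
  if (n == 0) {
    return(data.frame(date = character(), sensor = character(),
                      plot_id = character(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      nw_lon = numeric(), nw_lat = numeric(),
                      se_lon = numeric(), se_lat = numeric(),
                      center_lon = numeric(), center_lat = numeric(),
                      bounding_area = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_len(n), function(i) {
    pb <- pixel_box(boxes$x_min[i], boxes$y_min[i], boxes$x_max[i], boxes$y_max[i])
    gb <- bbox_pixel_to_geo(gt, pb, utm_zone = utm_zone)
    data.frame(date = as.character(date), sensor = sensor,
               plot_id = as.character(plot_id),
               x_min = pb$x_min, y_min = pb$y_min,
               x_max = pb$x_max, y_max = pb$y_max,
               nw_lon = gb$nw_lon, nw_lat = gb$nw_lat,
               se_lon = gb$se_lon, se_lat = gb$se_lat,
               center_lon = (gb$nw_lon + gb$se_lon) / 2,
               center_lat = (gb$nw_lat + gb$se_lat) / 2,
               bounding_area = bounding_area(gb),
               confidence = boxes$confidence[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write detection records as CSV and GeoJSON point features
#'
#' @param records detection records from \code{\link{detections_to_geo}}.
#' @param csv_path,geojson_path output paths (either may be NULL to skip).
#' @export
write_detections <- function(records, csv_path = NULL, geojson_path = NULL) {
  if (!is.null(csv_path)) write.csv(records, csv_path, row.names = FALSE)
  if (!is.null(geojson_path)) {
    pts <- data.frame(lon = records$center_lon, lat = records$center_lat,
                      date = records$date, sensor = records$sensor,
                      plot_id = records$plot_id,
                      bounding_area = records$bounding_area,
                      confidence = records$confidence)
    write_points_geojson(pts, geojson_path)
  }
  invisible(records)
}
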