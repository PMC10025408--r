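#' Plot-boundary map
#'
#' Field plots as simple lon/lat polygons with design attributes
#' (plot id, genotype, treatment, grid row/column).
#'
#' @param plots data.frame with columns \code{plot_id}, \code{genotype},
#'   \code{treatment}, \code{row}, \code{column}.
#' @param polygons list of n x 2 matrices (lon, lat), one per plot,
#'   unclosed rings.
#' @return an object of class \code{plot_map}.
#' @export
plot_map <- function(plots, polygons) {
  stopifnot(is.data.frame(plots), length(polygons) == nrow(plots))
  req <- c("plot_id", "genotype", "treatment")
  if (!all(req %in% names(plots))) stop_invalid("plots must have plot_id, genotype, treatment")
  if (anyDuplicated(plots$plot_id)) stop_invalid("plot_ids must be unique")
  structure(list(plots = plots, polygons = polygons), class = "plot_map")
}

#' @export
print.plot_map <- function(x, ...) {
  cat(sprintf("<plot_map> %d plots, %d genotypes, treatments: %s\n",
              nrow(x$plots), length(unique(x$plots$genotype)),
              paste(unique(x$plots$treatment), collapse = ", ")))
  invisible(x)
}

#' Write a plot map as a GeoJSON FeatureCollection
#'
#' @param pm a \code{\link{plot_map}}.
#' @param path output path.
#' @export
write_plot_geojson <- function(pm, path) {
  stopifnot(inherits(pm, "plot_map"))
  feats <- lapply(seq_len(nrow(pm$plots)), function(i) {
    ring <- pm$polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    props <- as.list(pm$plots[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of plot polygons
#'
#' Expects Polygon features with properties \code{plot_id},
#' \code{genotype}, \code{treatment} (and optionally \code{row},
#' \code{column}).
#'
#' @param path GeoJSON file path.
#' @return a \code{\link{plot_map}}.
#' @export
read_plot_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop_invalid("not a FeatureCollection")
  rows <- list(); polys <- list()
  for (ft in gj$features) {
    p <- ft$properties
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = as.character(p$plot_id),
      genotype = as.character(p$genotype %||% NA),
      treatment = as.character(p$treatment %||% NA),
      row = as.integer(p$row %||% NA),
      column = as.integer(p$column %||% NA),
      stringsAsFactors = FALSE)
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polys[[length(polys) + 1L]] <- m
  }
  plot_map(do.call(rbind, rows), polys)
}

#' Write point features as GeoJSON
#'
#' Generic helper for point layers (plant centers, marked outlier points).
#'
#' @param df data.frame with \code{lon}, \code{lat} and any property
#'   columns.
#' @param path output path.
#' @export
write_points_geojson <- function(df, path) {
  props <- setdiff(names(df), c("lon", "lat"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         properties = as.list(df[i, props, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON point features
#'
#' @param path GeoJSON file path.
#' @return data.frame with \code{lon}, \code{lat} and property columns.
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(gj$features)) return(data.frame(lon = numeric(), lat = numeric()))
  rows <- lapply(gj$features, function(ft) {
    xy <- ft$geometry$coordinates
    c(list(lon = xy[[1]], lat = xy[[2]]), ft$properties)
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- lapply(nm, function(k) sapply(rows, function(r) r[[k]] %||% NA))
  as.data.frame(setNames(out, nm), stringsAsFactors = FALSE)
}
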