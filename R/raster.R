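#' In-memory georeferenced raster
#'
#' A lightweight raster container: a numeric matrix (single band) or a
#' rows x cols x bands array, an affine \code{\link{geotransform}}, and a
#' nodata sentinel (NaN for floating-point data, 0 for integer-valued
#' data).
#'
#' @param values matrix or 3-d array of pixel values (rows x cols x bands).
#' @param gt a \code{\link{geotransform}}.
#' @param nodata nodata sentinel value.
#' @return an object of class \code{pf_raster}.
#' @export
pf_raster <- function(values, gt, nodata = NaN) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop_invalid("values must be a matrix or 3-d array")
  stopifnot(inherits(gt, "geotransform"))
  structure(list(values = values, gt = gt, nodata = nodata), class = "pf_raster")
}

#' @export
print.pf_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pf_raster> %d x %d pixels, %d band(s), ul=(%.6f, %.6f)\n",
              d[1], d[2], d[3], x$gt$c, x$gt$f))
  invisible(x)
}

raster_nbands <- function(r) dim(r$values)[3]
raster_dim <- function(r) dim(r$values)[1:2]

#' Write a raster as TIFF plus world file
#'
#' The pixel payload goes to a 32-bit TIFF; because TIFF stores samples in
#' [0, 1], the value range is recorded in a JSON sidecar
#' (\code{<path>.json}) together with the nodata sentinel, and the six
#' affine coefficients go to an ESRI world file (\code{.tfw}) so that the
#' geotransform round-trips exactly.
#'
#' @param r a \code{\link{pf_raster}}.
#' @param path output path ending in \code{.tif}.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "pf_raster"))
  v <- r$values
  finite <- is.finite(v)
  lo <- if (any(finite)) min(v[finite]) else 0
  hi <- if (any(finite)) max(v[finite]) else 1
  span <- if (hi > lo) hi - lo else 1
  norm <- (v - lo) / span
  norm[!finite] <- 0
  img <- if (dim(v)[3] == 1L) norm[, , 1] else norm
  tiff::writeTIFF(img, path, bits.per.sample = 32, compression = "none")
  ## world file: center-of-upper-left-pixel convention
  gt <- r$gt
  tfw <- c(gt$a, gt$d, gt$b, gt$e, gt$c + gt$a * 0.5 + gt$b * 0.5,
           gt$f + gt$d * 0.5 + gt$e * 0.5)
  writeLines(sprintf("%.17g", tfw), sub("\\.tiff?$", ".tfw", path))
  meta <- list(value_min = lo, value_max = hi, nodata = r$nodata,
               nodata_mask = if (any(!finite)) which(!finite) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster written by \code{\link{write_raster}}
#'
#' @param path path to the \code{.tif} file; the \code{.tfw} world file and
#'   \code{.json} sidecar written alongside are required.
#' @return a \code{\link{pf_raster}}.
#' @export
read_raster <- function(path) {
  img <- tiff::readTIFF(path)
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  tfw <- as.numeric(readLines(sub("\\.tiff?$", ".tfw", path)))
  if (length(tfw) != 6) stop_invalid("world file must have 6 lines")
  gt <- geotransform(a = tfw[1], d = tfw[2], b = tfw[3], e = tfw[4],
                     c = tfw[5] - tfw[1] * 0.5 - tfw[3] * 0.5,
                     f = tfw[6] - tfw[2] * 0.5 - tfw[4] * 0.5)
  meta_path <- paste0(path, ".json")
  nodata <- NaN; lo <- 0; hi <- 1; mask <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    lo <- meta$value_min; hi <- meta$value_max
    nodata <- if (is.null(meta$nodata) || is.character(meta$nodata)) NaN else meta$nodata
    mask <- meta$nodata_mask
    span <- if (hi > lo) hi - lo else 1
    img <- img * span + lo
  }
  if (!is.null(mask) && length(mask)) img[mask] <- if (is.nan(nodata)) NaN else nodata
  pf_raster(img, gt, nodata = nodata)
}

## invert the affine: (lon,lat) -> fractional pixel (x, y), center convention
geo_to_pixel <- function(gt, lon, lat) {
  det <- gt$a * gt$e - gt$b * gt$d
  u <- lon - gt$c - gt$a * 0.5 - gt$b * 0.5
  v <- lat - gt$f - gt$d * 0.5 - gt$e * 0.5
  data.frame(x = (gt$e * u - gt$b * v) / det,
             y = (-gt$d * u + gt$a * v) / det)
}

#' Clip a raster to plot boundaries
#'
#' Produces one clipped raster per plot polygon intersecting the raster
#' footprint. Each clip covers the pixel-aligned bounding box of its
#' polygon; pixels whose centers fall outside the polygon are masked with
#' the nodata sentinel. The clip's geotransform upper-left corner maps to
#' the polygon bounding-box upper-left.
#'
#' @param r a \code{\link{pf_raster}}.
#' @param plots a \code{\link{plot_map}}.
#' @return named list of \code{pf_raster} clips keyed by plot_id; plots
#'   fully outside the raster are omitted.
#' @export
clip_raster_to_plots <- function(r, plots) {
  stopifnot(inherits(r, "pf_raster"), inherits(plots, "plot_map"))
  d <- raster_dim(r)
  out <- list()
  for (i in seq_len(nrow(plots$plots))) {
    poly <- plots$polygons[[i]]
    if (anyNA(poly) || nrow(poly) < 3) stop_invalid("invalid plot polygon")
    px <- geo_to_pixel(r$gt, poly[, 1], poly[, 2])
    x0 <- floor(min(px$x)); x1 <- ceiling(max(px$x))
    y0 <- floor(min(px$y)); y1 <- ceiling(max(px$y))
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, d[2] - 1); y1 <- min(y1, d[1] - 1)
    if (x1 < x0 || y1 < y0) next
    rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
    sub <- r$values[rows, cols, , drop = FALSE]
    ## mask pixel centers outside the polygon
    cc <- expand.grid(x = x0:x1, y = y0:y1)
    geo <- pixel_to_geo(r$gt, cc$x, cc$y)
    inside <- mgcv::in.out(rbind(as.matrix(poly), poly[1, , drop = FALSE]),
                           cbind(geo$lon, geo$lat))
    if (!any(inside)) next
    mask <- matrix(inside, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    for (b in seq_len(dim(sub)[3])) {
      band <- sub[, , b]
      band[!mask] <- r$nodata
      sub[, , b] <- band
    }
    gt <- r$gt
    cgt <- geotransform(a = gt$a, b = gt$b, d = gt$d, e = gt$e,
                        c = gt$c + gt$a * x0 + gt$b * y0,
                        f = gt$f + gt$d * x0 + gt$e * y0)
    out[[as.character(plots$plots$plot_id[i])]] <- pf_raster(sub, cgt, nodata = r$nodata)
  }
  out
}
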