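#' Affine raster geotransform
#'
#' A 6-coefficient affine mapping from 0-based pixel coordinates
#' (x = column, y = row) to geographic coordinates. Coefficients follow
#' the standard geotransform convention: \code{a} E-W pixel spacing,
#' \code{b}/\code{d} row/column rotation terms, \code{e} N-S pixel spacing
#' (negative for north-up), \code{c}/\code{f} the upper-left corner
#' longitude/latitude. Sampling is at pixel centers (+0.5 pixel).
#'
#' @param a,b,c,d,e,f affine coefficients (degrees, degrees/pixel).
#' @return an object of class \code{geotransform}.
#' @examples
#' gt <- geotransform(a = 1e-5, b = 0, c = -112, d = 0, e = -1e-5, f = 33)
#' pixel_to_geo(gt, 10, 0)
#' @export
geotransform <- function(a, b = 0, c, d = 0, e, f) {
  for (v in list(a, b, c, d, e, f))
    if (!is_finite_num(v) || length(v) != 1L) stop_invalid("geotransform coefficients must be finite scalars")
  if (abs(a) <= 0 || abs(e) <= 0) stop_invalid("pixel spacings a and e must be nonzero")
  if (abs(a * e - b * d) == 0) stop_invalid("geotransform is singular (a*e - b*d == 0)")
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f), class = "geotransform")
}

#' @export
print.geotransform <- function(x, ...) {
  cat(sprintf("<geotransform> a=%g b=%g c=%g d=%g e=%g f=%g\n",
              x$a, x$b, x$c, x$d, x$e, x$f))
  invisible(x)
}

#' Pixel to geographic coordinates
#'
#' Maps pixel (column, row) coordinates to (longitude, latitude) through
#' the affine geotransform with the pixel-center convention:
#' \code{lon = a*x + b*y + a*0.5 + b*0.5 + c},
#' \code{lat = d*x + e*y + d*0.5 + e*0.5 + f}.
#'
#' @param gt a \code{\link{geotransform}}.
#' @param x,y numeric pixel column(s) and row(s), 0-based; vectorized.
#' @return a data.frame with columns \code{lon}, \code{lat}.
#' @export
pixel_to_geo <- function(gt, x, y) {
  stopifnot(inherits(gt, "geotransform"))
  if (!is_finite_num(x) || !is_finite_num(y)) stop_invalid("pixel coordinates must be finite")
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  data.frame(lon = gt$a * x + gt$b * y + gt$a * 0.5 + gt$b * 0.5 + gt$c,
             lat = gt$d * x + gt$e * y + gt$d * 0.5 + gt$e * 0.5 + gt$f)
}

#' Pixel-space bounding box
#'
#' @param x_min,y_min,x_max,y_max pixel coordinates (columns x, rows y);
#'   requires \code{x_min < x_max}, \code{y_min < y_max} and non-negative
#'   coordinates.
#' @return an object of class \code{pixel_box}.
#' @export
pixel_box <- function(x_min, y_min, x_max, y_max) {
  v <- c(x_min, y_min, x_max, y_max)
  if (!is_finite_num(v)) stop_invalid("pixel box coordinates must be finite")
  if (any(v < 0)) stop_invalid("pixel box coordinates must be >= 0")
  if (!(x_min < x_max && y_min < y_max)) stop_invalid("degenerate pixel box")
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "pixel_box")
}

#' Geographic bounding box with UTM corners
#'
#' Stores the NW/SE corners of a box in lon/lat degrees together with
#' their UTM easting/northing (meters) and the UTM zone.
#'
#' @param nw_lon,nw_lat,se_lon,se_lat corner coordinates in degrees.
#' @param nw_e,nw_n,se_e,se_n corner UTM coordinates in meters.
#' @param utm_zone UTM zone id.
#' @return an object of class \code{geo_bounding_box}.
#' @export
geo_bounding_box <- function(nw_lon, nw_lat, se_lon, se_lat,
                             nw_e = NA_real_, nw_n = NA_real_,
                             se_e = NA_real_, se_n = NA_real_,
                             utm_zone = NA_integer_) {
  structure(list(nw_lon = nw_lon, nw_lat = nw_lat, se_lon = se_lon, se_lat = se_lat,
                 nw_e = nw_e, nw_n = nw_n, se_e = se_e, se_n = se_n,
                 utm_zone = utm_zone),
            class = "geo_bounding_box")
}

#' Pixel box to georeferenced bounding box
#'
#' The NW corner comes from (x_min, y_min) and the SE corner from
#' (x_max, y_max) through \code{\link{pixel_to_geo}}; both corners are
#' projected to UTM with \code{\link{geo_to_utm}}.
#'
#' @param gt a \code{\link{geotransform}}.
#' @param box a \code{\link{pixel_box}}.
#' @param utm_zone optional forced UTM zone.
#' @return a \code{\link{geo_bounding_box}}.
#' @export
bbox_pixel_to_geo <- function(gt, box, utm_zone = NULL) {
  stopifnot(inherits(box, "pixel_box"))
  nw <- pixel_to_geo(gt, box$x_min, box$y_min)
  se <- pixel_to_geo(gt, box$x_max, box$y_max)
  zone <- utm_zone %||% utm_zone_from_lon((nw$lon + se$lon) / 2)
  nwu <- geo_to_utm(nw$lon, nw$lat, zone = zone)
  seu <- geo_to_utm(se$lon, se$lat, zone = zone)
  geo_bounding_box(nw$lon, nw$lat, se$lon, se$lat,
                   nw_e = nwu$easting, nw_n = nwu$northing,
                   se_e = seu$easting, se_n = seu$northing,
                   utm_zone = zone)
}

#' Plant bounding area in the UTM plane
#'
#' Area of a georeferenced bounding box computed from its UTM corners as
#' \code{|(SEe - NWe) * (SEn - NWn)|} in square meters. Under north-up
#' conventions the northing difference is negative, so the absolute value
#' is taken: an area must be non-negative.
#'
#' @param box a \code{\link{geo_bounding_box}} with UTM fields populated.
#' @return area in m^2.
#' @examples
#' b <- geo_bounding_box(0, 0, 0, 0, nw_e = 400000, nw_n = 3660010,
#'                       se_e = 400002, se_n = 3660008, utm_zone = 12L)
#' bounding_area(b)  # 4
#' @export
bounding_area <- function(box) {
  stopifnot(inherits(box, "geo_bounding_box"))
  if (anyNA(c(box$nw_e, box$nw_n, box$se_e, box$se_n)))
    stop_invalid("UTM corner fields are not populated")
  if (length(box$utm_zone) == 2L && box$utm_zone[1] != box$utm_zone[2])
    stop_invalid("corners lie in different UTM zones")
  abs((box$se_e - box$nw_e) * (box$se_n - box$nw_n))
}
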