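## WGS84 <-> UTM via the transverse-Mercator Krueger series (4th order in
## the third flattening n). Truncation error is far below a millimeter over
## UTM zone widths, which is ample for plant bounding areas measured in m^2.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

.tm_consts <- local({
  f <- .wgs84$f
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4
  list(
    n = n,
    e = sqrt(f * (2 - f)),
    A = .wgs84$a / (1 + n) * (1 + n2 / 4 + n4 / 64),
    alpha = c(n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180,
              13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440,
              61 * n3 / 240 - 103 * n4 / 140,
              49561 * n4 / 161280),
    beta = c(n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360,
             n2 / 48 + n3 / 15 - 437 * n4 / 1440,
             17 * n3 / 480 - 37 * n4 / 840,
             4397 * n4 / 161280))
})

#' UTM zone for a longitude
#'
#' @param lon longitude in degrees.
#' @return integer zone in 1..60.
#' @export
utm_zone_from_lon <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Geographic to UTM coordinates (WGS84)
#'
#' Forward transverse-Mercator projection with the standard UTM scale
#' factor 0.9996 and 500 km false easting; southern-hemisphere points get
#' the 10,000 km false northing. The zone is inferred from the longitude
#' unless forced.
#'
#' @param lon,lat degrees; vectorized. Latitude must lie in [-80, 84]
#'   (the UTM validity band).
#' @param zone optional forced UTM zone (for fields straddling a zone edge).
#' @return data.frame with columns \code{easting}, \code{northing} (m) and
#'   \code{zone}.
#' @export
geo_to_utm <- function(lon, lat, zone = NULL) {
  if (!is_finite_num(lon) || !is_finite_num(lat)) stop_invalid("non-finite coordinates")
  if (any(lon < -180 | lon > 180)) stop_invalid("longitude out of [-180, 180]")
  if (any(lat < -80 | lat > 84)) stop_invalid("latitude out of the UTM band [-80, 84]")
  zone <- zone %||% utm_zone_from_lon(lon)
  lon0 <- zone * 6 - 183
  k <- .tm_consts
  phi <- lat * pi / 180
  lam <- (lon - lon0) * pi / 180
  ## conformal latitude
  t_ <- sinh(atanh(sin(phi)) - k$e * atanh(k$e * sin(phi)))
  xi_p <- atan2(t_, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t_^2 + cos(lam)^2))
  xi <- xi_p; eta <- eta_p
  for (j in 1:4) {
    xi <- xi + k$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + k$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  easting <- 500000 + 0.9996 * k$A * eta
  northing <- 0.9996 * k$A * xi + ifelse(lat < 0, 10000000, 0)
  data.frame(easting = easting, northing = northing, zone = zone)
}

#' UTM to geographic coordinates (WGS84)
#'
#' Inverse of \code{\link{geo_to_utm}}.
#'
#' @param easting,northing UTM coordinates in meters; vectorized.
#' @param zone UTM zone.
#' @param south logical, TRUE for southern-hemisphere coordinates.
#' @return data.frame with columns \code{lon}, \code{lat} in degrees.
#' @export
utm_to_geo <- function(easting, northing, zone, south = FALSE) {
  if (!is_finite_num(easting) || !is_finite_num(northing)) stop_invalid("non-finite coordinates")
  k <- .tm_consts
  lon0 <- zone * 6 - 183
  xi <- (northing - ifelse(south, 10000000, 0)) / (0.9996 * k$A)
  eta <- (easting - 500000) / (0.9996 * k$A)
  xi_p <- xi; eta_p <- eta
  for (j in 1:4) {
    xi_p <- xi_p - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  ## invert the conformal latitude by Newton iteration (exact inverse of
  ## the forward conformal mapping, to machine precision)
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  e <- k$e
  e2m <- 1 - e^2
  tau <- tau_p / e2m
  for (it in 1:6) {
    sig <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    tau_pa <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2)
    tau <- tau + (tau_p - tau_pa) * (1 + e2m * tau^2) /
      (e2m * sqrt((1 + tau^2) * (1 + tau_pa^2)))
  }
  phi <- atan(tau)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  data.frame(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
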