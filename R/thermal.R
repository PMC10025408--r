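#' Thermal calibration coefficients
#'
#' Linear digital-number (DN) to Celsius calibration,
#' \code{celsius = gain * DN + offset}. The coefficients are instrument
#' calibration measurements supplied through configuration.
#'
#' @param gain degrees C per DN; must be nonzero.
#' @param offset degrees C.
#' @return an object of class \code{thermal_calibration}.
#' @export
thermal_calibration <- function(gain, offset) {
  if (!is_finite_num(c(gain, offset)) || gain == 0)
    stop_invalid("gain must be finite and nonzero")
  structure(list(gain = gain, offset = offset), class = "thermal_calibration")
}

#' Calibrate a DN image to Celsius
#'
#' Elementwise linear calibration; non-finite (nodata) pixels propagate.
#'
#' @param dn_image numeric matrix/array of digital numbers.
#' @param cal a \code{\link{thermal_calibration}}.
#' @return image of temperatures in Celsius, same shape.
#' @export
calibrate_dn <- function(dn_image, cal) {
  stopifnot(inherits(cal, "thermal_calibration"))
  cal$gain * dn_image + cal$offset
}

#' Invert a thermal calibration
#' @param celsius_image temperatures in Celsius.
#' @param cal a \code{\link{thermal_calibration}}.
#' @return digital numbers.
#' @export
uncalibrate_celsius <- function(celsius_image, cal) {
  stopifnot(inherits(cal, "thermal_calibration"))
  (celsius_image - cal$offset) / cal$gain
}

## kmeans++-style seeding: spread initial centers, deterministic under seed
kmeanspp_centers <- function(x, k) {
  n <- length(x)
  centers <- numeric(k)
  centers[1] <- x[sample.int(n, 1)]
  for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
    if (all(d2 == 0)) centers[j] <- x[sample.int(n, 1)]
    else centers[j] <- x[sample.int(n, 1, prob = d2)]
  }
  centers
}

#' Per-plant canopy temperature by K-means
#'
#' Clusters the pixel temperatures of a plant's bounding-box clip with
#' K-means (K = 3, kmeans++ seeding, 10 restarts). Transpiring canopies
#' are cooler than daytime soil, so by default the coldest-mean cluster
#' is canopy; with K = 3 the middle (mixed boundary) cluster is excluded
#' from canopy statistics. Reports the median and mean canopy
#' temperatures (MEDT, MEAT), canopy quantiles, and the median of a
#' centered ROI window.
#'
#' @param plant_clip numeric matrix of temperatures in Celsius (the
#'   plant's predicted bounding box cropped from the plot raster); NA/NaN
#'   treated as nodata.
#' @param roi_size side of the centered region-of-interest window in
#'   pixels (clipped at the edges of small clips).
#' @param canopy_rule which cluster is canopy: "coldest" (default),
#'   "warmest" or "largest".
#' @param seed RNG seed for the clustering restarts.
#' @return an object of class \code{canopy_temperature}: list with
#'   \code{medt}, \code{meat}, \code{roi_temp}, \code{n_canopy_pixels},
#'   \code{q05,q25,q75,q95}, \code{cluster_means} and a \code{degenerate}
#'   flag (TRUE when all pixels are identical and whole-clip statistics
#'   are returned).
#' @export
extract_canopy_temperature <- function(plant_clip, roi_size = 10,
                                       canopy_rule = c("coldest", "warmest", "largest"),
                                       seed = 1L) {
  canopy_rule <- match.arg(canopy_rule)
  m <- as.matrix(plant_clip)
  vals <- as.vector(m)
  ok <- is.finite(vals)
  if (sum(ok) < 3) stop_invalid("insufficient-data: fewer than 3 valid pixels")
  x <- vals[ok]
  roi <- roi_median(m, roi_size)
  if (diff(range(x)) == 0) {
    q <- rep(x[1], 4)
    return(structure(list(medt = x[1], meat = x[1], roi_temp = roi,
                          n_canopy_pixels = length(x),
                          q05 = q[1], q25 = q[2], q75 = q[3], q95 = q[4],
                          cluster_means = rep(x[1], 3), degenerate = TRUE),
                     class = "canopy_temperature"))
  }
  km <- withr_seed(seed, {
    best <- NULL
    for (r in 1:10) {
      ctr <- kmeanspp_centers(x, 3)
      if (length(unique(ctr)) < 3)
        ctr <- ctr + seq(0, 1e-9, length.out = 3)
      fit <- suppressWarnings(stats::kmeans(x, centers = matrix(ctr), iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  mu <- as.vector(km$centers)
  canopy_k <- switch(canopy_rule,
                     coldest = which.min(mu),
                     warmest = which.max(mu),
                     largest = which.max(km$size))
  cx <- x[km$cluster == canopy_k]
  q <- quantile(cx, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  structure(list(medt = median(cx), meat = mean(cx), roi_temp = roi,
                 n_canopy_pixels = length(cx),
                 q05 = q[1], q25 = q[2], q75 = q[3], q95 = q[4],
                 cluster_means = sort(mu), degenerate = FALSE),
            class = "canopy_temperature")
}

## median of a roi_size x roi_size window centered in the clip, edges clipped
roi_median <- function(m, roi_size) {
  nr <- nrow(m); nc <- ncol(m)
  half <- roi_size / 2
  r0 <- max(1, floor(nr / 2 - half) + 1); r1 <- min(nr, floor(nr / 2 + half))
  c0 <- max(1, floor(nc / 2 - half) + 1); c1 <- min(nc, floor(nc / 2 + half))
  w <- m[r0:r1, c0:c1]
  median(w[is.finite(w)])
}

## evaluate expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
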