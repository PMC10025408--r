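test_that("pixel_to_geo evaluates the pixel-center affine", {
  gt <- geotransform(a = 1e-5, b = 0, c = -112.0, d = 0, e = -1e-5, f = 33.0)
  g <- pixel_to_geo(gt, 10, 0)
  expect_equal(g$lon, -111.999895)
  expect_equal(g$lat, 32.999995)
  ## the half-pixel center offset cancels at (-0.5, -0.5)
  g0 <- pixel_to_geo(gt, -0.5, -0.5)
  expect_identical(c(g0$lon, g0$lat), c(gt$c, gt$f))
})

test_that("pixel_to_geo matches a 2x3 affine-matrix oracle with rotation", {
  set.seed(1)
  gt <- geotransform(a = 1.3e-5, b = 2e-7, c = -112, d = -1e-7, e = -0.9e-5,
                     f = 33)
  x <- runif(100, 0, 500); y <- runif(100, 0, 500)
  A <- matrix(c(gt$a, gt$b, gt$c, gt$d, gt$e, gt$f), 2, byrow = TRUE)
  oracle <- t(A %*% rbind(x + 0.5, y + 0.5, 1))
  got <- pixel_to_geo(gt, x, y)
  expect_equal(got$lon, oracle[, 1], tolerance = 1e-12)
  expect_equal(got$lat, oracle[, 2], tolerance = 1e-12)
  ## affinity: midpoints map to midpoints
  m <- pixel_to_geo(gt, (x[1] + x[2]) / 2, (y[1] + y[2]) / 2)
  expect_equal(m$lon, (got$lon[1] + got$lon[2]) / 2)
  expect_equal(m$lat, (got$lat[1] + got$lat[2]) / 2)
})

test_that("geotransform rejects degenerate coefficient sets", {
  expect_error(geotransform(a = 0, c = 0, e = -1, f = 0), "nonzero")
  expect_error(geotransform(a = 1, b = 1, c = 0, d = 1, e = 1, f = 0),
               "singular")
  gt <- gt_northup()
  expect_error(pixel_to_geo(gt, NaN, 1), class = "phenofield_invalid_argument")
})

test_that("geo_to_utm infers the zone and stays in range", {
  u <- geo_to_utm(-111.975, 33.073)
  expect_identical(u$zone, utm_zone_from_lon(-111.975))
  expect_identical(u$zone, 12L)  # floor(lon/6)+31
  expect_gt(u$easting, 0); expect_lt(u$easting, 1e6)
  expect_gt(u$northing, 0)
  expect_error(geo_to_utm(0, 89), "latitude")
})

test_that("UTM projection round-trips and matches a meridian-arc oracle", {
  set.seed(2)
  lon <- runif(25, -114, -108.1); lat <- runif(25, 10, 70)
  u <- geo_to_utm(lon, lat)
  g <- utm_to_geo(u$easting, u$northing, u$zone)
  u2 <- geo_to_utm(g$lon, g$lat, zone = u$zone)
  expect_lt(max(abs(u2$easting - u$easting)), 1e-6)
  expect_lt(max(abs(u2$northing - u$northing)), 1e-6)
  ## two points 1e-5 deg apart in latitude are ~1.11 m apart
  a <- geo_to_utm(-111.975, 33.073); b <- geo_to_utm(-111.975, 33.073 + 1e-5)
  expect_equal(b$northing - a$northing, 1.11, tolerance = 0.01)
  ## northing increment along the central meridian equals the scaled
  ## meridian arc (numerical integration oracle)
  aa <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  M <- function(phi) aa * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5
  arc <- integrate(M, 33 * pi / 180, 33.1 * pi / 180, rel.tol = 1e-12)$value
  p1 <- geo_to_utm(-111, 33, zone = 12); p2 <- geo_to_utm(-111, 33.1, zone = 12)
  expect_equal(p2$northing - p1$northing, 0.9996 * arc, tolerance = 1e-3)
})

test_that("bbox_pixel_to_geo takes NW from (x_min, y_min) and SE from (x_max, y_max)", {
  gt <- gt_northup()
  gb <- bbox_pixel_to_geo(gt, pixel_box(0, 0, 10, 10))
  expect_gt(gb$nw_lat, gb$se_lat)
  expect_gt(gb$se_lon, gb$nw_lon)
  expect_gt(gb$se_e, gb$nw_e)   # east increases eastward
  expect_gt(gb$nw_n, gb$se_n)   # north-up
  ## corner-wise oracle
  nw <- pixel_to_geo(gt, 0, 0); se <- pixel_to_geo(gt, 10, 10)
  expect_identical(c(gb$nw_lon, gb$nw_lat), c(nw$lon, nw$lat))
  expect_identical(c(gb$se_lon, gb$se_lat), c(se$lon, se$lat))
  expect_error(pixel_box(5, 0, 5, 10), "degenerate")
  expect_error(pixel_box(-1, 0, 5, 10), ">= 0")
})

test_that("bounding_area is the absolute UTM extent product", {
  b <- geo_bounding_box(0, 0, 0, 0, nw_e = 400000, nw_n = 3660010,
                        se_e = 400002, se_n = 3660008, utm_zone = 12L)
  expect_equal(bounding_area(b), 4.0)
  b0 <- geo_bounding_box(0, 0, 0, 0, nw_e = 1, nw_n = 1, se_e = 1, se_n = 1)
  expect_equal(bounding_area(b0), 0.0)
  ## random boxes match width x height, and are label-swap invariant
  set.seed(3)
  for (i in 1:200) {
    e <- sort(runif(2, 4e5, 5e5)); n <- sort(runif(2, 3.6e6, 3.7e6))
    b1 <- geo_bounding_box(0, 0, 0, 0, nw_e = e[1], nw_n = n[2],
                           se_e = e[2], se_n = n[1])
    b2 <- geo_bounding_box(0, 0, 0, 0, nw_e = e[2], nw_n = n[1],
                           se_e = e[1], se_n = n[2])
    expect_equal(bounding_area(b1), diff(e) * diff(n), tolerance = 1e-9)
    expect_identical(bounding_area(b1), bounding_area(b2))
  }
})

test_that("clip_raster_to_plots clips, masks and georeferences each plot", {
  ## 100 x 100 raster holding 4 disjoint rectangular plots
  gt <- gt_northup(step = 1e-5)
  vals <- matrix(runif(100 * 100), 100, 100)
  r <- pf_raster(vals, gt)
  mk_poly <- function(x0, y0, x1, y1) {
    ## pixel rect -> lon/lat ring
    c1 <- pixel_to_geo(gt, x0, y0); c2 <- pixel_to_geo(gt, x1, y1)
    cbind(lon = c(c1$lon, c2$lon, c2$lon, c1$lon),
          lat = c(c1$lat, c1$lat, c2$lat, c2$lat))
  }
  pm <- plot_map(data.frame(plot_id = c("a", "b", "c", "d", "far"),
                            genotype = "g", treatment = "WW"),
                 list(mk_poly(5, 5, 25, 45), mk_poly(30, 5, 50, 45),
                      mk_poly(5, 50, 25, 90), mk_poly(30, 50, 50, 90),
                      mk_poly(500, 500, 600, 600)))
  clips <- clip_raster_to_plots(r, pm)
  expect_named(clips, c("a", "b", "c", "d"))  # plot outside raster excluded
  ## each clip's geotransform reproduces its polygon NW corner within 1 px
  for (k in names(clips)) {
    poly <- pm$polygons[[match(k, pm$plots$plot_id)]]
    expect_lt(abs(clips[[k]]$gt$c - min(poly[, 1])), 1.5e-5)
    expect_lt(abs(clips[[k]]$gt$f - max(poly[, 2])), 1.5e-5)
  }
  ## mask-count oracle: disjoint plots cannot cover more than the raster
  n_unmasked <- sum(vapply(clips, function(cl) sum(is.finite(cl$values)),
                           numeric(1)))
  expect_lte(n_unmasked, 100 * 100)
  expect_gt(n_unmasked, 0)
  ## re-clipping a clip with the same polygon is idempotent
  pm_a <- plot_map(pm$plots[1, ], pm$polygons[1])
  again <- clip_raster_to_plots(clips$a, pm_a)$a
  expect_identical(dim(again$values), dim(clips$a$values))
  both <- is.finite(again$values) & is.finite(clips$a$values)
  expect_identical(again$values[both], clips$a$values[both])
  expect_identical(is.finite(again$values), is.finite(clips$a$values))
})

test_that("raster TIFF + world file round-trips the geotransform exactly", {
  gt <- geotransform(a = 1.25e-5, b = 3e-8, c = -112.01, d = -2e-8,
                     e = -1.1e-5, f = 33.002)
  r <- pf_raster(matrix(seq(10, 40, length.out = 12), 3, 4), gt)
  path <- file.path(tempdir(), "rt.tif")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_equal(unclass(r2$gt), unclass(gt), tolerance = 1e-15)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
})
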