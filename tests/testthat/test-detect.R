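## Reference detector and georeferencing of detections.

disk_image <- function(nrow = 80, ncol = 80, centers, r = 8, bg = 0.1,
                       fg = 0.9) {
  m <- matrix(bg, nrow, ncol)
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ]
    xs <- pmax(1, cc[1] - r):pmin(ncol, cc[1] + r)
    ys <- pmax(1, cc[2] - r):pmin(nrow, cc[2] + r)
    d <- outer((ys - cc[2])^2, (xs - cc[1])^2, "+") <= r^2
    m[ys, xs][d] <- fg
  }
  m
}

test_that("reference detector finds each bright disk in its own box", {
  centers <- rbind(c(20, 20), c(60, 55))
  img <- disk_image(centers = centers, r = 8)
  r <- pf_raster(img, gt_northup())
  boxes <- detect_plants_reference(r, min_area_px = 10,
                                   intensity_threshold = 0.5)
  expect_identical(nrow(boxes), 2L)
  ## each truth disk center falls inside exactly one box (0-based coords)
  for (i in 1:2) {
    inside <- boxes$x_min <= centers[i, 1] - 1 & boxes$x_max >= centers[i, 1] &
      boxes$y_min <= centers[i, 2] - 1 & boxes$y_max >= centers[i, 2]
    expect_identical(sum(inside), 1L)
  }
  ## boxes are tight around the disk equations
  expect_true(all(boxes$x_max - boxes$x_min >= 15))
  expect_true(all(boxes$x_max - boxes$x_min <= 17))
  expect_true(all(boxes$confidence >= 0 & boxes$confidence <= 1))
})

test_that("detector returns no boxes for background or sub-threshold areas", {
  flat <- pf_raster(matrix(0.1, 50, 50), gt_northup())
  expect_identical(nrow(detect_plants_reference(flat)), 0L)
  small <- disk_image(50, 50, rbind(c(25, 25)), r = 2)
  got <- detect_plants_reference(pf_raster(small, gt_northup()),
                                 min_area_px = 50,
                                 intensity_threshold = 0.5)
  expect_identical(nrow(got), 0L)
})

test_that("greenness index drives 3-band detection and otsu finds the split", {
  set.seed(4)
  arr <- array(0, dim = c(60, 60, 3))
  arr[, , 1] <- 0.45 + rnorm(3600, 0, 0.02)
  arr[, , 2] <- 0.33 + rnorm(3600, 0, 0.02)
  arr[, , 3] <- 0.22 + rnorm(3600, 0, 0.02)
  d <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100
  g <- arr[, , 2]; g[d] <- 0.6; arr[, , 2] <- g
  rr <- arr[, , 1]; rr[d] <- 0.2; arr[, , 1] <- rr
  boxes <- detect_plants_reference(pf_raster(arr, gt_northup()),
                                   min_area_px = 20)
  expect_identical(nrow(boxes), 1L)
})

test_that("detections_to_geo preserves count/order and matches a UTM oracle", {
  gt <- gt_northup(step = 1e-5)
  boxes <- data.frame(x_min = c(5, 40), y_min = c(5, 20),
                      x_max = c(15, 50), y_max = c(15, 30),
                      confidence = c(0.9, 0.4))
  rec <- detections_to_geo(boxes, gt, "2020-02-17", "rgb", "p01")
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$confidence, c(0.9, 0.4))
  expect_identical(rec$sensor, rep("rgb", 2))
  ## independent UTM-extent oracle for the bounding area
  for (i in 1:2) {
    nw <- pixel_to_geo(gt, boxes$x_min[i], boxes$y_min[i])
    se <- pixel_to_geo(gt, boxes$x_max[i], boxes$y_max[i])
    z <- utm_zone_from_lon(nw$lon)
    u <- geo_to_utm(c(nw$lon, se$lon), c(nw$lat, se$lat), zone = z)
    oracle <- abs(diff(u$easting) * diff(u$northing))
    expect_equal(rec$bounding_area[i], oracle, tolerance = 1e-6)
    expect_equal(rec$center_lon[i], (nw$lon + se$lon) / 2)
  }
  ## 10x10 px at 1e-5 deg/px: ~9.3 m E-W x ~11.1 m N-S at this latitude
  expect_gt(rec$bounding_area[1], 90)
  expect_lt(rec$bounding_area[1], 115)
  ## empty input -> empty output
  expect_identical(nrow(detections_to_geo(boxes[0, ], gt, "d", "rgb", "p")), 0L)
})

test_that("bounding area grows with pixel-box area under a fixed geotransform", {
  gt <- gt_northup(step = 1e-5)
  sizes <- c(4, 8, 16, 32)
  ba <- vapply(sizes, function(s) {
    detections_to_geo(data.frame(x_min = 0, y_min = 0, x_max = s, y_max = s,
                                 confidence = 1), gt, "d", "rgb", "p")$bounding_area
  }, numeric(1))
  expect_true(all(diff(ba) > 0))
})

test_that("detector registry injects detectors by name", {
  expect_error(get_detector("nope"), "unknown detector")
  register_detector("constant", function(clip, params)
    data.frame(x_min = 0, y_min = 0, x_max = 1, y_max = 1, confidence = 1))
  expect_identical(nrow(get_detector("constant")(NULL, list())), 1L)
})

test_that("reference detector achieves recall and precision >= 0.95 on a synthetic scene", {
  r <- tiny_render("2020-02-10", "rgb")
  boxes <- detect_plants_reference(r$rgb$raster, min_area_px = 15)
  truths <- r$rgb$truth_boxes
  mr <- match_detections(boxes, truths)
  met <- detection_metrics(mr$confusion)
  expect_gte(met$recall, 0.95)
  expect_gte(met$precision, 0.95)
})
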