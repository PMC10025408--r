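test_that("ASCII PLY round-trips points, intensity and frame tag", {
  sc <- structured_cloud(n_plant = 50, n_ground = 30)
  cl <- sc$cloud
  cl$intensity <- seq_len(nrow(cl$points)) / 10
  path <- file.path(tempdir(), "rt.ply")
  write_ply(cl, path)
  cl2 <- read_ply(path)
  expect_identical(cl2$points, cl$points)
  expect_identical(cl2$intensity, cl$intensity)
  expect_identical(cl2$frame, "field")
  expect_error(point_cloud(matrix(1, 2, 2)), "N x 3")
  expect_error(point_cloud(matrix(c(1, NA, 1), 1, 3)), "finite")
})

test_that("orient_and_scale applies scale, mirror and offsets, and inverts", {
  sc <- structured_cloud(n_plant = 40, n_ground = 20)
  raw <- point_cloud(sc$cloud$points * 1000, frame = "raw")  # mm units
  meta <- list(scale = 1e-3, offset = c(5, 10, 0.76), scan_direction = "east")
  fld <- orient_and_scale(raw, meta)
  expect_identical(fld$frame, "field")
  expect_equal(fld$points[, 1], sc$cloud$points[, 1] + 5, tolerance = 1e-12)
  ## west-scan mirror restores chirality: y reflected before offsets
  metaw <- modifyList(meta, list(scan_direction = "west"))
  fw <- orient_and_scale(raw, metaw)
  expect_equal(fw$points[, 2], -sc$cloud$points[, 2] + 10, tolerance = 1e-12)
  ## round trip
  back <- unorient_and_scale(fw, metaw)
  expect_equal(back$points, raw$points, tolerance = 1e-9)
  expect_error(orient_and_scale(raw, list(scale = 1)), "malformed-metadata")
})

test_that("dual-scan RANSAC translation recovers known shifts", {
  sc <- structured_cloud(n_plant = 800, n_ground = 500, seed = 12)
  east <- sc$cloud
  ## identical clouds -> near-zero translation
  al0 <- align_dual_scans(east, east, seed = 1)
  expect_lt(max(abs(al0$translation)), 1e-9)
  ## clean shift
  west <- east
  west$points[, 1] <- west$points[, 1] + 0.03
  west$points[, 2] <- west$points[, 2] - 0.01
  al <- align_dual_scans(east, west, seed = 1)
  expect_lt(max(abs(al$translation - c(-0.03, 0.01))), 1e-3)
  ## 1 mm noise and 10% gross outliers
  set.seed(13)
  wp <- west$points + matrix(rnorm(length(west$points), 0, 0.001),
                             nrow(west$points))
  out_idx <- sample.int(nrow(wp), round(0.1 * nrow(wp)))
  wp[out_idx, 1:2] <- wp[out_idx, 1:2] + matrix(runif(2 * length(out_idx), -0.5, 0.5),
                                                length(out_idx))
  noisy <- point_cloud(wp, frame = "field")
  al2 <- align_dual_scans(east, noisy, seed = 2)
  expect_lt(max(abs(al2$translation - c(-0.03, 0.01))), 5e-3)
  ## clouds with no common structure (disjoint z bands; the aligner only
  ## translates in xy) fail registration
  set.seed(99)
  far <- point_cloud(cbind(runif(500, -0.4, 0.4), runif(500, -0.4, 0.4),
                           runif(500, 5, 6)), frame = "field")
  expect_error(align_dual_scans(east, far, seed = 1, ransac_iters = 20),
               "registration-failed")
})

test_that("landmark affine is recovered from exact correspondences", {
  true_t <- affine_transform_2d(a = 1e-5, b = 0, c = -112, d = 0, e = -1e-5,
                                f = 33)
  xy <- cbind(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10))
  pairs <- data.frame(x = xy[, 1], y = xy[, 2],
                      lon = true_t$a * xy[, 1] + true_t$b * xy[, 2] + true_t$c,
                      lat = true_t$d * xy[, 1] + true_t$e * xy[, 2] + true_t$f)
  est <- estimate_landmark_affine(pairs)
  for (k in c("a", "b", "c", "d", "e", "f"))
    expect_lt(abs(est[[k]] - true_t[[k]]), 1e-10)
  ## 3 exact pairs interpolate with zero residual
  est3 <- estimate_landmark_affine(pairs[1:3, ])
  expect_lt(est3$rms, 1e-12)
  expect_error(estimate_landmark_affine(pairs[1:2, ]), "underdetermined")
  coll <- data.frame(x = 1:5, y = 2 * (1:5), lon = 1:5, lat = 1:5)
  expect_error(estimate_landmark_affine(coll), "collinear")
})

test_that("landmark-affine RMS residual matches least-squares expectation", {
  ## 20 pairs, gaussian residuals sigma: E[RMS^2] = sigma^2 (1 - 6/(2*20))
  sigma <- 2e-7
  rms2 <- replicate(200, {
    set.seed(NULL)
    x <- runif(20, 0, 20); y <- runif(20, 0, 20)
    pairs <- data.frame(x = x, y = y,
                        lon = 1e-5 * x - 112 + rnorm(20, 0, sigma),
                        lat = -1e-5 * y + 33 + rnorm(20, 0, sigma))
    estimate_landmark_affine(pairs)$rms^2
  })
  expect_equal(mean(rms2), sigma^2 * (1 - 6 / 40), tolerance = 0.1)
})

test_that("apply_affine maps xy, preserves z contract, and inverts", {
  sc <- structured_cloud(n_plant = 60, n_ground = 40)
  t1 <- affine_transform_2d(a = 1e-5, b = 2e-7, c = -112, d = -1e-7,
                            e = -1.1e-5, f = 33, z_scale = 2, z_offset = 0.1)
  geo <- apply_affine(sc$cloud, t1)
  expect_identical(geo$frame, "geo")
  expect_equal(geo$points[, 3], sc$cloud$points[, 3] * 2 + 0.1)
  back <- apply_affine(geo, invert_affine(t1))
  ## double-precision floor: inverting cancels ~112 degrees against
  ## 1e-5-degree coordinates
  expect_lt(max(abs(back$points - sc$cloud$points)), 1e-7)
  ## identity and translation-only transforms
  ident <- affine_transform_2d(1, 0, 0, 0, 1, 0)
  expect_equal(apply_affine(sc$cloud, ident)$points[, 1:2],
               sc$cloud$points[, 1:2])
  shift <- affine_transform_2d(1, 0, 0.5, 0, 1, -0.25)
  sh <- apply_affine(sc$cloud, shift)
  expect_equal(unname(colMeans(sh$points[, 1:2]) -
                        colMeans(sc$cloud$points[, 1:2])),
               c(0.5, -0.25), tolerance = 1e-12)
})

test_that("clip_plants gathers exactly the in-box points per tile", {
  set.seed(14)
  n <- 5000
  lon <- runif(n, -112.0002, -111.9998); lat <- runif(n, 33.00, 33.0004)
  tile <- point_cloud(cbind(lon, lat, runif(n, 0, 0.2)), frame = "geo")
  det <- data.frame(plant_id = "P1", date = "d",
                    nw_lon = -112.0001, nw_lat = 33.0002,
                    se_lon = -112.00005, se_lat = 33.0001,
                    center_lon = -112.000075, center_lat = 33.00015)
  frags <- clip_plants(list(t1 = tile), det, pad = 0)
  frag <- frags[["P1|t1"]]
  ## brute-force point-in-box oracle in UTM
  z <- utm_zone_from_lon(det$center_lon)
  u <- geo_to_utm(lon, lat, zone = z)
  cu <- geo_to_utm(c(det$nw_lon, det$se_lon), c(det$nw_lat, det$se_lat), zone = z)
  inbox <- u$easting >= min(cu$easting) & u$easting <= max(cu$easting) &
    u$northing >= min(cu$northing) & u$northing <= max(cu$northing)
  expect_identical(nrow(frag$cloud$points), sum(inbox))
  ## pad monotone containment
  frags_pad <- clip_plants(list(t1 = tile), det, pad = 5)
  expect_gte(nrow(frags_pad[["P1|t1"]]$cloud$points), nrow(frag$cloud$points))
  ## detection outside all tiles -> empty, flagged
  det_far <- det
  det_far[c("nw_lon", "se_lon", "center_lon")] <-
    det_far[c("nw_lon", "se_lon", "center_lon")] + 1
  fr2 <- clip_plants(list(t1 = tile), det_far, pad = 0)
  expect_true(fr2[["P1|t1"]]$empty)
})

test_that("ICP recovers a known rigid transform and merges fragments", {
  sc <- structured_cloud(n_plant = 500, n_ground = 200, seed = 15)
  a <- sc$cloud
  ## b = a rotated 2 degrees about z and shifted
  th <- 2 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- point_cloud(sweep(a$points %*% t(Rz), 2, c(0.02, 0.01, 0), "+"),
                   frame = "field")
  res <- icp_merge(a, b, max_corr = 0.1)
  expect_true(res$accepted)
  ## recovered transform composed with the applied one is the identity
  ang_err <- acos(pmin(1, (sum(diag(res$R %*% Rz)) - 1) / 2))
  expect_lt(ang_err, 1e-3)
  expect_lt(max(abs(res$R %*% c(0.02, 0.01, 0) + res$t)), 1e-3)
  expect_identical(nrow(res$merged$points), 2L * nrow(a$points))
  ## identity case
  res0 <- icp_merge(a, a, max_corr = 0.1)
  expect_lt(max(abs(res0$R - diag(3))), 1e-9)
  expect_lt(max(abs(res0$t)), 1e-9)
})

test_that("ICP objective trace is monotone non-increasing under noise", {
  sc <- structured_cloud(n_plant = 400, n_ground = 150, seed = 16)
  a <- sc$cloud
  set.seed(17)
  bp <- a$points + matrix(rnorm(length(a$points), 0, 0.002), nrow(a$points))
  b <- point_cloud(sweep(bp, 2, c(0.01, -0.005, 0), "+"), frame = "field")
  res <- icp_merge(a, b, max_corr = 0.1)
  expect_true(all(diff(res$error_trace) <= 1e-12))
  ## non-overlapping fragments get rejected with a warning
  far <- point_cloud(sweep(a$points, 2, c(10, 0, 0), "+"), frame = "field")
  expect_warning(res2 <- icp_merge(a, far, max_corr = 0.05, max_iter = 5),
                 "rejected")
  expect_false(res2$accepted)
  expect_null(res2$merged)
})

test_that("landmark JSON file contract round-trips", {
  pairs <- data.frame(x = c(0, 5, 2), y = c(1, 0, 4),
                      lon = c(-112, -111.99995, -112.00002),
                      lat = c(33, 33.00001, 33.00004))
  path <- file.path(tempdir(), "lm.json")
  write_landmarks(pairs, path)
  got <- read_landmarks(path)
  expect_equal(got, pairs, tolerance = 1e-12)
})
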