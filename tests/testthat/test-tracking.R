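## constructed multi-date detection tables
mk_dets <- function(centers, dates, jitter = 1e-8, sensor = "rgb",
                    plot_id = "p1", seed = 27) {
  set.seed(seed)
  do.call(rbind, lapply(dates, function(d) {
    data.frame(date = d, sensor = sensor, plot_id = plot_id,
               center_lon = centers[, 1] + rnorm(nrow(centers), 0, jitter),
               center_lat = centers[, 2] + rnorm(nrow(centers), 0, jitter),
               bounding_area = 0.05, confidence = 1,
               stringsAsFactors = FALSE)
  }))
}

test_that("well-separated plants form one cluster per plant across dates", {
  centers <- cbind(-112 + (0:4) * 2e-6, 33)
  dets <- mk_dets(centers, c("d1", "d2", "d3"))
  cl <- cluster_detections(dets, threshold = 6e-7)
  expect_identical(nrow(cl$clusters), 5L)
  expect_true(all(cl$clusters$n_members == 3L))
  ## track purity: every cluster holds one true plant
  true_plant <- rep(rep(1:5, 3), 1)
  purity <- vapply(split(true_plant, cl$members$plant_id),
                   function(g) mean(g == g[1]), numeric(1))
  expect_true(all(purity == 1))
  ## membership invariant under input order
  perm <- sample(nrow(dets))
  cl2 <- cluster_detections(dets[perm, ], threshold = 6e-7)
  key <- function(x) unname(split(order(x$members$center_lon),
                                  x$members$plant_id[order(x$members$center_lon)]))
  expect_identical(nrow(cl2$clusters), 5L)
  expect_identical(sort(cl2$clusters$n_members), sort(cl$clusters$n_members))
})

test_that("single detections and marked outliers behave as specified", {
  one <- mk_dets(cbind(-112, 33), "d1")
  cl <- cluster_detections(one)
  expect_identical(nrow(cl$clusters), 1L)
  expect_false(cl$clusters$is_double)
  ## a cluster containing a marked outlier point is flagged double
  centers <- cbind(-112 + (0:2) * 2e-6, 33)
  dets <- mk_dets(centers, c("d1", "d2"))
  outl <- data.frame(lon = -112 + 2e-6, lat = 33)  # on plant 2
  cl2 <- cluster_detections(dets, outliers = outl)
  expect_identical(sum(cl2$clusters$is_double), 1L)
  dbl <- cl2$clusters[cl2$clusters$is_double, ]
  expect_lt(abs(dbl$centroid_lon - (-112 + 2e-6)), 1e-7)
  ## empty input
  cl0 <- cluster_detections(dets[0, ])
  expect_identical(nrow(cl0$clusters), 0L)
})

test_that("same-date surplus members are split into new clusters", {
  ## two same-date detections close together plus one on another date
  dets <- data.frame(date = c("d1", "d1", "d2"), sensor = "rgb",
                     plot_id = "p1",
                     center_lon = -112 + c(0, 1e-8, 0.5e-8),
                     center_lat = c(33, 33, 33),
                     stringsAsFactors = FALSE)
  cl <- cluster_detections(dets, threshold = 6e-7)
  expect_identical(nrow(cl$clusters), 2L)
  per_cluster <- split(dets$date, cl$members$plant_id)
  expect_true(all(vapply(per_cluster, anyDuplicated, integer(1)) == 0L))
})

test_that("plant ids combine genotype and cluster number", {
  pm <- plot_map(data.frame(plot_id = "p1", genotype = "Iceberg",
                            treatment = "WW"),
                 list(cbind(c(-112.1, -111.9, -111.9, -112.1),
                            c(32.9, 32.9, 33.1, 33.1))))
  dets <- mk_dets(cbind(-112 + (0:1) * 2e-6, 33), "d1")
  cl <- cluster_detections(dets, plots = pm)
  expect_true(all(grepl("^Iceberg_[0-9]+$", cl$clusters$plant_id)))
  expect_false(anyDuplicated(cl$clusters$plant_id) > 0)
})

test_that("thermal detections merge into nearest clusters within threshold", {
  centers <- cbind(-112 + (0:3) * 2e-6, 33)
  rgb <- mk_dets(centers, c("d1", "d2"))
  cl <- cluster_detections(rgb)
  th <- mk_dets(centers, "d1", sensor = "thermal", seed = 28)
  th$center_lon <- th$center_lon + 1e-8
  mg <- merge_rgb_thermal(cl, th)
  expect_identical(nrow(mg$unmatched), 0L)
  expect_identical(sum(mg$clusters$members$sensor == "thermal"), 4L)
  ## ids inherited from the host cluster
  tm <- mg$clusters$members
  for (i in which(tm$sensor == "thermal")) {
    host <- tm[tm$sensor == "rgb" &
                 abs(tm$center_lon - tm$center_lon[i]) < 1e-7, ]
    expect_true(tm$plant_id[i] %in% host$plant_id)
  }
  ## far detection stays unmatched; empty set is a no-op
  far <- mk_dets(cbind(-112 + 1e-3, 33), "d1", sensor = "thermal")
  mg2 <- merge_rgb_thermal(cl, far)
  expect_identical(nrow(mg2$unmatched), 1L)
  mg3 <- merge_rgb_thermal(cl, far[0, ])
  expect_identical(nrow(mg3$clusters$members), nrow(cl$members))
})

test_that("join_modalities broadcasts PSII by plot and unions keys", {
  pm <- plot_map(data.frame(plot_id = "p1", genotype = "G1", treatment = "WW"),
                 list(cbind(c(-113, -111, -111, -113), c(32, 32, 34, 34))))
  dets <- mk_dets(cbind(-112 + (0:1) * 2e-6, 33), c("d1", "d2"))
  cl <- cluster_detections(dets, plots = pm)
  psii <- data.frame(plot_id = "p1", date = "d1", f0 = 100, fm = 500,
                     fv = 400, fvfm = 0.8)
  t3d <- data.frame(plant_id = c(cl$clusters$plant_id[1], "ghost_9"),
                    date = c("d2", "d2"), ph = c(0.1, 0.2),
                    aabv = 1e-3, obv = 1e-3, chv = 5e-4, np = 100)
  expect_warning(rec <- join_modalities(cl, psii, t3d, plots = pm), "orphan")
  ## union of keys: 2 plants x 2 dates + orphan
  expect_identical(nrow(rec), 5L)
  d1 <- rec[rec$date == "d1" & !rec$orphan, ]
  expect_true(all(d1$fvfm == 0.8))   # plot-level broadcast
  expect_true(all(is.na(d1$ph)))     # no 3D on that date
  d2 <- rec[rec$date == "d2" & rec$plant_id == cl$clusters$plant_id[1], ]
  expect_equal(d2$ph, 0.1)
  expect_true(rec$orphan[rec$plant_id == "ghost_9"])
  expect_true(all(rec$genotype[!rec$orphan] == "G1"))
})

test_that("association confusion follows the marked/flagged contract", {
  ## direct count arithmetic: TP=99 FN=1 FP=7 TN=893
  assessed <- data.frame(
    marked = rep(c(TRUE, TRUE, FALSE, FALSE), c(99, 1, 7, 893)),
    flagged = rep(c(TRUE, FALSE, TRUE, FALSE), c(99, 1, 7, 893)))
  ev <- evaluate_association(assessed)
  expect_equal(ev$recall, 0.99)
  expect_equal(ev$precision, 99 / 106, tolerance = 1e-12)
  expect_equal(ev$accuracy, 0.992)
  ## perfect flagging
  perf <- data.frame(marked = c(TRUE, TRUE, FALSE), flagged = c(TRUE, TRUE, FALSE))
  evp <- evaluate_association(perf)
  expect_equal(evp$recall, 1); expect_equal(evp$precision, 1)
  ## zero marked and zero flagged: recall absent, accuracy 1
  none <- data.frame(marked = rep(FALSE, 10), flagged = rep(FALSE, 10))
  evn <- evaluate_association(none)
  expect_true(is.na(evn$recall))
  expect_equal(evn$accuracy, 1)
})
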