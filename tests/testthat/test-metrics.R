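box_df <- function(x0, y0, x1, y1) list(x_min = x0, y_min = y0,
                                        x_max = x1, y_max = y1)

test_that("iou handles identity, disjoint and the 1/7 worked case", {
  a <- pixel_box(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, pixel_box(10, 10, 12, 12)), 0.0)
  b <- pixel_box(1, 1, 3, 3)
  expect_equal(iou(a, b), 1 / 7, tolerance = 1e-12)
  expect_identical(iou(a, b), iou(b, a))
  expect_error(iou(a, box_df(0, 0, 2, 2)), "same coordinate kind")
})

test_that("iou matches a rasterized overlap-count oracle", {
  set.seed(24)
  for (i in 1:20) {
    c1 <- sort(runif(2, 0, 10)); c2 <- sort(runif(2, 0, 10))
    c3 <- sort(runif(2, 0, 10)); c4 <- sort(runif(2, 0, 10))
    a <- box_df(c1[1], c2[1], c1[2], c2[2])
    b <- box_df(c3[1], c4[1], c3[2], c4[2])
    ## fine-grid pixel-count oracle
    g <- seq(0.0025, 10, by = 0.005)
    ina <- outer(g >= a$y_min & g <= a$y_max, g >= a$x_min & g <= a$x_max, "&")
    inb <- outer(g >= b$y_min & g <= b$y_max, g >= b$x_min & g <= b$x_max, "&")
    oracle <- sum(ina & inb) / sum(ina | inb)
    expect_equal(iou(a, b), oracle, tolerance = 0.02)
  }
})

test_that("iou shrinks monotonically as one box shrinks inside the other", {
  outer_box <- pixel_box(0, 0, 10, 10)
  sizes <- c(9, 6, 3, 1)
  vals <- vapply(sizes, function(s) iou(outer_box, pixel_box(0, 0, s, s)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("greedy matching assigns one truth per prediction", {
  truths <- data.frame(x_min = c(0, 20), y_min = c(0, 0),
                       x_max = c(10, 30), y_max = c(10, 10))
  ## exact predictions
  mr <- match_detections(truths, truths)
  expect_identical(mr$confusion$tp, 2L)
  expect_identical(mr$confusion$fp, 0L)
  expect_identical(mr$confusion$fn, 0L)
  ## no predictions -> all FN
  mr0 <- match_detections(truths[0, ], truths)
  expect_identical(mr0$confusion$fn, 2L)
  ## two predictions on one truth: best is TP, the other FP
  preds <- data.frame(x_min = c(0, 1), y_min = c(0, 1),
                      x_max = c(10, 10), y_max = c(10, 10))
  mr2 <- match_detections(preds, truths[1, , drop = FALSE])
  expect_identical(mr2$confusion$tp, 1L)
  expect_identical(mr2$confusion$fp, 1L)
  expect_identical(mr2$confusion$fn, 0L)
  expect_identical(which(mr2$matches$tp), 1L)  # the higher-IoU prediction
})

test_that("recall/precision/F1 follow their formulas with NA on empty classes", {
  m <- detection_metrics(detection_confusion(tp = 8, fp = 2, fn = 2))
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$f1, 0.8)
  ## harmonic-mean bracketing
  set.seed(25)
  for (i in 1:50) {
    c <- detection_confusion(tp = sample(0:50, 1), fp = sample(1:20, 1),
                             fn = sample(1:20, 1))
    mm <- detection_metrics(c)
    expect_gte(mm$f1 + 1e-12, min(mm$precision, mm$recall))
    expect_lte(mm$f1 - 1e-12, max(mm$precision, mm$recall))
  }
  und <- detection_metrics(detection_confusion(tp = 0, fp = 0, fn = 0))
  expect_true(is.na(und$recall) && is.na(und$precision))
  expect_false(und$defined[["recall"]])
})

test_that("point-wise accuracy is (TP+TN)/total", {
  expect_equal(pointwise_accuracy(detection_confusion(90, 3, 2, tn = 5)), 0.95)
  expect_equal(pointwise_accuracy(detection_confusion(7, 0, 0, tn = 3)), 1.0)
  expect_error(pointwise_accuracy(detection_confusion(1, 1, 1)), "tn")
  ## counting oracle on a synthetic labeling
  set.seed(26)
  truth <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  pred <- truth; flip <- sample(500, 50); pred[flip] <- !pred[flip]
  cc <- detection_confusion(tp = sum(pred & truth), fp = sum(pred & !truth),
                            fn = sum(!pred & truth), tn = sum(!pred & !truth))
  expect_equal(pointwise_accuracy(cc), mean(pred == truth))
})

test_that("median IoU is grouped by date and matches sort-and-pick", {
  matches <- data.frame(iou = c(0.2, 0.8, 0.9, 0.5, 0.7),
                        date = c("d1", "d1", "d1", "d2", "d2"))
  med <- median_iou_by_date(matches)
  expect_identical(nrow(med), 2L)
  expect_equal(med$median_iou[med$date == "d1"], 0.8)
  expect_equal(med$median_iou[med$date == "d2"], 0.6)
  ## brute-force oracle
  brute <- function(v) { s <- sort(v); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else mean(s[n / 2 + 0:1]) }
  expect_equal(med$median_iou[med$date == "d1"], brute(c(0.2, 0.8, 0.9)))
})

test_that("round_half_up rounds half away from zero", {
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(-0.125, 2), -0.13)
  expect_identical(round_half_up(0.934, 2), 0.93)
})
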