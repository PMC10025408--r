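#' Intersection over union of two boxes
#'
#' IoU = |A intersect B| / |A union B| for two axis-aligned boxes of the
#' same coordinate kind (both pixel boxes, or both geographic boxes in
#' lon/lat). Returns 0 for disjoint boxes.
#'
#' @param a,b boxes: \code{\link{pixel_box}} objects, or any list/row with
#'   \code{x_min, y_min, x_max, y_max} fields.
#' @return IoU in [0, 1].
#' @examples
#' iou(pixel_box(0, 0, 2, 2), pixel_box(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  if (inherits(a, "pixel_box") != inherits(b, "pixel_box"))
    stop_invalid("boxes must be of the same coordinate kind")
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- area_a + area_b - inter
  if (un <= 0) return(0)
  inter / un
}

#' Match predicted boxes to ground-truth boxes
#'
#' Greedy one-to-one matching by descending IoU: each truth box is
#' consumed by at most one prediction. A prediction whose best available
#' IoU is >= \code{iou_threshold} is a true positive; otherwise it is a
#' false positive. Every unmatched truth is a false negative.
#'
#' @param preds,truths data.frames of boxes with \code{x_min, y_min,
#'   x_max, y_max} columns; \code{preds} may carry a \code{date} column
#'   propagated into the match table.
#' @param iou_threshold TP threshold (0.5 by convention).
#' @return list with \code{matches} (per-prediction best IoU, matched
#'   truth index or NA, TP flag, date) and \code{confusion} (tp, fp, fn
#'   counts).
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  np <- nrow(preds); nt <- nrow(truths)
  date <- if ("date" %in% names(preds)) preds$date else rep(NA_character_, np)
  if (np == 0) {
    return(list(matches = data.frame(pred = integer(), iou = numeric(),
                                     truth = integer(), tp = logical(),
                                     date = character()),
                confusion = detection_confusion(tp = 0, fp = 0, fn = nt)))
  }
  m <- matrix(0, np, max(nt, 1))
  if (nt > 0)
    for (i in seq_len(np)) for (j in seq_len(nt))
      m[i, j] <- iou(preds[i, ], truths[j, ])
  best_iou <- rep(0, np); best_truth <- rep(NA_integer_, np)
  taken <- rep(FALSE, max(nt, 1))
  if (nt > 0) {
    ord <- order(-as.vector(m), as.vector(row(m)), as.vector(col(m)))
    assigned <- rep(FALSE, np)
    for (k in ord) {
      if (m[k] <= 0) break
      i <- row(m)[k]; j <- col(m)[k]
      if (assigned[i] || taken[j]) next
      assigned[i] <- TRUE; taken[j] <- TRUE
      best_iou[i] <- m[i, j]; best_truth[i] <- j
    }
  }
  tp_flag <- best_iou >= iou_threshold
  matches <- data.frame(pred = seq_len(np), iou = best_iou,
                        truth = best_truth, tp = tp_flag,
                        date = date, stringsAsFactors = FALSE)
  conf <- detection_confusion(tp = sum(tp_flag), fp = sum(!tp_flag),
                              fn = if (nt > 0) sum(!taken) else 0)
  list(matches = matches, confusion = conf)
}

#' Detection confusion counts
#' @param tp,fp,fn,tn non-negative counts (\code{tn} only meaningful in
#'   point-wise contexts).
#' @return an object of class \code{detection_confusion}.
#' @export
detection_confusion <- function(tp = 0, fp = 0, fn = 0, tn = NA_real_) {
  if (any(c(tp, fp, fn, tn) < 0, na.rm = TRUE)) stop_invalid("counts must be >= 0")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "detection_confusion")
}

#' Recall, precision and F1 from confusion counts
#'
#' recall = TP/(TP+FN); precision = TP/(TP+FP);
#' F1 = 2 * precision * recall / (precision + recall). An undefined
#' denominator yields NA for that metric with \code{defined} flags.
#'
#' @param c a \code{\link{detection_confusion}} (or list with tp, fp, fn).
#' @return list with \code{recall}, \code{precision}, \code{f1} and a
#'   \code{defined} logical vector.
#' @examples
#' detection_metrics(detection_confusion(tp = 2519, fp = 178, fn = 54))
#' @export
detection_metrics <- function(c) {
  recall <- if ((c$tp + c$fn) > 0) c$tp / (c$tp + c$fn) else NA_real_
  precision <- if ((c$tp + c$fp) > 0) c$tp / (c$tp + c$fp) else NA_real_
  f1 <- if (is.na(recall) || is.na(precision)) NA_real_
    else if ((recall + precision) > 0)
      2 * precision * recall / (precision + recall)
    else 0  # both defined and zero
  list(recall = recall, precision = precision, f1 = f1,
       defined = c(recall = !is.na(recall), precision = !is.na(precision),
                   f1 = !is.na(f1)))
}

#' Point-wise accuracy
#'
#' (TP + TN) / (TP + FP + TN + FN), for point-wise segmentation
#' assessment.
#'
#' @param c a \code{\link{detection_confusion}} with \code{tn} populated.
#' @return accuracy in [0, 1].
#' @export
pointwise_accuracy <- function(c) {
  if (is.na(c$tn)) stop_invalid("tn count required for point-wise accuracy")
  total <- c$tp + c$fp + c$tn + c$fn
  if (total <= 0) stop_invalid("zero total count")
  (c$tp + c$tn) / total
}

#' Median IoU per collection date
#'
#' @param matches the \code{matches} data.frame from
#'   \code{\link{match_detections}} (possibly row-bound over dates).
#' @return data.frame with \code{date} and \code{median_iou}.
#' @export
median_iou_by_date <- function(matches) {
  sp <- split(matches$iou, matches$date)
  data.frame(date = names(sp),
             median_iou = vapply(sp, median, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Rounding used when comparing against printed tables (R's
#' \code{round} rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
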