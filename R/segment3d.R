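#' Segment plant and soil points by RANSAC plane fit
#'
#' Mirrors the model-assisted annotation heuristic: a RANSAC plane is fit
#' to the cloud (the ground), refined by least squares on its inliers,
#' and oriented upward. Points within \code{dist_thresh} of the plane, or
#' below the plane plus \code{margin}, are soil; the rest are plant.
#' Learned segmenters can replace this reference implementation through
#' the same labels contract.
#'
#' @param cloud a \code{\link{point_cloud}} containing ground points.
#' @param plane_iters RANSAC iterations.
#' @param dist_thresh plane inlier distance in meters.
#' @param margin height above the plane still labeled soil, meters.
#' @param min_inlier_frac segmentation fails below this plane inlier
#'   fraction.
#' @param seed RNG seed.
#' @return list with \code{labels} (character "plant"/"soil"),
#'   \code{plane} (normal \code{n}, offset \code{d} with n.p = d),
#'   \code{inlier_frac}.
#' @export
segment_plant_soil <- function(cloud, plane_iters = 100, dist_thresh = 0.004,
                               margin = 0.005, min_inlier_frac = 0.15,
                               seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  n <- nrow(P)
  if (n < 3) stop_invalid("segmentation-failed: fewer than 3 points")
  withr_seed(seed, {
    ## the scanners look down, so the ground is the lowest surface:
    ## drawing candidate triples from the lower half of the z range makes
    ## the RANSAC robust to canopy-dominated clips
    low <- which(P[, 3] <= quantile(P[, 3], 0.5))
    if (length(low) < 3) low <- seq_len(n)
    best <- list(count = -1L, n = c(0, 0, 1), d = 0)
    for (it in seq_len(plane_iters)) {
      i <- low[sample.int(length(low), 3)]
      v1 <- P[i[2], ] - P[i[1], ]; v2 <- P[i[3], ] - P[i[1], ]
      nv <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next
      nv <- nv / nn
      d <- sum(nv * P[i[1], ])
      cnt <- sum(abs(P %*% nv - d) <= dist_thresh)
      if (cnt > best$count) best <- list(count = cnt, n = nv, d = d)
    }
    if (best$count < 3) stop_invalid("segmentation-failed: no plane found")
    ## least-squares refinement on the inliers
    inl <- abs(P %*% best$n - best$d) <= dist_thresh
    Q <- P[inl, , drop = FALSE]
    ctr <- colMeans(Q)
    ev <- eigen(crossprod(sweep(Q, 2, ctr)), symmetric = TRUE)
    nv <- ev$vectors[, 3]
    if (nv[3] < 0) nv <- -nv  # orient upward
    d <- sum(nv * ctr)
    signed <- as.numeric(P %*% nv - d)
    inlier_frac <- mean(abs(signed) <= dist_thresh)
    if (inlier_frac < min_inlier_frac)
      stop_invalid("segmentation-failed: plane inlier fraction ",
                   signif(inlier_frac, 3), " below floor")
    soil <- abs(signed) <= dist_thresh | signed < margin
    list(labels = ifelse(soil, "soil", "plant"),
         plane = list(n = nv, d = d), inlier_frac = inlier_frac)
  })
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distance: core points have at least
#' \code{min_pts} neighbors (self included) within \code{eps}; clusters
#' are connected components of core points plus their border points;
#' label 0 marks noise.
#'
#' @param points N x d numeric matrix.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size for a core point.
#' @return integer cluster labels of length N (0 = noise).
#' @export
dbscan_cluster <- function(points, eps, min_pts = 10) {
  P <- as.matrix(points)
  n <- nrow(P)
  d2 <- as.matrix(dist(P))^2
  eps2 <- eps^2
  nbrs <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Strip residual neighbor-plant points with DBSCAN
#'
#' Clusters the plant-labeled points and keeps the cluster whose centroid
#' is nearest the expected plant center (ties broken by larger cluster);
#' noise points are dropped.
#'
#' @param cloud a \code{\link{point_cloud}} of plant-labeled points in the
#'   local meter frame.
#' @param eps DBSCAN radius in meters.
#' @param min_pts DBSCAN core-point threshold.
#' @param expected_center length-2 (x, y) expected plant center in the
#'   cloud's frame; fragments clipped by \code{\link{clip_plants}} are
#'   centered, so the default is the origin.
#' @return the focal \code{\link{point_cloud}}.
#' @export
remove_neighbors_dbscan <- function(cloud, eps = 0.05, min_pts = 10,
                                    expected_center = c(0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (nrow(cloud$points) < min_pts)
    stop_invalid("empty-focal: fewer than min_pts points")
  labels <- dbscan_cluster(cloud$points, eps = eps, min_pts = min_pts)
  keep <- labels > 0
  if (!any(keep)) stop_invalid("empty-focal: all points labeled noise")
  ids <- sort(unique(labels[keep]))
  cent_d <- vapply(ids, function(k) {
    ctr <- colMeans(cloud$points[labels == k, 1:2, drop = FALSE])
    sqrt(sum((ctr - expected_center)^2))
  }, numeric(1))
  sizes <- vapply(ids, function(k) sum(labels == k), numeric(1))
  ord <- order(cent_d, -sizes)
  focal <- ids[ord[1]]
  point_cloud(cloud$points[labels == focal, , drop = FALSE],
              frame = cloud$frame)
}
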