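#' Point cloud container
#'
#' An N x 3 matrix of xyz coordinates (x east, y north, z up; meters in
#' the field frame after registration), optional per-point intensity, and
#' a frame tag: \code{raw} (scanner units), \code{field} (field meters)
#' or \code{geo} (xy in lon/lat degrees after the landmark affine).
#'
#' @param points N x 3 numeric matrix.
#' @param intensity optional numeric vector of length N.
#' @param frame frame tag.
#' @return an object of class \code{point_cloud}.
#' @export
point_cloud <- function(points, intensity = NULL,
                        frame = c("raw", "field", "geo")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1) stop_invalid("points must be N x 3 with N >= 1")
  if (!all(is.finite(points))) stop_invalid("points must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, intensity = intensity, frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, frame=%s\n", nrow(x$points), x$frame))
  invisible(x)
}

#' Write a point cloud as ASCII PLY
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param path output path.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  has_int <- !is.null(cloud$intensity)
  header <- c("ply", "format ascii 1.0",
              sprintf("comment frame %s", cloud$frame),
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              if (has_int) "property double intensity",
              "end_header")
  body <- if (has_int)
    sprintf("%.17g %.17g %.17g %.17g", cloud$points[, 1], cloud$points[, 2],
            cloud$points[, 3], cloud$intensity)
  else sprintf("%.17g %.17g %.17g", cloud$points[, 1], cloud$points[, 2],
               cloud$points[, 3])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Binary PLY is not supported; clouds written by \code{\link{write_ply}}
#' round-trip exactly.
#'
#' @param path PLY file path.
#' @return a \code{\link{point_cloud}}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop_invalid("not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop_invalid("PLY header missing end_header")
  header <- lines[1:end]
  if (!any(grepl("^format ascii", header))) stop_invalid("only ASCII PLY supported")
  nvert <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property", header, value = TRUE))
  frame <- sub("comment frame ", "", grep("^comment frame", header, value = TRUE)[1])
  if (is.na(frame) || !frame %in% c("raw", "field", "geo")) frame <- "raw"
  body <- lines[(end + 1):(end + nvert)]
  m <- matrix(as.numeric(unlist(strsplit(body, " ", fixed = TRUE))),
              ncol = length(props), byrow = TRUE)
  colnames(m) <- props
  point_cloud(m[, c("x", "y", "z"), drop = FALSE],
              intensity = if ("intensity" %in% props) m[, "intensity"] else NULL,
              frame = frame)
}

#' Orient and scale a raw scan into the field frame
#'
#' Applies the unit scale, the west-scan mirror flag (y-axis reflection,
#' restoring right-handed chirality), and the gantry position offsets,
#' producing a right-handed field frame (+x east, +y north, +z up).
#'
#' @param cloud a \code{\link{point_cloud}} in the raw frame.
#' @param metadata list with \code{scale} (raw unit to meters),
#'   \code{offset} (length-3 gantry offsets, m) and \code{scan_direction}
#'   ("east" or "west"; west scans are mirrored in y).
#' @return a field-frame \code{\link{point_cloud}}.
#' @export
orient_and_scale <- function(cloud, metadata) {
  stopifnot(inherits(cloud, "point_cloud"))
  req <- c("scale", "offset", "scan_direction")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop_invalid("malformed-metadata: missing ", paste(miss, collapse = ", "))
  p <- cloud$points * metadata$scale
  if (identical(metadata$scan_direction, "west")) p[, 2] <- -p[, 2]
  p <- sweep(p, 2, as.numeric(metadata$offset), "+")
  point_cloud(p, intensity = cloud$intensity, frame = "field")
}

#' Invert \code{\link{orient_and_scale}}
#' @param cloud a field-frame \code{\link{point_cloud}}.
#' @param metadata the same metadata passed to \code{\link{orient_and_scale}}.
#' @return the raw-frame cloud.
#' @export
unorient_and_scale <- function(cloud, metadata) {
  p <- sweep(cloud$points, 2, as.numeric(metadata$offset), "-")
  if (identical(metadata$scan_direction, "west")) p[, 2] <- -p[, 2]
  point_cloud(p / metadata$scale, intensity = cloud$intensity, frame = "raw")
}

## nearest-neighbor indices of each query row in ref (chunked brute
## force). Coordinates are centered first: the a^2 + b^2 - 2ab expansion
## cancels catastrophically when offsets (e.g. 1e-7 degrees) are tiny
## against the coordinate magnitude (e.g. longitude ~ -112).
nn1_index <- function(ref, query, chunk = 512L) {
  ctr <- colMeans(ref)
  ref <- sweep(ref, 2, ctr)
  query <- sweep(query, 2, ctr)
  nr <- nrow(ref); nq <- nrow(query)
  rs <- rowSums(ref^2)
  idx <- integer(nq); d2 <- numeric(nq)
  for (s in seq(1, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q^2), rs, "+") - 2 * q %*% t(ref)
    j <- max.col(-d, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- d[cbind(seq_len(e - s + 1L), j)]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

## restrict a scan pair to the densest above-ground window, so that
## nearest-neighbor scoring sees full local point density even on large
## field tiles. Window side in meters; slack covers the unknown shift.
scan_focus <- function(E, W, side = 2, slack = 0.3) {
  zt <- quantile(E[, 3], 0.5)
  Eh <- E[E[, 3] >= zt, , drop = FALSE]
  if (nrow(Eh) < 100) Eh <- E
  cx <- floor(Eh[, 1] / side); cy <- floor(Eh[, 2] / side)
  key <- paste(cx, cy)
  kbest <- names(which.max(table(key)))
  sel <- key == kbest
  ctr <- c(mean(Eh[sel, 1]), mean(Eh[sel, 2]))
  keep <- function(P, r) P[abs(P[, 1] - ctr[1]) <= r &
                           abs(P[, 2] - ctr[2]) <= r, , drop = FALSE]
  list(E = keep(E, side / 2 + slack), W = keep(W, side / 2 + 2 * slack))
}

#' Align a dual-scan pair by RANSAC translation
#'
#' Estimates the (x, y) translation bringing the west scan onto the east
#' scan. Scoring is restricted to the densest above-ground window of the
#' east scan (full local density is what makes nearest-neighbor inlier
#' counts meaningful on large tiles): random candidate correspondences
#' propose translations, each scored by the fraction of west focus
#' points with an east neighbor within \code{inlier_tol} after shifting;
#' the best proposal is refined by the mean inlier correspondence
#' offset. The z axis is untouched.
#'
#' @param east,west field-frame \code{\link{point_cloud}}s.
#' @param ransac_iters number of RANSAC proposals.
#' @param inlier_tol inlier distance tolerance in meters.
#' @param min_inlier_frac registration fails below this inlier fraction.
#' @param window focus window side in meters.
#' @param seed RNG seed.
#' @return list with \code{translation} (x, y), \code{inlier_frac}.
#' @export
align_dual_scans <- function(east, west, ransac_iters = 80,
                             inlier_tol = 0.015, min_inlier_frac = 0.25,
                             window = 2, seed = 1L) {
  stopifnot(inherits(east, "point_cloud"), inherits(west, "point_cloud"))
  withr_seed(seed, {
    fc <- scan_focus(east$points, west$points, side = window)
    E <- fc$E; W <- fc$W
    if (nrow(E) < 10 || nrow(W) < 10) { E <- east$points; W <- west$points }
    if (nrow(E) > 6000) E <- E[sample.int(nrow(E), 6000), , drop = FALSE]
    ## score with strictly above-ground points: a featureless ground plane
    ## matches at any xy shift and would swamp the inlier signal
    zg <- quantile(W[, 3], 0.1)
    Wh <- W[W[, 3] > zg + 0.03, , drop = FALSE]
    if (nrow(Wh) < 50) Wh <- W[W[, 3] >= quantile(W[, 3], 0.5), , drop = FALSE]
    if (nrow(Wh) < 50) Wh <- W
    score_n <- min(nrow(Wh), 300L)
    Ws <- Wh[sample.int(nrow(Wh), score_n), , drop = FALSE]
    ## correspondence candidates: canopy apexes (per-cell local z maxima)
    ## are the most distinctive features of the scene; at least one
    ## east/west apex pair belongs to the same physical plant
    apexes <- function(P, cell = 0.3) {
      top <- P[P[, 3] >= quantile(P[, 3], 0.9), , drop = FALSE]
      if (nrow(top) < 3) return(P)
      key <- paste(floor(top[, 1] / cell), floor(top[, 2] / cell))
      idx <- vapply(split(seq_len(nrow(top)), key),
                    function(ii) ii[which.max(top[ii, 3])], integer(1))
      top[idx, , drop = FALSE]
    }
    Et <- apexes(E); Wt <- apexes(W)
    pairs <- expand.grid(i = seq_len(nrow(Et)), j = seq_len(nrow(Wt)))
    pairs <- pairs[abs(Et[pairs$i, 3] - Wt[pairs$j, 3]) < 0.03, , drop = FALSE]
    if (!nrow(pairs))
      pairs <- data.frame(i = sample.int(nrow(Et), ransac_iters, replace = TRUE),
                          j = sample.int(nrow(Wt), ransac_iters, replace = TRUE))
    ## score only points that land inside the east coverage: points
    ## shifted outside it have no legitimate correspondent and would both
    ## dilute the inlier fraction and bias the refinement
    ebb <- apply(E[, 1:2, drop = FALSE], 2, range)
    score <- function(tr, points) {
      shifted <- points
      shifted[, 1] <- shifted[, 1] + tr[1]; shifted[, 2] <- shifted[, 2] + tr[2]
      inb <- shifted[, 1] >= ebb[1, 1] + 0.05 & shifted[, 1] <= ebb[2, 1] - 0.05 &
        shifted[, 2] >= ebb[1, 2] + 0.05 & shifted[, 2] <= ebb[2, 2] - 0.05
      if (sum(inb) < 20) return(list(frac = 0))
      sh <- shifted[inb, , drop = FALSE]
      nn <- nn1_index(E, sh)
      list(frac = mean(nn$dist < inlier_tol), shifted = sh, nn = nn)
    }
    ## two-stage evaluation: every apex pair is screened with a small
    ## scoring subset (the true pair is always among the proposals), the
    ## best few are rescored in full
    Wc <- Ws[seq_len(min(nrow(Ws), 120L)), , drop = FALSE]
    coarse <- vapply(seq_len(nrow(pairs)), function(k) {
      tr <- Et[pairs$i[k], 1:2] - Wt[pairs$j[k], 1:2]
      score(tr, Wc)$frac
    }, numeric(1))
    top <- order(-coarse)[seq_len(min(length(coarse), max(10L, ransac_iters %/% 8)))]
    best <- list(frac = -1, t = c(0, 0))
    for (k in top) {
      tr <- Et[pairs$i[k], 1:2] - Wt[pairs$j[k], 1:2]
      sc <- score(tr, Ws)
      if (sc$frac > best$frac) best <- list(frac = sc$frac, t = tr)
    }
    ## refine with the full inlier set
    tr <- best$t
    for (pass in 1:3) {
      sc <- score(tr, Ws)
      if (sc$frac == 0) break
      ok <- sc$nn$dist < inlier_tol
      if (!any(ok)) break
      delta <- E[sc$nn$index[ok], 1:2, drop = FALSE] -
        sc$shifted[ok, 1:2, drop = FALSE]
      tr <- tr + colMeans(delta)
    }
    frac <- score(tr, Ws)$frac
    if (frac < min_inlier_frac)
      stop_invalid("registration-failed: inlier fraction ", signif(frac, 3),
                   " below floor ", min_inlier_frac)
    list(translation = unname(tr), inlier_frac = frac)
  })
}

#' 2D affine transform (cloud xy to lon/lat)
#'
#' Six coefficients mapping field-frame (x, y) to (lon, lat):
#' lon = a x + b y + c, lat = d x + e y + f. z passes through with a
#' configured scale and offset.
#'
#' @param a,b,c,d,e,f coefficients.
#' @param z_scale,z_offset applied to z on \code{\link{apply_affine}}.
#' @return an object of class \code{affine_transform_2d}.
#' @export
affine_transform_2d <- function(a, b, c, d, e, f, z_scale = 1, z_offset = 0) {
  if (abs(a * e - b * d) == 0) stop_invalid("affine linear part is singular")
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f,
                 z_scale = z_scale, z_offset = z_offset, rms = NA_real_),
            class = "affine_transform_2d")
}

#' Estimate the landmark affine transform
#'
#' Least-squares 6-parameter 2D affine from landmark correspondences
#' between field-frame cloud coordinates (meters) and orthomosaic lon/lat
#' (degrees). At least 3 non-collinear pairs are required; with exactly 3
#' the fit interpolates.
#'
#' @param pairs data.frame with columns \code{x}, \code{y} (cloud meters)
#'   and \code{lon}, \code{lat} (degrees).
#' @return an \code{\link{affine_transform_2d}} with the RMS residual (in
#'   degrees) in field \code{rms}.
#' @export
estimate_landmark_affine <- function(pairs) {
  if (!all(c("x", "y", "lon", "lat") %in% names(pairs)))
    stop_invalid("pairs must have x, y, lon, lat")
  if (nrow(pairs) < 3) stop_invalid("underdetermined: need >= 3 landmark pairs")
  X <- cbind(1, pairs$x, pairs$y)
  if (qr(X)$rank < 3) stop_invalid("underdetermined: landmarks are collinear")
  f1 <- lm.fit(X, pairs$lon); f2 <- lm.fit(X, pairs$lat)
  res <- c(f1$residuals, f2$residuals)
  t <- affine_transform_2d(a = f1$coefficients[2], b = f1$coefficients[3],
                           c = f1$coefficients[1],
                           d = f2$coefficients[2], e = f2$coefficients[3],
                           f = f2$coefficients[1])
  t$rms <- sqrt(mean(res^2))
  t
}

#' Apply a landmark affine to a field-frame cloud
#'
#' @param cloud a field-frame \code{\link{point_cloud}}.
#' @param t an \code{\link{affine_transform_2d}}.
#' @return a geo-frame cloud (xy in degrees, z in meters).
#' @export
apply_affine <- function(cloud, t) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(t, "affine_transform_2d"))
  p <- cloud$points
  lon <- t$a * p[, 1] + t$b * p[, 2] + t$c
  lat <- t$d * p[, 1] + t$e * p[, 2] + t$f
  point_cloud(cbind(lon, lat, p[, 3] * t$z_scale + t$z_offset),
              intensity = cloud$intensity, frame = "geo")
}

#' Invert a landmark affine
#' @param t an \code{\link{affine_transform_2d}}.
#' @return the inverse transform (geo to field).
#' @export
invert_affine <- function(t) {
  det <- t$a * t$e - t$b * t$d
  ia <- t$e / det; ib <- -t$b / det; id <- -t$d / det; ie <- t$a / det
  affine_transform_2d(a = ia, b = ib, c = -(ia * t$c + ib * t$f),
                      d = id, e = ie, f = -(id * t$c + ie * t$f),
                      z_scale = 1 / t$z_scale,
                      z_offset = -t$z_offset / t$z_scale)
}

#' Clip per-plant point-cloud fragments from geo tiles
#'
#' For each detection, gathers all tile points inside the detection's
#' UTM bounding box expanded by \code{pad} meters on every side. Fragments
#' are returned in a local meter frame centered on the detection box
#' center (x east, y north), keyed by (plant id, tile id).
#'
#' @param tiles named list of geo-frame \code{\link{point_cloud}} tiles.
#' @param detections detection records (from
#'   \code{\link{detections_to_geo}}), optionally with a \code{plant_id}
#'   column used as the fragment key.
#' @param pad padding in meters (>= 0).
#' @return list of fragments; each has \code{cloud} (local-frame
#'   \code{point_cloud} or NULL), \code{plant_id}, \code{tile},
#'   \code{center_lon/center_lat}, \code{empty} flag.
#' @export
clip_plants <- function(tiles, detections, pad = 0.05) {
  if (pad < 0) stop_invalid("pad must be >= 0")
  ids <- if ("plant_id" %in% names(detections)) detections$plant_id
         else sprintf("det%04d", seq_len(nrow(detections)))
  ## project each tile once
  zone <- utm_zone_from_lon(mean(detections$center_lon))
  tiles_utm <- lapply(tiles, function(tl) {
    stopifnot(inherits(tl, "point_cloud"))
    u <- geo_to_utm(tl$points[, 1], tl$points[, 2], zone = zone)
    cbind(e = u$easting, n = u$northing, z = tl$points[, 3])
  })
  out <- list()
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    cu <- geo_to_utm(c(d$nw_lon, d$se_lon), c(d$nw_lat, d$se_lat), zone = zone)
    e0 <- min(cu$easting) - pad; e1 <- max(cu$easting) + pad
    n0 <- min(cu$northing) - pad; n1 <- max(cu$northing) + pad
    ce <- mean(cu$easting); cn <- mean(cu$northing)
    for (tn in names(tiles_utm)) {
      tp <- tiles_utm[[tn]]
      sel <- tp[, 1] >= e0 & tp[, 1] <= e1 & tp[, 2] >= n0 & tp[, 2] <= n1
      frag <- if (any(sel))
        point_cloud(cbind(tp[sel, 1] - ce, tp[sel, 2] - cn, tp[sel, 3]),
                    frame = "field")
      else NULL
      out[[paste(ids[i], tn, sep = "|")]] <-
        list(cloud = frag, plant_id = ids[i], tile = tn,
             center_lon = d$center_lon, center_lat = d$center_lat,
             empty = is.null(frag))
    }
  }
  out
}

## Kabsch: rigid (R, t) minimizing ||A - (R B + t)||_F
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(B, 2, cb)) %*% sweep(A, 2, ca)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(ca - R %*% cb))
}

#' Merge two cloud fragments with point-to-point ICP
#'
#' Iteratively matches each point of \code{b} to its nearest neighbor in
#' \code{a} (correspondences beyond \code{max_corr} dropped), estimates
#' the rigid transform by the Kabsch algorithm, and composes updates
#' until the mean correspondence error changes by less than \code{tol}
#' (relative) or \code{max_iter} is reached. The merged cloud is
#' \code{a} plus transformed \code{b}.
#'
#' @param a,b \code{\link{point_cloud}} fragments in the same frame.
#' @param max_corr maximum correspondence distance in meters.
#' @param max_iter iteration cap.
#' @param tol relative objective-change termination tolerance.
#' @param min_fitness merge rejected (fragments kept separate, warning)
#'   below this final inlier fraction.
#' @return list with \code{merged} (\code{point_cloud} or NULL when
#'   rejected), \code{R}, \code{t}, \code{fitness}, \code{error_trace},
#'   \code{accepted}.
#' @export
icp_merge <- function(a, b, max_corr = 0.05, max_iter = 50, tol = 1e-8,
                      min_fitness = 0.3) {
  stopifnot(inherits(a, "point_cloud"), inherits(b, "point_cloud"))
  A <- a$points; B <- b$points
  R <- diag(3); tvec <- c(0, 0, 0)
  trace <- numeric(0); prev <- Inf
  for (it in seq_len(max_iter)) {
    Bt <- sweep(B %*% t(R), 2, tvec, "+")
    nn <- nn1_index(A, Bt)
    ok <- nn$dist <= max_corr
    if (sum(ok) < 3) break
    err <- mean(nn$dist[ok])
    ## inlier churn can propose a worse state: stop at the last best
    if (is.finite(prev) && err > prev) break
    trace <- c(trace, err)
    upd <- kabsch(A[nn$index[ok], , drop = FALSE], Bt[ok, , drop = FALSE])
    R <- upd$R %*% R
    tvec <- as.numeric(upd$R %*% tvec) + upd$t
    if (is.finite(prev) && abs(prev - err) <= tol * max(prev, .Machine$double.eps)) break
    prev <- err
  }
  Bt <- sweep(B %*% t(R), 2, tvec, "+")
  nn <- nn1_index(A, Bt)
  fitness <- mean(nn$dist <= max_corr)
  if (fitness < min_fitness) {
    warning("icp_merge: fitness ", signif(fitness, 3), " below floor; merge rejected")
    return(list(merged = NULL, R = R, t = tvec, fitness = fitness,
                error_trace = trace, accepted = FALSE))
  }
  list(merged = point_cloud(rbind(A, Bt), frame = a$frame),
       R = R, t = tvec, fitness = fitness, error_trace = trace,
       accepted = TRUE)
}

#' Read landmark pairs from JSON
#'
#' The interactive co-registration step is replaced by a file contract:
#' a JSON array of records with \code{cloud_xy} (meters) and
#' \code{geo_lonlat} (degrees).
#'
#' @param path JSON file path.
#' @return data.frame with columns \code{x}, \code{y}, \code{lon},
#'   \code{lat}.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = FALSE)
  pick <- function(field, k)
    vapply(lm[[field]], function(v) as.numeric(v[[k]]), numeric(1))
  data.frame(x = pick("cloud_xy", 1), y = pick("cloud_xy", 2),
             lon = pick("geo_lonlat", 1), lat = pick("geo_lonlat", 2))
}

#' Write landmark pairs to JSON
#' @param pairs data.frame with \code{x}, \code{y}, \code{lon}, \code{lat}.
#' @param path output path.
#' @export
write_landmarks <- function(pairs, path) {
  jsonlite::write_json(
    list(cloud_xy = lapply(seq_len(nrow(pairs)), function(i) c(pairs$x[i], pairs$y[i])),
         geo_lonlat = lapply(seq_len(nrow(pairs)), function(i) c(pairs$lon[i], pairs$lat[i]))),
    path, digits = NA)
  invisible(path)
}
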