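#' Volume of the 3D convex hull of a point set
#'
#' Incremental convex hull (beneath-beyond with vectorized visibility
#' tests). Returns NA for fewer than 4 points or a degenerate (coplanar)
#' set.
#'
#' @param pts N x 3 numeric matrix.
#' @return hull volume, or NA when undefined.
#' @export
convex_hull_volume <- function(pts) {
  P <- unique(as.matrix(pts))
  n <- nrow(P)
  if (n < 4) return(NA_real_)
  diam <- max(apply(P, 2, function(v) diff(range(v))))
  if (diam == 0) return(NA_real_)
  eps <- 1e-10 * diam
  ## initial simplex: spread points
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2); i2 <- which.max(d1)
  v <- P[i2, ] - P[i1, ]
  w <- sweep(P, 2, P[i1, ])
  cr <- cbind(w[, 2] * v[3] - w[, 3] * v[2],
              w[, 3] * v[1] - w[, 1] * v[3],
              w[, 1] * v[2] - w[, 2] * v[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- cr[i3, ]
  if (sum(nrm^2) < eps^2) return(NA_real_)
  h <- abs(w %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < eps) return(NA_real_)  # coplanar
  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(P[simplex, ])
  faces <- rbind(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                 simplex[c(1, 3, 4)], simplex[c(2, 3, 4)])
  face_geom <- function(f) {
    a <- P[f[1], ]; b <- P[f[2], ]; cc <- P[f[3], ]
    nv <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
            (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
            (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    d <- sum(nv * a)
    if (sum(nv * interior) > d) { nv <- -nv; d <- -d }  # outward
    c(nv, d)
  }
  G <- t(apply(faces, 1, face_geom))
  for (p in setdiff(seq_len(n), simplex)) {
    vis <- as.numeric(G[, 1:3, drop = FALSE] %*% P[p, ]) - G[, 4] > eps
    if (!any(vis)) next
    ## horizon: edges of visible faces not shared by two visible faces
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2), drop = FALSE], vf[, c(2, 3), drop = FALSE],
                   vf[, c(1, 3), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    tab <- table(key)
    horizon <- edges[key %in% names(tab)[tab == 1L], , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    G <- G[!vis, , drop = FALSE]
    if (nrow(horizon)) {
      newf <- cbind(horizon, p)
      newg <- t(apply(newf, 1, face_geom))
      faces <- rbind(faces, newf)
      G <- rbind(G, newg)
    }
  }
  ## volume as sum of tetrahedra from the interior point (outward faces)
  vol <- 0
  for (i in seq_len(nrow(faces))) {
    a <- P[faces[i, 1], ] - interior
    b <- P[faces[i, 2], ] - interior
    cc <- P[faces[i, 3], ] - interior
    vol <- vol + abs(a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                     a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                     a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  unname(vol)
}

#' Morphometric traits of a focal plant cloud
#'
#' Plant height PH = Zmax - Zmin; AABV = product of the axis-aligned
#' extents; OBV = extent product in the principal-component frame (a
#' deterministic approximation of the minimal oriented box); CHV = convex
#' hull volume (NA for degenerate clouds); NP = point count.
#'
#' @param cloud a focal \code{\link{point_cloud}}.
#' @return an object of class \code{plant_traits_3d}: list with \code{ph},
#'   \code{aabv}, \code{obv}, \code{chv}, \code{np}.
#' @export
point_cloud_traits <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  if (nrow(P) < 1) stop_invalid("empty cloud")
  ext <- apply(P, 2, function(v) diff(range(v)))
  ph <- ext[3]
  aabv <- prod(ext)
  obv <- if (nrow(P) >= 3) {
    ## eigen on the covariance keeps the identity frame for axis-aligned
    ## (or covariance-degenerate) clouds, making OBV deterministic
    ev <- eigen(stats::cov(P), symmetric = TRUE)
    rot <- sweep(P, 2, colMeans(P)) %*% ev$vectors
    prod(apply(rot, 2, function(v) diff(range(v))))
  } else 0
  chv <- convex_hull_volume(P)
  structure(list(ph = unname(ph), aabv = unname(aabv), obv = unname(obv),
                 chv = chv, np = nrow(P)),
            class = "plant_traits_3d")
}

#' @export
print.plant_traits_3d <- function(x, ...) {
  cat(sprintf("<plant_traits_3d> PH=%.4f m AABV=%.3e OBV=%.3e CHV=%.3e NP=%d\n",
              x$ph, x$aabv, x$obv, x$chv %||% NA_real_, x$np))
  invisible(x)
}
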