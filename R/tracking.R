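## Sequential multimodal clustering: per-date detections -> individual
## plant time series, merged-plant ("double") flagging, and fusion of
## RGB, thermal, PSII and 3D traits into one table.

#' Cluster detections into individual-plant time series
#'
#' Agglomerative (hierarchical) clustering of detection centers on raw
#' (lon, lat) degrees, cut at a distance threshold (default 6e-7). Marked
#' outlier points — field locations where two plants merged into one
#' apparent canopy — are clustered together with the detections, and any
#' cluster containing one is flagged \code{is_double}. Each cluster gets
#' a unique plant id "genotype_clusterNumber". A cluster can hold at most
#' one detection per (date, sensor); surplus same-date members (the ones
#' farther from the cluster centroid) are split off and re-clustered.
#'
#' @param detections detection records (all dates) with
#'   \code{center_lon}, \code{center_lat}, \code{date}, \code{sensor},
#'   \code{plot_id} columns.
#' @param outliers optional data.frame of marked outlier points with
#'   \code{lon}, \code{lat}.
#' @param threshold clustering distance threshold in degrees.
#' @param linkage hclust linkage ("average" by default).
#' @param plots optional \code{\link{plot_map}} supplying genotypes for
#'   plant ids.
#' @return an object of class \code{plant_clusters}: list with
#'   \code{members} (the detections plus \code{plant_id}) and
#'   \code{clusters} (per-cluster centroid, size, \code{is_double}).
#' @export
cluster_detections <- function(detections, outliers = NULL, threshold = 6e-7,
                               linkage = "average", plots = NULL) {
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  nd <- nrow(detections)
  if (nd == 0) {
    return(structure(list(members = cbind(detections,
                                          plant_id = character(0)),
                          clusters = data.frame(plant_id = character(),
                                                centroid_lon = numeric(),
                                                centroid_lat = numeric(),
                                                n_members = integer(),
                                                is_double = logical())),
                     class = "plant_clusters"))
  }
  no <- if (is.null(outliers)) 0L else nrow(outliers)
  xy <- rbind(cbind(detections$center_lon, detections$center_lat),
              if (no) cbind(outliers$lon, outliers$lat))
  is_out <- c(rep(FALSE, nd), rep(TRUE, no))
  grp <- if (nrow(xy) == 1) 1L else {
    hc <- hclust(dist(xy), method = linkage)
    cutree(hc, h = threshold)
  }
  ## split surplus same-(date, sensor) members off into new groups
  repeat {
    moved <- FALSE
    for (g in unique(grp[!is_out])) {
      m <- which(grp == g & !is_out)
      if (length(m) < 2) next
      key <- paste(detections$date[m], detections$sensor[m])
      if (!anyDuplicated(key)) next
      ctr <- colMeans(xy[m, , drop = FALSE])
      d <- sqrt(rowSums(sweep(xy[m, , drop = FALSE], 2, ctr)^2))
      drop_idx <- unlist(lapply(split(seq_along(m), key), function(ii) {
        if (length(ii) < 2) return(integer(0))
        ii[-which.min(d[ii])]
      }))
      ## each spare becomes its own cluster (no two spares should be
      ## lumped together just for having been split from the same group)
      grp[m[drop_idx]] <- max(grp) + seq_along(drop_idx)
      moved <- TRUE
    }
    if (!moved) break
  }
  det_grp <- grp[!is_out]
  keep <- sort(unique(det_grp))
  ## deterministic numbering: clusters ordered by centroid (lat desc, lon)
  cent <- t(vapply(keep, function(g)
    colMeans(xy[grp == g & !is_out, , drop = FALSE]), numeric(2)))
  ord <- order(-cent[, 2], cent[, 1])
  keep <- keep[ord]; cent <- cent[ord, , drop = FALSE]
  geno_of <- function(g) {
    if (is.null(plots)) return("unknown")
    pid <- modal_value(detections$plot_id[det_grp == g])
    gn <- plots$plots$genotype[match(pid, plots$plots$plot_id)]
    if (is.na(gn)) "unknown" else gn
  }
  cl <- data.frame(
    plant_id = vapply(seq_along(keep), function(i)
      paste0(geno_of(keep[i]), "_", i), character(1)),
    centroid_lon = cent[, 1], centroid_lat = cent[, 2],
    n_members = vapply(keep, function(g) sum(det_grp == g), integer(1)),
    is_double = vapply(keep, function(g) any(grp[is_out] == g), logical(1)),
    stringsAsFactors = FALSE)
  members <- detections
  members$plant_id <- cl$plant_id[match(det_grp, keep)]
  structure(list(members = members, clusters = cl), class = "plant_clusters")
}

#' @export
print.plant_clusters <- function(x, ...) {
  cat(sprintf("<plant_clusters> %d clusters (%d double) over %d detections\n",
              nrow(x$clusters), sum(x$clusters$is_double), nrow(x$members)))
  invisible(x)
}

#' Merge thermal detections into RGB plant clusters
#'
#' Each thermal detection joins the RGB cluster whose centroid is nearest
#' within the threshold, inheriting its plant id; unmatched thermal
#' detections are reported separately.
#'
#' @param clusters a \code{\link{plant_clusters}} from RGB detections.
#' @param thermal_detections thermal detection records (same CRS).
#' @param threshold maximum centroid distance in degrees.
#' @return list with the updated \code{clusters} (thermal rows appended
#'   to \code{members}) and \code{unmatched} thermal rows.
#' @export
merge_rgb_thermal <- function(clusters, thermal_detections, threshold = 6e-7) {
  stopifnot(inherits(clusters, "plant_clusters"))
  nt <- nrow(thermal_detections)
  if (nt == 0) return(list(clusters = clusters,
                           unmatched = thermal_detections))
  cent <- as.matrix(clusters$clusters[, c("centroid_lon", "centroid_lat")])
  q <- cbind(thermal_detections$center_lon, thermal_detections$center_lat)
  nn <- nn1_index(cbind(cent, 0), cbind(q, 0))
  matched <- nn$dist <= threshold
  tt <- thermal_detections
  tt$plant_id <- ifelse(matched, clusters$clusters$plant_id[nn$index], NA)
  mem <- merge_rows(clusters$members, tt[matched, , drop = FALSE])
  clusters$members <- mem
  list(clusters = clusters, unmatched = tt[!matched, , drop = FALSE])
}

## rbind data.frames with differing columns, filling with NA
merge_rows <- function(a, b) {
  if (!nrow(b)) return(a)
  for (k in setdiff(names(a), names(b))) b[[k]] <- NA
  for (k in setdiff(names(b), names(a))) a[[k]] <- NA
  rbind(a, b[names(a)])
}

#' Fuse modalities into the multimodal trait table
#'
#' One record per (plant_id, date) present in any modality: RGB bounding
#' area, thermal MEDT/MEAT, 3D morphometrics joined by (plant_id, date),
#' and plot-level PSII traits broadcast to every plant of the plot by
#' (plot_id, date). Missing modalities stay NA. 3D rows whose plant_id is
#' unknown to the clusters are kept and flagged \code{orphan} with a
#' warning.
#'
#' @param clusters a \code{\link{plant_clusters}} (after any thermal
#'   merge).
#' @param psii_plot_table data.frame keyed by (plot_id, date) with
#'   \code{f0}, \code{fm}, \code{fv}, \code{fvfm}; may be NULL.
#' @param traits3d_table data.frame keyed by (plant_id, date) with
#'   \code{ph}, \code{aabv}, \code{obv}, \code{chv}, \code{np}; may be
#'   NULL.
#' @param plots optional \code{\link{plot_map}} (adds genotype and
#'   treatment columns).
#' @return data.frame, one row per (plant_id, date).
#' @export
join_modalities <- function(clusters, psii_plot_table = NULL,
                            traits3d_table = NULL, plots = NULL) {
  stopifnot(inherits(clusters, "plant_clusters"))
  mem <- clusters$members
  keys <- unique(rbind(
    data.frame(plant_id = mem$plant_id, date = mem$date,
               stringsAsFactors = FALSE),
    if (!is.null(traits3d_table) && nrow(traits3d_table))
      data.frame(plant_id = traits3d_table$plant_id,
                 date = traits3d_table$date, stringsAsFactors = FALSE)))
  known <- keys$plant_id %in% clusters$clusters$plant_id
  if (any(!known)) warning("orphan plant_id(s) in 3D traits: ",
                           paste(unique(keys$plant_id[!known]), collapse = ", "))
  out <- keys
  out$orphan <- !known
  ci <- match(out$plant_id, clusters$clusters$plant_id)
  out$is_double <- clusters$clusters$is_double[ci]
  out$center_lon <- clusters$clusters$centroid_lon[ci]
  out$center_lat <- clusters$clusters$centroid_lat[ci]
  ## RGB bounding area + plot
  rgb <- mem[mem$sensor == "rgb", , drop = FALSE]
  ri <- match(paste(out$plant_id, out$date),
              paste(rgb$plant_id, rgb$date))
  out$plot_id <- rgb$plot_id[ri]
  out$bounding_area <- rgb$bounding_area[ri]
  ## fall back to any member's plot for dates without RGB
  miss <- is.na(out$plot_id)
  if (any(miss)) {
    anyp <- vapply(out$plant_id[miss], function(p) {
      v <- modal_value(mem$plot_id[mem$plant_id == p])
      if (length(v) != 1L || is.na(v)) NA_character_ else as.character(v)
    }, character(1))
    out$plot_id[miss] <- anyp
  }
  ## thermal
  for (k in c("medt", "meat", "roi_temp")) {
    if (!k %in% names(mem)) next
    th <- mem[mem$sensor == "thermal", , drop = FALSE]
    ti <- match(paste(out$plant_id, out$date), paste(th$plant_id, th$date))
    out[[k]] <- th[[k]][ti]
  }
  ## 3D
  if (!is.null(traits3d_table) && nrow(traits3d_table)) {
    di <- match(paste(out$plant_id, out$date),
                paste(traits3d_table$plant_id, traits3d_table$date))
    for (k in intersect(c("ph", "aabv", "obv", "chv", "np"),
                        names(traits3d_table)))
      out[[k]] <- traits3d_table[[k]][di]
  }
  ## PSII broadcast by plot
  if (!is.null(psii_plot_table) && nrow(psii_plot_table)) {
    pi <- match(paste(out$plot_id, out$date),
                paste(psii_plot_table$plot_id, psii_plot_table$date))
    for (k in intersect(c("f0", "fm", "fv", "fvfm"), names(psii_plot_table)))
      out[[k]] <- psii_plot_table[[k]][pi]
  }
  if (!is.null(plots)) {
    mi <- match(out$plot_id, plots$plots$plot_id)
    out$genotype <- plots$plots$genotype[mi]
    out$treatment <- plots$plots$treatment[mi]
  }
  out[order(out$plant_id, out$date), , drop = FALSE]
}

#' Evaluate double-plant association against field marks
#'
#' Confusion over assessed plant identifications: TP = field-marked and
#' flagged double by the clustering; FN = marked, not flagged; FP =
#' unmarked, flagged; TN = unmarked, not flagged. Recall, precision and
#' F1 follow the detection-metric formulas, plus accuracy =
#' (TP+TN)/total; an empty marked class leaves recall absent (NA).
#'
#' @param assessed data.frame with logical columns \code{marked} (field
#'   ground truth) and \code{flagged} (clustering verdict); or a
#'   \code{\link{plant_clusters}} whose \code{is_double} is used as
#'   \code{flagged} together with \code{marked_outliers}.
#' @param marked_outliers optional data.frame of outlier points
#'   (\code{lon}, \code{lat}) used to derive \code{marked} by proximity
#'   when \code{assessed} is a cluster object.
#' @param tol proximity tolerance in degrees for deriving \code{marked}.
#' @return list with \code{confusion} and \code{recall}, \code{precision},
#'   \code{f1}, \code{accuracy}.
#' @export
evaluate_association <- function(assessed, marked_outliers = NULL,
                                 tol = 6e-7) {
  if (inherits(assessed, "plant_clusters")) {
    cl <- assessed$clusters
    marked <- rep(FALSE, nrow(cl))
    if (!is.null(marked_outliers) && nrow(marked_outliers)) {
      ## each field mark identifies one canopy: its nearest cluster
      cent <- cbind(cl$centroid_lon, cl$centroid_lat, 0)
      op <- cbind(marked_outliers$lon, marked_outliers$lat, 0)
      nn <- nn1_index(cent, op)
      marked[nn$index[nn$dist <= tol]] <- TRUE
    }
    assessed <- data.frame(marked = marked, flagged = cl$is_double)
  }
  tp <- sum(assessed$marked & assessed$flagged)
  fn <- sum(assessed$marked & !assessed$flagged)
  fp <- sum(!assessed$marked & assessed$flagged)
  tn <- sum(!assessed$marked & !assessed$flagged)
  conf <- detection_confusion(tp = tp, fp = fp, fn = fn, tn = tn)
  m <- detection_metrics(conf)
  list(confusion = conf, recall = m$recall, precision = m$precision,
       f1 = m$f1, accuracy = (tp + tn) / max(1, tp + fp + fn + tn))
}
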