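## Stage implementations behind the pipeline runner. Each stage maps an
## input unit (one raster, one 101-frame stack, one scan pair, the whole
## season for joins) to files under the output root; all communication
## between stages goes through files, so stages can run in isolation.

stage_units <- function(op, module, ctx) {
  inroot <- ctx$input_root
  switch(op,
    simulate = {
      p <- module$parameters %||% list()
      dates <- p$dates %||% formals(sim_config)$dates
      c("field", eval(dates))
    },
    rgb = ,
    thermal = ,
    psii = ,
    cloud = {
      pat <- module$inputs %||% switch(op, rgb = "rgb_*.tif",
                                       thermal = "thermal_*.tif",
                                       psii = "psii/*/*",
                                       cloud = "clouds/*_east.ply")
      found <- Sys.glob(file.path(inroot, pat))
      sub(paste0("^", inroot, "/?"), "", found)
    },
    track = ,
    fuse = ,
    evaluate = "season",
    repeatability = {
      found <- Sys.glob(file.path(inroot, module$inputs %||% "traits_*.csv"))
      sub(paste0("^", inroot, "/?"), "", found)
    },
    stop_invalid("unknown operation: ", op))
}

stage_run <- function(op, unit, ctx, params, seed) {
  switch(op,
    simulate = stage_simulate(unit, ctx, params),
    rgb = stage_rgb(unit, ctx, params),
    thermal = stage_thermal(unit, ctx, params, seed),
    psii = stage_psii(unit, ctx, params),
    track = stage_track(unit, ctx, params),
    cloud = stage_cloud(unit, ctx, params, seed),
    fuse = stage_fuse(unit, ctx, params),
    evaluate = stage_evaluate(unit, ctx, params),
    repeatability = stage_repeatability(unit, ctx, params),
    stop_invalid("unknown operation: ", op))
}

sim_from_params <- function(ctx, params) {
  params$seed <- params$seed %||% derive_seed(ctx$seed, "simulate", "scene")
  do.call(sim_config, params)
}

stage_simulate <- function(unit, ctx, params) {
  cfg <- sim_from_params(ctx, params)
  truth <- generate_field(cfg)
  root <- ctx$input_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (unit == "field") {
    write_plot_geojson(truth$plots, file.path(root, "plots.geojson"))
    write_points_geojson(truth$outliers, file.path(root, "outliers.geojson"))
    write_landmarks(scene_landmarks(truth), file.path(root, "landmarks.json"))
    jsonlite::write_json(list(gain = cfg$thermal_gain,
                              offset = cfg$thermal_offset),
                         file.path(root, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    gtt <- ground_truth_tables(truth)
    dir.create(file.path(root, "truth"), showWarnings = FALSE)
    write.csv(gtt$plants, file.path(root, "truth", "plants.csv"),
              row.names = FALSE)
    write.csv(gtt$psii, file.path(root, "truth", "psii.csv"),
              row.names = FALSE)
    return(invisible(NULL))
  }
  date <- unit
  r <- render_modalities(truth, date)
  write_raster(r$rgb$raster, file.path(root, sprintf("rgb_%s.tif", date)))
  write.csv(truth_boxes_geo(r$rgb$truth_boxes, r$rgb$raster$gt),
            file.path(root, "truth", sprintf("boxes_rgb_%s.csv", date)),
            row.names = FALSE)
  write_raster(r$thermal$raster, file.path(root, sprintf("thermal_%s.tif", date)))
  write.csv(truth_boxes_geo(r$thermal$truth_boxes, r$thermal$raster$gt),
            file.path(root, "truth", sprintf("boxes_thermal_%s.csv", date)),
            row.names = FALSE)
  for (pid in names(r$psii))
    write_psii_stack(r$psii[[pid]]$stack,
                     file.path(root, "psii", date, pid), date = date)
  if (!is.null(r$cloud)) {
    dir.create(file.path(root, "clouds"), showWarnings = FALSE)
    write_ply(r$cloud$east, file.path(root, "clouds", sprintf("%s_east.ply", date)))
    write_ply(r$cloud$west, file.path(root, "clouds", sprintf("%s_west.ply", date)))
  }
  invisible(NULL)
}

## truth pixel boxes -> geographic corner table for evaluation
truth_boxes_geo <- function(boxes, gt) {
  if (is.null(boxes) || !nrow(boxes)) {
    return(data.frame(true_id = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(), y_max = numeric()))
  }
  nw <- pixel_to_geo(gt, boxes$x_min, boxes$y_min)
  se <- pixel_to_geo(gt, boxes$x_max, boxes$y_max)
  data.frame(true_id = boxes$true_id,
             x_min = nw$lon, x_max = se$lon,
             y_min = se$lat, y_max = nw$lat)
}

date_from_unit <- function(unit) {
  m <- regmatches(unit, regexpr("[0-9]{4}-[0-9]{2}-[0-9]{2}", unit))
  if (!length(m)) stop_invalid("cannot parse date from unit: ", unit)
  m
}

stage_rgb <- function(unit, ctx, params) {
  date <- date_from_unit(unit)
  r <- read_raster(file.path(ctx$input_root, unit))
  plots <- read_plot_geojson(file.path(ctx$input_root, "plots.geojson"))
  clips <- clip_raster_to_plots(r, plots)
  out <- list()
  for (pid in names(clips)) {
    boxes <- detect_plants_reference(clips[[pid]],
                                     min_area_px = params$min_area_px %||% 15,
                                     intensity_threshold = params$intensity_threshold %||% "otsu")
    out[[pid]] <- detections_to_geo(boxes, clips[[pid]]$gt, date, "rgb", pid)
  }
  det <- do.call(rbind, out)
  dir.create(file.path(ctx$output_root, "rgb"), recursive = TRUE,
             showWarnings = FALSE)
  write_detections(det,
    csv_path = file.path(ctx$output_root, "rgb", sprintf("detections_%s.csv", date)),
    geojson_path = file.path(ctx$output_root, "rgb", sprintf("centers_%s.geojson", date)))
  invisible(det)
}

stage_thermal <- function(unit, ctx, params, seed) {
  date <- date_from_unit(unit)
  r <- read_raster(file.path(ctx$input_root, unit))
  cal_j <- jsonlite::read_json(file.path(ctx$input_root, "calibration.json"),
                               simplifyVector = TRUE)
  cal <- thermal_calibration(cal_j$gain, cal_j$offset)
  celsius <- pf_raster(calibrate_dn(r$values, cal), r$gt, nodata = r$nodata)
  plots <- read_plot_geojson(file.path(ctx$input_root, "plots.geojson"))
  clips <- clip_raster_to_plots(celsius, plots)
  out <- list()
  for (pid in names(clips)) {
    clip <- clips[[pid]]
    ## canopies are colder than daytime soil: detect on the negated image
    neg <- pf_raster(-clip$values, clip$gt, nodata = clip$nodata)
    boxes <- detect_plants_reference(neg,
                                     min_area_px = params$min_area_px %||% 5,
                                     intensity_threshold = params$intensity_threshold %||% "otsu")
    det <- detections_to_geo(boxes, clip$gt, date, "thermal", pid)
    if (!nrow(det)) next
    ct <- lapply(seq_len(nrow(det)), function(i) {
      sub <- clip$values[(det$y_min[i] + 1):det$y_max[i],
                         (det$x_min[i] + 1):det$x_max[i], 1]
      tryCatch({
        x <- extract_canopy_temperature(sub,
               roi_size = params$roi_size %||% 10,
               seed = derive_seed(seed, pid, i))
        data.frame(medt = x$medt, meat = x$meat, roi_temp = x$roi_temp,
                   n_canopy_pixels = x$n_canopy_pixels,
                   degenerate = x$degenerate)
      }, error = function(e)
        data.frame(medt = NA_real_, meat = NA_real_, roi_temp = NA_real_,
                   n_canopy_pixels = 0L, degenerate = NA))
    })
    out[[pid]] <- cbind(det, do.call(rbind, ct))
  }
  det <- do.call(rbind, out)
  dir.create(file.path(ctx$output_root, "thermal"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(det, file.path(ctx$output_root, "thermal",
                           sprintf("detections_%s.csv", date)),
            row.names = FALSE)
  invisible(det)
}

stage_psii <- function(unit, ctx, params) {
  date <- date_from_unit(unit)
  plot_id <- basename(unit)
  stack <- read_psii_stack(file.path(ctx$input_root, unit))
  thr <- if (!is.null(params$thresholds))
    contribution_thresholds(as.numeric(params$thresholds)) else NULL
  maps <- compute_f0_fm(stack, thr)
  tr <- fluorescence_traits(maps$f0, maps$fm, maps$bin)
  row <- data.frame(plot_id = plot_id, date = date, f0 = tr$f0, fm = tr$fm,
                    fv = tr$fv, fvfm = tr$fvfm, n_pixels = tr$n_pixels)
  dir.create(file.path(ctx$output_root, "psii"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(row, file.path(ctx$output_root, "psii",
                           sprintf("%s_%s.csv", date, plot_id)),
            row.names = FALSE)
  invisible(row)
}

read_csvs <- function(paths) {
  if (!length(paths)) return(NULL)
  do.call(rbind, lapply(paths, read.csv, stringsAsFactors = FALSE,
                        colClasses = NA))
}

stage_track <- function(unit, ctx, params) {
  rgb <- read_csvs(Sys.glob(file.path(ctx$output_root, "rgb", "detections_*.csv")))
  if (is.null(rgb)) stop_invalid("track: no RGB detections found")
  plots <- read_plot_geojson(file.path(ctx$input_root, "plots.geojson"))
  out_path <- file.path(ctx$input_root, "outliers.geojson")
  outliers <- if (file.exists(out_path)) read_points_geojson(out_path) else NULL
  if (!is.null(outliers) && !nrow(outliers)) outliers <- NULL
  cl <- cluster_detections(rgb, outliers = outliers,
                           threshold = params$threshold %||% 6e-7,
                           linkage = params$linkage %||% "average",
                           plots = plots)
  thermal <- read_csvs(Sys.glob(file.path(ctx$output_root, "thermal",
                                          "detections_*.csv")))
  unmatched <- NULL
  if (!is.null(thermal)) {
    mg <- merge_rgb_thermal(cl, thermal,
                            threshold = params$threshold %||% 6e-7)
    cl <- mg$clusters
    unmatched <- mg$unmatched
  }
  dir.create(file.path(ctx$output_root, "track"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(cl$members, file.path(ctx$output_root, "track", "members.csv"),
            row.names = FALSE)
  write.csv(cl$clusters, file.path(ctx$output_root, "track", "clusters.csv"),
            row.names = FALSE)
  if (!is.null(unmatched))
    write.csv(unmatched, file.path(ctx$output_root, "track",
                                   "unmatched_thermal.csv"), row.names = FALSE)
  invisible(cl)
}

read_clusters <- function(ctx) {
  members <- read.csv(file.path(ctx$output_root, "track", "members.csv"),
                      stringsAsFactors = FALSE)
  clusters <- read.csv(file.path(ctx$output_root, "track", "clusters.csv"),
                       stringsAsFactors = FALSE)
  structure(list(members = members, clusters = clusters),
            class = "plant_clusters")
}

stage_cloud <- function(unit, ctx, params, seed) {
  date <- date_from_unit(unit)
  east <- read_ply(file.path(ctx$input_root, unit))
  west <- read_ply(file.path(ctx$input_root, sub("_east\\.ply$", "_west.ply", unit)))
  al <- align_dual_scans(east, west,
                         ransac_iters = params$ransac_iters %||% 150,
                         inlier_tol = params$inlier_tol %||% 0.01,
                         seed = derive_seed(seed, "align"))
  west$points[, 1] <- west$points[, 1] + al$translation[1]
  west$points[, 2] <- west$points[, 2] + al$translation[2]
  aff <- estimate_landmark_affine(
    read_landmarks(file.path(ctx$input_root, "landmarks.json")))
  tiles <- list(east = apply_affine(east, aff), west = apply_affine(west, aff))
  mem <- read_clusters(ctx)$members
  det <- mem[mem$sensor == "rgb" & mem$date == date, , drop = FALSE]
  if (!nrow(det)) stop_invalid("cloud: no tracked detections for ", date)
  frags <- clip_plants(tiles, det, pad = params$pad %||% 0.1)
  rows <- list()
  for (pid in unique(det$plant_id)) {
    fe <- frags[[paste(pid, "east", sep = "|")]]
    fw <- frags[[paste(pid, "west", sep = "|")]]
    row <- tryCatch({
      merged <- if (!fe$empty && !fw$empty) {
        mg <- suppressWarnings(
          icp_merge(fe$cloud, fw$cloud,
                    max_corr = params$max_corr %||% 0.05))
        if (mg$accepted) mg$merged else fe$cloud
      } else if (!fe$empty) fe$cloud
        else if (!fw$empty) fw$cloud
        else stop_invalid("no points for plant ", pid)
      seg <- segment_plant_soil(merged,
               plane_iters = params$plane_iters %||% 100,
               dist_thresh = params$dist_thresh %||% 0.004,
               margin = params$margin %||% 0.005,
               seed = derive_seed(seed, "seg", pid))
      plant <- point_cloud(merged$points[seg$labels == "plant", , drop = FALSE],
                           frame = merged$frame)
      focal <- remove_neighbors_dbscan(plant,
                 eps = params$eps %||% 0.04,
                 min_pts = params$min_pts %||% 8)
      tr <- point_cloud_traits(focal)
      data.frame(plant_id = pid, date = date, ph = tr$ph, aabv = tr$aabv,
                 obv = tr$obv, chv = tr$chv %||% NA_real_, np = tr$np,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(plant_id = pid, date = date, ph = NA_real_,
                 aabv = NA_real_, obv = NA_real_, chv = NA_real_,
                 np = NA_integer_, stringsAsFactors = FALSE))
    rows[[pid]] <- row
  }
  out <- do.call(rbind, rows)
  dir.create(file.path(ctx$output_root, "cloud"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(out, file.path(ctx$output_root, "cloud",
                           sprintf("traits3d_%s.csv", date)),
            row.names = FALSE)
  invisible(out)
}

stage_fuse <- function(unit, ctx, params) {
  cl <- read_clusters(ctx)
  psii <- read_csvs(Sys.glob(file.path(ctx$output_root, "psii", "*.csv")))
  t3d <- read_csvs(Sys.glob(file.path(ctx$output_root, "cloud", "traits3d_*.csv")))
  plots <- read_plot_geojson(file.path(ctx$input_root, "plots.geojson"))
  fused <- suppressWarnings(
    join_modalities(cl, psii_plot_table = psii, traits3d_table = t3d,
                    plots = plots))
  write.csv(fused, file.path(ctx$output_root, "fused.csv"), row.names = FALSE)
  invisible(fused)
}

stage_evaluate <- function(unit, ctx, params) {
  dir.create(file.path(ctx$output_root, "evaluate"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list(); med_rows <- list()
  for (sensor in c("rgb", "thermal")) {
    dets <- Sys.glob(file.path(ctx$output_root, sensor, "detections_*.csv"))
    for (f in dets) {
      date <- date_from_unit(basename(f))
      truth_f <- file.path(ctx$input_root, "truth",
                           sprintf("boxes_%s_%s.csv", sensor, date))
      if (!file.exists(truth_f)) next
      preds <- read.csv(f, stringsAsFactors = FALSE)
      truths <- read.csv(truth_f, stringsAsFactors = FALSE)
      pb <- data.frame(x_min = preds$nw_lon, x_max = preds$se_lon,
                       y_min = preds$se_lat, y_max = preds$nw_lat,
                       date = date)
      mr <- match_detections(pb, truths)
      met <- detection_metrics(mr$confusion)
      rows[[paste(sensor, date)]] <- data.frame(
        sensor = sensor, date = date, tp = mr$confusion$tp,
        fp = mr$confusion$fp, fn = mr$confusion$fn,
        recall = met$recall, precision = met$precision, f1 = met$f1)
      med_rows[[paste(sensor, date)]] <- cbind(sensor = sensor,
                                               median_iou_by_date(mr$matches))
    }
  }
  det_tab <- do.call(rbind, rows)
  if (!is.null(det_tab))
    write.csv(det_tab, file.path(ctx$output_root, "evaluate",
                                 "detection_metrics.csv"), row.names = FALSE)
  if (length(med_rows))
    write.csv(do.call(rbind, med_rows),
              file.path(ctx$output_root, "evaluate", "median_iou.csv"),
              row.names = FALSE)
  ## association of double plants
  out_path <- file.path(ctx$input_root, "outliers.geojson")
  if (file.exists(out_path) &&
      file.exists(file.path(ctx$output_root, "track", "clusters.csv"))) {
    cl <- read_clusters(ctx)
    marked <- read_points_geojson(out_path)
    ev <- evaluate_association(cl, marked_outliers = marked)
    jsonlite::write_json(
      list(tp = ev$confusion$tp, fp = ev$confusion$fp,
           fn = ev$confusion$fn, tn = ev$confusion$tn,
           recall = ev$recall, precision = ev$precision, f1 = ev$f1,
           accuracy = ev$accuracy),
      file.path(ctx$output_root, "evaluate", "association.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(det_tab)
}

stage_repeatability <- function(unit, ctx, params) {
  df <- read.csv(file.path(ctx$input_root, unit), stringsAsFactors = FALSE)
  tab <- repeatability_table(df)
  dir.create(file.path(ctx$output_root, "repeatability"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(tab, file.path(ctx$output_root, "repeatability",
                           paste0("r_", basename(unit))), row.names = FALSE)
  invisible(tab)
}
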