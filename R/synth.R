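## Deterministic synthetic-field season generator. Emulates the study
## system at desk scale: a lettuce field on raised beds (two seed lines
## per plot, 10 equidistant plants after thinning), scanned over a season
## by an RGB camera, a thermal camera, a PSII chlorophyll-fluorescence
## imager (101-frame captures of plot centers) and a pair of east/west
## structured-light laser scanners. Every stage of the processing
## pipeline has matching ground truth.

#' Synthetic season configuration
#'
#' Defaults define the reference desk-scale study conditions: a 4 x 4
#' plot grid near (-112.0, 33.07) (UTM zone 12), 10 plants per plot on
#' two seed lines 0.31 m apart, five weekly collection dates with
#' logistic canopy growth, a 22 degC canopy / 35 degC soil daytime
#' contrast, F0/FM pulse kinetics per plot, hemispherical plant point
#' clouds on a ground plane with a known east/west scan misalignment,
#' and a 10 percent per-plot rate of merged "double" plants.
#'
#' @param n_plot_rows,n_plot_cols plot grid size.
#' @param plants_per_plot plants per plot (two seed lines).
#' @param dates character vector of collection dates.
#' @param cloud_dates dates with 3D scans (laser scanning began later in
#'   the season; default the last date).
#' @param origin field SW corner (lon, lat) in degrees.
#' @param plot_w,plot_l plot width/length in meters.
#' @param gap gap between plots in meters.
#' @param line_sep seed line separation in meters.
#' @param r0,rmax,growth_rate logistic radius growth (m, m, per date).
#' @param genotype_sd lognormal sd of the genotype effect on final
#'   radius.
#' @param n_genotypes genotypes cycled over plots.
#' @param plant_temp,soil_temp,temp_noise canopy/soil temperatures and
#'   pixel noise, degC.
#' @param thermal_gain,thermal_offset DN calibration (degC/DN, degC).
#' @param f0_range,fm_range per-plot F0 and FM draws (instrument counts).
#' @param psii_noise frame noise sd (counts).
#' @param psii_thresholds five FM contribution-threshold edges.
#' @param psii_window PSII capture window side, m.
#' @param rgb_gsd,thermal_gsd,psii_gsd ground sample distances, m/pixel.
#' @param cloud_density plant-surface point density, points/m^2.
#' @param ground_density ground point density, points/m^2.
#' @param cloud_noise point noise sd, m.
#' @param west_shift true west-scan (x, y) misalignment, m.
#' @param double_plant_rate per-plot probability of a merged plant pair.
#' @param seed master seed; all randomness flows from it through fixed
#'   per-modality substreams.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_plot_rows = 4, n_plot_cols = 4, plants_per_plot = 10,
                       dates = c("2020-01-20", "2020-01-27", "2020-02-03",
                                 "2020-02-10", "2020-02-17"),
                       cloud_dates = NULL,
                       origin = c(-112.0, 33.07),
                       plot_w = 1.02, plot_l = 4.0, gap = 0.5,
                       line_sep = 0.31,
                       r0 = 0.03, rmax = 0.12, growth_rate = 1.4,
                       genotype_sd = 0.08, n_genotypes = 8,
                       plant_temp = 22, soil_temp = 35, temp_noise = 0.3,
                       thermal_gain = 0.04, thermal_offset = -273.15,
                       f0_range = c(90, 110), fm_range = c(450, 550),
                       psii_noise = 1, psii_thresholds = c(50, 200, 300, 400, 500),
                       psii_window = 1.0,
                       rgb_gsd = 0.01, thermal_gsd = 0.02, psii_gsd = 0.02,
                       cloud_density = 4000, ground_density = 800,
                       cloud_noise = 0.001, west_shift = c(0.03, -0.01),
                       double_plant_rate = 0.1, seed = 42L) {
  cfg <- as.list(environment())
  if (is.null(cfg$cloud_dates))
    cfg$cloud_dates <- tail(dates, 1)
  with(cfg, {
    if (n_plot_rows < 1 || n_plot_cols < 1 || plants_per_plot < 1)
      stop_invalid("invalid-config: counts must be >= 1")
    if (growth_rate <= 0 || rmax <= r0)
      stop_invalid("invalid-config: growth parameters")
    if (double_plant_rate < 0 || double_plant_rate > 1)
      stop_invalid("invalid-config: double_plant_rate")
  })
  structure(cfg, class = "sim_config")
}

## degrees per meter of easting/northing at the field origin
local_deg_per_m <- function(origin) {
  u <- geo_to_utm(origin[1], origin[2])
  ge <- utm_to_geo(u$easting + 1, u$northing, u$zone)
  gn <- utm_to_geo(u$easting, u$northing + 1, u$zone)
  c(lon = ge$lon - origin[1], lat = gn$lat - origin[2])
}

#' Generate a synthetic field season
#'
#' Deterministic under the config seed. Lays out the plot grid, places
#' plants on two seed lines per plot, draws per-genotype logistic growth,
#' creates occasional merged "double" plant pairs (two plants closer than
#' the sum of their final radii) and emits a marked outlier point for
#' each.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an object of class \code{scene_truth}: list with \code{cfg},
#'   \code{plots} (\code{\link{plot_map}}), \code{plants}, \code{radii}
#'   (plants x dates, m), \code{affine} (true field-to-geo
#'   \code{\link{affine_transform_2d}}), \code{outliers},
#'   \code{deg_per_m}.
#' @export
generate_field <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dpm <- local_deg_per_m(cfg$origin)
  to_lon <- function(x) cfg$origin[1] + x * dpm["lon"]
  to_lat <- function(y) cfg$origin[2] + y * dpm["lat"]
  treatments <- c("WW", "D1", "D2")
  ## plot grid
  plots <- list(); polys <- list(); idx <- 0L
  for (i in seq_len(cfg$n_plot_rows)) for (j in seq_len(cfg$n_plot_cols)) {
    idx <- idx + 1L
    x0 <- (j - 1) * (cfg$plot_w + cfg$gap)
    y0 <- (i - 1) * (cfg$plot_l + cfg$gap)
    plots[[idx]] <- data.frame(
      plot_id = sprintf("p%02d_%02d", i, j),
      genotype = sprintf("G%02d", (idx - 1L) %% cfg$n_genotypes + 1L),
      treatment = treatments[(j - 1L) %% 3L + 1L],
      row = i, column = j,
      x0 = x0, y0 = y0, stringsAsFactors = FALSE)
    polys[[idx]] <- cbind(
      lon = to_lon(c(x0, x0 + cfg$plot_w, x0 + cfg$plot_w, x0)),
      lat = to_lat(c(y0, y0, y0 + cfg$plot_l, y0 + cfg$plot_l)))
  }
  plots <- do.call(rbind, plots)
  pm <- plot_map(plots[, c("plot_id", "genotype", "treatment", "row", "column")],
                 polys)
  nd <- length(cfg$dates)
  withr_seed(derive_seed(cfg$seed, "field"), {
    g_eff <- setNames(rnorm(cfg$n_genotypes, 0, cfg$genotype_sd),
                      sprintf("G%02d", seq_len(cfg$n_genotypes)))
    per_line <- ceiling(cfg$plants_per_plot / 2)
    rows <- list(); outliers <- list()
    for (p in seq_len(nrow(plots))) {
      pl <- plots[p, ]
      n_this <- cfg$plants_per_plot
      line_x <- pl$x0 + cfg$plot_w / 2 + c(-1, 1) * cfg$line_sep / 2
      k <- 0L
      for (ln in 1:2) for (s in seq_len(per_line)) {
        if (k >= n_this) break
        k <- k + 1L
        ## thinned stands keep a few cm of placement variation around the
        ## equidistant positions
        y <- pl$y0 + cfg$plot_l * (s - 0.5) / per_line + rnorm(1, 0, 0.04)
        x <- line_x[ln] + rnorm(1, 0, 0.02)
        rows[[length(rows) + 1L]] <- data.frame(
          true_id = sprintf("%s_t%02d", pl$plot_id, k),
          plot_id = pl$plot_id, genotype = pl$genotype,
          x = x, y = y, double_of = NA_character_,
          stringsAsFactors = FALSE)
      }
      ## merged pair: a twin closer than the sum of final radii
      if (runif(1) < cfg$double_plant_rate) {
        host_i <- length(rows) - sample.int(n_this, 1) + 1L
        host <- rows[[host_i]]
        twin <- host
        twin$true_id <- paste0(host$true_id, "b")
        twin$y <- host$y + 0.8 * cfg$rmax
        twin$double_of <- host$true_id
        rows[[host_i]]$double_of <- twin$true_id
        rows[[length(rows) + 1L]] <- twin
        outliers[[length(outliers) + 1L]] <- data.frame(
          lon = to_lon((host$x + twin$x) / 2),
          lat = to_lat((host$y + twin$y) / 2))
      }
    }
    plants <- do.call(rbind, rows)
    plants$lon <- to_lon(plants$x)
    plants$lat <- to_lat(plants$y)
    ## logistic growth: genotype effect plus plant-to-plant variation on
    ## the final radius
    rmax_i <- cfg$rmax * exp(g_eff[plants$genotype] +
                               rnorm(nrow(plants), 0, 0.03))
    t_mid <- (nd + 1) / 2
    radii <- sapply(seq_len(nd), function(t)
      cfg$r0 + (rmax_i - cfg$r0) /
        (1 + exp(-cfg$growth_rate * (t - t_mid))))
    radii <- matrix(radii, nrow = nrow(plants),
                    dimnames = list(plants$true_id, cfg$dates))
    ## any canopy pair that merges by season end is a "double": marked in
    ## the field with an outlier point, as intentional twins are
    final_r <- radii[, nd]
    dmat <- as.matrix(dist(cbind(plants$x, plants$y)))
    for (i in seq_len(nrow(plants) - 1L)) {
      if (!is.na(plants$double_of[i])) next
      for (j in seq((i + 1L), nrow(plants))) {
        if (!is.na(plants$double_of[j])) next
        if (dmat[i, j] < final_r[i] + final_r[j]) {
          plants$double_of[i] <- plants$true_id[j]
          plants$double_of[j] <- plants$true_id[i]
          outliers[[length(outliers) + 1L]] <- data.frame(
            lon = to_lon((plants$x[i] + plants$x[j]) / 2),
            lat = to_lat((plants$y[i] + plants$y[j]) / 2))
          break
        }
      }
    }
    ## per-plot fluorescence truth
    f0_p <- runif(nrow(plots), cfg$f0_range[1], cfg$f0_range[2])
    fm_p <- runif(nrow(plots), cfg$fm_range[1], cfg$fm_range[2])
    psii <- data.frame(plot_id = plots$plot_id, f0 = f0_p, fm = fm_p,
                       fvfm = (fm_p - f0_p) / fm_p, stringsAsFactors = FALSE)
    out_df <- if (length(outliers)) do.call(rbind, outliers)
              else data.frame(lon = numeric(), lat = numeric())
    structure(list(
      cfg = cfg, plots = pm, plot_frames = plots, plants = plants,
      radii = radii, psii_truth = psii, outliers = out_df,
      deg_per_m = dpm,
      affine = affine_transform_2d(a = unname(dpm["lon"]), b = 0,
                                   c = cfg$origin[1], d = 0,
                                   e = unname(dpm["lat"]), f = cfg$origin[2]),
      field_w = cfg$n_plot_cols * cfg$plot_w + (cfg$n_plot_cols - 1) * cfg$gap,
      field_l = cfg$n_plot_rows * cfg$plot_l + (cfg$n_plot_rows - 1) * cfg$gap),
      class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d plots, %d plants, %d dates, %d marked doubles\n",
              nrow(x$plot_frames), nrow(x$plants), length(x$cfg$dates),
              nrow(x$outliers)))
  invisible(x)
}

## raster scaffold over the field footprint (+margin), north-up
scene_raster_frame <- function(truth, gsd_m, margin = 0.3) {
  cfg <- truth$cfg; dpm <- truth$deg_per_m
  w <- truth$field_w + 2 * margin
  h <- truth$field_l + 2 * margin
  ncol <- ceiling(w / gsd_m); nrow <- ceiling(h / gsd_m)
  gt <- geotransform(a = gsd_m * unname(dpm["lon"]), b = 0,
                     c = cfg$origin[1] - margin * unname(dpm["lon"]),
                     d = 0, e = -gsd_m * unname(dpm["lat"]),
                     f = cfg$origin[2] + (truth$field_l + margin) * unname(dpm["lat"]))
  ## pixel-center field coordinates in meters
  xs <- -margin + (seq_len(ncol) - 0.5) * gsd_m
  ys <- truth$field_l + margin - (seq_len(nrow) - 0.5) * gsd_m
  list(gt = gt, nrow = nrow, ncol = ncol, xs = xs, ys = ys, gsd = gsd_m,
       margin = margin)
}

## plant disk mask + per-plant pixel boxes on a raster frame
plant_mask_on_frame <- function(truth, frame, date) {
  mask <- matrix(FALSE, frame$nrow, frame$ncol)
  boxes <- list()
  r_d <- truth$radii[, date]
  for (i in seq_len(nrow(truth$plants))) {
    px <- truth$plants$x[i]; py <- truth$plants$y[i]; r <- r_d[i]
    ci <- which(abs(frame$xs - px) <= r)
    ri <- which(abs(frame$ys - py) <= r)
    if (!length(ci) || !length(ri)) next
    dx <- frame$xs[ci] - px; dy <- frame$ys[ri] - py
    disk <- outer(dy^2, dx^2, "+") <= r^2
    mask[ri, ci] <- mask[ri, ci] | disk
    boxes[[length(boxes) + 1L]] <- data.frame(
      true_id = truth$plants$true_id[i],
      x_min = min(ci) - 1, y_min = min(ri) - 1,
      x_max = max(ci), y_max = max(ri))
  }
  list(mask = mask, boxes = do.call(rbind, boxes))
}

#' Render one date of sensor data from the scene truth
#'
#' Produces, for the given date: the RGB raster (plant disks on a soil
#' background with illumination noise), the thermal DN raster with its
#' known calibration and plant mask, one 101-frame PSII stack per plot
#' (pre-pulse F0 frame, linear pulse ramp to FM, post-pulse decay), an
#' east/west point-cloud pair with a known west-scan translation and
#' per-point plant/soil truth labels, and exact landmark pairs from the
#' true field-to-geo affine. All randomness derives from the config seed
#' and the date, so modalities are independent substreams.
#'
#' @param truth a \code{\link{scene_truth}}.
#' @param date one of the season dates.
#' @param modalities subset of c("rgb", "thermal", "psii", "cloud") to
#'   render.
#' @return list with elements \code{rgb} (pf_raster + truth boxes),
#'   \code{thermal} (DN pf_raster, calibration, plant mask, truth boxes),
#'   \code{psii} (per-plot stacks + per-plot truth), \code{cloud}
#'   (east/west \code{point_cloud}s, labels, true shift), and
#'   \code{landmarks}.
#' @export
render_modalities <- function(truth, date,
                              modalities = c("rgb", "thermal", "psii", "cloud")) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!date %in% truth$cfg$dates) stop_invalid("date not in season: ", date)
  cfg <- truth$cfg
  out <- list(date = date)
  if ("rgb" %in% modalities) out$rgb <- withr_seed(
    derive_seed(cfg$seed, "rgb", date), render_rgb(truth, date))
  if ("thermal" %in% modalities) out$thermal <- withr_seed(
    derive_seed(cfg$seed, "thermal", date), render_thermal(truth, date))
  if ("psii" %in% modalities) out$psii <- withr_seed(
    derive_seed(cfg$seed, "psii", date), render_psii(truth, date))
  if ("cloud" %in% modalities && date %in% cfg$cloud_dates)
    out$cloud <- withr_seed(
      derive_seed(cfg$seed, "cloud", date), render_clouds(truth, date))
  out$landmarks <- scene_landmarks(truth)
  out
}

render_rgb <- function(truth, date) {
  frame <- scene_raster_frame(truth, truth$cfg$rgb_gsd)
  pm <- plant_mask_on_frame(truth, frame, date)
  n <- frame$nrow * frame$ncol
  soil <- c(0.45, 0.33, 0.22); plant <- c(0.18, 0.55, 0.12)
  bands <- lapply(1:3, function(b) {
    v <- matrix(soil[b] + rnorm(n, 0, 0.02), frame$nrow, frame$ncol)
    v[pm$mask] <- plant[b] + rnorm(sum(pm$mask), 0, 0.02)
    v
  })
  arr <- array(unlist(bands), dim = c(frame$nrow, frame$ncol, 3))
  list(raster = pf_raster(arr, frame$gt), truth_boxes = pm$boxes,
       mask = pm$mask)
}

render_thermal <- function(truth, date) {
  cfg <- truth$cfg
  frame <- scene_raster_frame(truth, cfg$thermal_gsd)
  pm <- plant_mask_on_frame(truth, frame, date)
  temp <- matrix(cfg$soil_temp + rnorm(frame$nrow * frame$ncol, 0, cfg$temp_noise),
                 frame$nrow, frame$ncol)
  temp[pm$mask] <- cfg$plant_temp + rnorm(sum(pm$mask), 0, cfg$temp_noise)
  cal <- thermal_calibration(cfg$thermal_gain, cfg$thermal_offset)
  dn <- uncalibrate_celsius(temp, cal)
  list(raster = pf_raster(dn, frame$gt), calibration = cal,
       mask = pm$mask, truth_boxes = pm$boxes, temp_truth = temp)
}

render_psii <- function(truth, date) {
  cfg <- truth$cfg
  dpm <- truth$deg_per_m
  half <- cfg$psii_window / 2
  npx <- ceiling(cfg$psii_window / cfg$psii_gsd)
  stacks <- list()
  for (p in seq_len(nrow(truth$plot_frames))) {
    pl <- truth$plot_frames[p, ]
    cx <- pl$x0 + cfg$plot_w / 2; cy <- pl$y0 + cfg$plot_l / 2
    gt <- geotransform(a = cfg$psii_gsd * unname(dpm["lon"]), b = 0,
                       c = truth$cfg$origin[1] + (cx - half) * unname(dpm["lon"]),
                       d = 0, e = -cfg$psii_gsd * unname(dpm["lat"]),
                       f = truth$cfg$origin[2] + (cy + half) * unname(dpm["lat"]))
    xs <- cx - half + (seq_len(npx) - 0.5) * cfg$psii_gsd
    ys <- cy + half - (seq_len(npx) - 0.5) * cfg$psii_gsd
    mask <- matrix(FALSE, npx, npx)
    in_plot <- which(truth$plants$plot_id == pl$plot_id)
    for (i in in_plot) {
      r <- truth$radii[i, date]
      ci <- which(abs(xs - truth$plants$x[i]) <= r)
      ri <- which(abs(ys - truth$plants$y[i]) <= r)
      if (!length(ci) || !length(ri)) next
      disk <- outer((ys[ri] - truth$plants$y[i])^2,
                    (xs[ci] - truth$plants$x[i])^2, "+") <= r^2
      mask[ri, ci] <- mask[ri, ci] | disk
    }
    pt <- truth$psii_truth[truth$psii_truth$plot_id == pl$plot_id, ]
    f0_map <- matrix(5, npx, npx); fm_map <- matrix(8, npx, npx)
    f0_map[mask] <- pt$f0; fm_map[mask] <- pt$fm
    frames <- vector("list", 101L)
    nz <- function() matrix(rnorm(npx * npx, 0, cfg$psii_noise), npx, npx)
    frames[[1]] <- f0_map + nz()
    for (j in 1:50)
      frames[[j + 1]] <- f0_map + (fm_map - f0_map) * (j / 50) + nz()
    for (j in 1:50)
      frames[[j + 51]] <- f0_map + (fm_map - f0_map) * exp(-j / 10) + nz()
    stacks[[pl$plot_id]] <- list(
      stack = validate_stack(frames, gt = gt, plot_id = pl$plot_id),
      mask = mask, f0_true = pt$f0, fm_true = pt$fm, fvfm_true = pt$fvfm)
  }
  stacks
}

## uniform hemisphere-surface sample of radius r at (cx, cy, 0)
sample_hemisphere <- function(n, cx, cy, r) {
  z <- runif(n, 0, r)
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(r^2 - z^2, 0))
  cbind(cx + rho * cos(phi), cy + rho * sin(phi), z)
}

render_clouds <- function(truth, date) {
  cfg <- truth$cfg
  sample_scan <- function() {
    margin <- 0.3
    area <- (truth$field_w + 2 * margin) * (truth$field_l + 2 * margin)
    ng <- round(area * cfg$ground_density)
    ground <- cbind(runif(ng, -margin, truth$field_w + margin),
                    runif(ng, -margin, truth$field_l + margin),
                    rnorm(ng, 0, cfg$cloud_noise))
    pts <- list(ground); labs <- list(rep("soil", ng))
    ids <- list(rep(NA_character_, ng))
    for (i in seq_len(nrow(truth$plants))) {
      r <- truth$radii[i, date]
      np <- max(20L, round(2 * pi * r^2 * cfg$cloud_density))
      h <- sample_hemisphere(np, truth$plants$x[i], truth$plants$y[i], r)
      h <- h + matrix(rnorm(3 * np, 0, cfg$cloud_noise), np)
      pts[[length(pts) + 1L]] <- h
      labs[[length(labs) + 1L]] <- rep("plant", np)
      ids[[length(ids) + 1L]] <- rep(truth$plants$true_id[i], np)
    }
    list(points = do.call(rbind, pts), labels = unlist(labs),
         plant_id = unlist(ids))
  }
  east <- sample_scan()
  west <- sample_scan()
  wp <- west$points
  wp[, 1] <- wp[, 1] + cfg$west_shift[1]
  wp[, 2] <- wp[, 2] + cfg$west_shift[2]
  list(east = point_cloud(east$points, frame = "field"),
       west = point_cloud(wp, frame = "field"),
       labels_east = east$labels, labels_west = west$labels,
       plant_id_east = east$plant_id, plant_id_west = west$plant_id,
       west_shift = cfg$west_shift)
}

## exact landmark pairs from the true field-to-geo affine
scene_landmarks <- function(truth) {
  xs <- c(0, truth$field_w, 0, truth$field_w, truth$field_w / 2, truth$field_w / 4)
  ys <- c(0, 0, truth$field_l, truth$field_l, truth$field_l / 2, truth$field_l / 4)
  a <- truth$affine
  data.frame(x = xs, y = ys,
             lon = a$a * xs + a$b * ys + a$c,
             lat = a$d * xs + a$e * ys + a$f)
}

#' Ground-truth trait tables for a scene
#'
#' Tidy truth keyed like the pipeline outputs: per (plant, date) true
#' bounding area (the (2r)^2 box of a radius-r disk), plant height
#' (hemisphere radius), canopy temperature, and per plot the true
#' F0/FM/FV/FM.
#'
#' @param truth a \code{\link{scene_truth}}.
#' @return list with \code{plants} (per plant x date) and \code{psii}
#'   (per plot) data.frames.
#' @export
ground_truth_tables <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cfg <- truth$cfg
  grid <- expand.grid(true_id = truth$plants$true_id, date = cfg$dates,
                      stringsAsFactors = FALSE)
  i <- match(grid$true_id, truth$plants$true_id)
  r <- truth$radii[cbind(i, match(grid$date, cfg$dates))]
  plants <- data.frame(
    true_id = grid$true_id, date = grid$date,
    plot_id = truth$plants$plot_id[i],
    genotype = truth$plants$genotype[i],
    lon = truth$plants$lon[i], lat = truth$plants$lat[i],
    radius = r, ba_true = (2 * r)^2, ph_true = r,
    medt_true = cfg$plant_temp,
    is_double_true = !is.na(truth$plants$double_of[i]),
    stringsAsFactors = FALSE)
  list(plants = plants, psii = truth$psii_truth)
}
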