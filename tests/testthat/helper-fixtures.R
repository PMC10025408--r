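## Shared fixtures, built once per test run.

.fixture_env <- new.env()

## a small 2 x 2 plot season with three dates
tiny_scene <- function() {
  if (is.null(.fixture_env$scene)) {
    .fixture_env$scene <- generate_field(sim_config(
      n_plot_rows = 2, n_plot_cols = 2,
      dates = c("2020-02-03", "2020-02-10", "2020-02-17"), seed = 42L))
  }
  .fixture_env$scene
}

tiny_render <- function(date = "2020-02-17", modalities = c("rgb", "thermal",
                                                            "psii", "cloud")) {
  key <- paste(date, paste(modalities, collapse = "+"))
  if (is.null(.fixture_env$render[[key]])) {
    if (is.null(.fixture_env$render)) .fixture_env$render <- list()
    .fixture_env$render[[key]] <- render_modalities(tiny_scene(), date,
                                                    modalities = modalities)
  }
  .fixture_env$render[[key]]
}

## deterministic structured test cloud: hemisphere on a ground patch
structured_cloud <- function(r = 0.15, n_plant = 600, n_ground = 400,
                             noise = 0, seed = 1) {
  set.seed(seed)
  z <- runif(n_plant, 0, r); phi <- runif(n_plant, 0, 2 * pi)
  rho <- sqrt(r^2 - z^2)
  plant <- cbind(rho * cos(phi), rho * sin(phi), z)
  ground <- cbind(runif(n_ground, -0.4, 0.4), runif(n_ground, -0.4, 0.4), 0)
  pts <- rbind(plant, ground)
  if (noise > 0) pts <- pts + matrix(rnorm(length(pts), 0, noise), nrow(pts))
  list(cloud = point_cloud(pts, frame = "field"),
       labels = c(rep("plant", n_plant), rep("soil", n_ground)))
}

## simple north-up geotransform helper
gt_northup <- function(step = 1e-5, lon0 = -112, lat0 = 33)
  geotransform(a = step, b = 0, c = lon0, d = 0, e = -step, f = lat0)
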