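## YAML-configured pipeline runner: the processing instructions live in a
## config with four sections ("tags", "modules", "workload_manager",
## "paths"); modules run in listed order, and within a module the input
## units are dispatched to a local worker pool. Every stochastic stage is
## seeded per input unit, never per worker, so results are bitwise
## independent of the worker count.

PIPELINE_OPERATIONS <- c("simulate", "rgb", "thermal", "psii", "track",
                         "cloud", "fuse", "evaluate", "repeatability")

#' Load and validate a pipeline YAML config
#'
#' The config must contain the four sections \code{tags}, \code{modules},
#' \code{workload_manager} and \code{paths}. Unknown top-level keys warn
#' but are kept. Each module needs a unique \code{name} and a known
#' \code{operation}; \code{workload_manager} fields beyond
#' \code{n_workers} (cores per worker, memory per core) are validated and
#' recorded but drive only the local pool.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return an object of class \code{pipeline_config}.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  req <- c("tags", "modules", "workload_manager", "paths")
  for (s in req)
    if (is.null(cfg[[s]])) stop_invalid("invalid-config: missing section '", s, "'")
  extra <- setdiff(names(cfg), req)
  if (length(extra)) warning("unknown config keys: ", paste(extra, collapse = ", "))
  nms <- vapply(cfg$modules, function(m) m$name %||% "", character(1))
  if (any(nms == "") || anyDuplicated(nms))
    stop_invalid("invalid-config: module names must be present and unique")
  for (m in cfg$modules) {
    op <- m$operation %||% m$name
    if (!op %in% PIPELINE_OPERATIONS)
      stop_invalid("invalid-config: unknown operation '", op, "'")
  }
  cfg$workload_manager$n_workers <- cfg$workload_manager$n_workers %||% 1L
  cfg$paths$input_root <- cfg$paths$input_root %||% "."
  cfg$paths$output_root <- cfg$paths$output_root %||% "out"
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Serialize a pipeline config to YAML
#' @param cfg a \code{\link{load_config}} result (or compatible list).
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Default synthetic-season pipeline config
#'
#' The standard end-to-end run: simulate a season, process RGB, thermal
#' and PSII, track plants, process the 3D scans against the tracked
#' detections, fuse modalities, and evaluate against the generator truth.
#'
#' @param input_root directory for simulated sensor data.
#' @param output_root directory for pipeline outputs.
#' @param n_workers local pool size.
#' @param seed global pipeline seed.
#' @param sim named list of \code{\link{sim_config}} overrides.
#' @return a \code{pipeline_config}.
#' @export
default_pipeline_config <- function(input_root, output_root, n_workers = 1,
                                    seed = 42, sim = list()) {
  load_config(list(
    tags = list(season = "synthetic", generator = "phenofield"),
    modules = list(
      list(name = "simulate", operation = "simulate", parameters = sim),
      list(name = "rgb", operation = "rgb",
           inputs = "rgb_*.tif",
           parameters = list(min_area_px = 15)),
      list(name = "thermal", operation = "thermal",
           inputs = "thermal_*.tif",
           parameters = list(min_area_px = 5)),
      list(name = "psii", operation = "psii", inputs = "psii/*/*",
           parameters = list(thresholds = c(50, 200, 300, 400, 500))),
      list(name = "track", operation = "track",
           parameters = list(threshold = 6e-7)),
      list(name = "cloud", operation = "cloud", inputs = "clouds/*_east.ply",
           parameters = list(pad = 0.1)),
      list(name = "fuse", operation = "fuse"),
      list(name = "evaluate", operation = "evaluate")),
    workload_manager = list(n_workers = n_workers, cores_per_worker = 1,
                            memory_per_core = "2G"),
    paths = list(input_root = input_root, output_root = output_root,
                 seed = seed)))
}

#' Run a pipeline
#'
#' Executes the configured modules in listed order. Within a module,
#' input units (one raster, one 101-frame stack, one scan pair, ...) are
#' dispatched to a pool of \code{n_workers} local workers; a failed task
#' is logged and does not abort its module (downstream joins tolerate
#' gaps), but a required module with zero resolvable inputs aborts the
#' pipeline. Every task derives its RNG seed from (global seed, module
#' name, unit id), so outputs are bitwise independent of the worker
#' count.
#'
#' @param cfg a \code{\link{load_config}} result.
#' @param seed global seed (overrides \code{paths$seed}).
#' @return invisibly, the task-log data.frame (also written as JSON lines
#'   to \code{output_root/pipeline_log.jsonl}).
#' @export
run_pipeline <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- seed %||% cfg$paths$seed %||% 42
  n_workers <- max(1L, as.integer(cfg$workload_manager$n_workers))
  ctx <- list(input_root = cfg$paths$input_root,
              output_root = cfg$paths$output_root,
              seed = seed, cfg = cfg)
  dir.create(ctx$output_root, recursive = TRUE, showWarnings = FALSE)
  logs <- list()
  for (m in cfg$modules) {
    op <- m$operation %||% m$name
    params <- m$parameters %||% list()
    units <- stage_units(op, m, ctx)
    required <- m$required %||% TRUE
    if (!length(units)) {
      if (required) stop_invalid("pipeline-aborted: no inputs for module '", m$name, "'")
      next
    }
    run_one <- function(u) {
      t0 <- Sys.time()
      res <- tryCatch({
        stage_run(op, u, ctx, params,
                  seed = derive_seed(seed, m$name, u))
        list(status = "ok", message = "")
      }, error = function(e) list(status = "failed",
                                  message = conditionMessage(e)))
      data.frame(task_id = paste(m$name, u, sep = ":"), module = m$name,
                 unit = u, status = res$status,
                 start = format(t0, "%Y-%m-%dT%H:%M:%OS3"),
                 end = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                 message = res$message, stringsAsFactors = FALSE)
    }
    rows <- if (n_workers > 1 && length(units) > 1 &&
                .Platform$OS.type == "unix")
      parallel::mclapply(units, run_one, mc.cores = n_workers)
    else lapply(units, run_one)
    logs[[m$name]] <- do.call(rbind, rows)
  }
  log_df <- do.call(rbind, logs)
  rownames(log_df) <- NULL
  con <- file(file.path(ctx$output_root, "pipeline_log.jsonl"), "w")
  for (i in seq_len(nrow(log_df)))
    writeLines(jsonlite::toJSON(as.list(log_df[i, ]), auto_unbox = TRUE), con)
  close(con)
  invisible(log_df)
}
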