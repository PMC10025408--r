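## PSII chlorophyll fluorescence: 101-frame capture stacks.
## Frame 1 (index 0) is captured shortly before the saturating LED pulse
## (F0), frames 2..51 during the one-second pulse (FM = per-pixel max),
## frames 52..101 after the pulse (retained but unused).

PSII_N_FRAMES <- 101L
PSII_PULSE_FRAMES <- 2:51

#' Validate a PSII fluorescence stack
#'
#' Accepts exactly 101 same-shape frames and attaches the timing roles:
#' one pre-pulse frame, 50 saturating-pulse frames, 50 post-pulse frames.
#'
#' @param frames list of 101 numeric matrices, ordered in capture time.
#' @param gt optional \code{\link{geotransform}}.
#' @param plot_id optional plot identifier.
#' @return an object of class \code{fluorescence_stack}.
#' @export
validate_stack <- function(frames, gt = NULL, plot_id = NA_character_) {
  if (length(frames) != PSII_N_FRAMES)
    stop_invalid("malformed-stack: expected 101 frames, got ", length(frames))
  d <- dim(frames[[1]])
  for (fr in frames)
    if (!identical(dim(fr), d))
      stop_invalid("malformed-stack: frame shape mismatch")
  structure(list(frames = frames, gt = gt, plot_id = plot_id,
                 timing = list(pre = 1L, pulse = PSII_PULSE_FRAMES,
                               post = 52:101)),
            class = "fluorescence_stack")
}

#' FM contribution thresholds
#'
#' Five strictly ascending bin edges over the FM intensity range, used to
#' segment pixels into contribution classes; pixels whose FM falls below
#' the first edge are background. The instrument-specific values are
#' supplied through configuration; the default derives five equal
#' quantile edges from the capture's own FM histogram.
#'
#' @param edges five strictly ascending numeric edges.
#' @return an object of class \code{contribution_thresholds}.
#' @export
contribution_thresholds <- function(edges) {
  if (length(edges) != 5 || any(diff(edges) <= 0))
    stop_invalid("thresholds must be 5 strictly ascending edges")
  structure(list(edges = edges), class = "contribution_thresholds")
}

#' Default thresholds from an FM map
#'
#' Five equal quantile edges (10th to 90th percentile) of the FM
#' distribution of the capture itself.
#'
#' @param fm_map numeric matrix of per-pixel FM.
#' @return a \code{\link{contribution_thresholds}}.
#' @export
default_thresholds <- function(fm_map) {
  q <- quantile(fm_map[is.finite(fm_map)], probs = seq(0.1, 0.9, length.out = 5),
                names = FALSE)
  if (any(diff(q) <= 0)) q <- q + seq(0, 1e-9, length.out = 5) * max(1, abs(q[5]))
  contribution_thresholds(q)
}

#' Per-pixel F0, FM and contribution-bin maps
#'
#' F0 is the pre-pulse frame value; FM is the per-pixel maximum over the
#' 50 saturating-pulse frames. Each pixel is binned by the threshold
#' interval containing its FM: bin 0 (below the first edge) is
#' background and is excluded from plot aggregation.
#'
#' @param stack a \code{\link{fluorescence_stack}}.
#' @param thresholds a \code{\link{contribution_thresholds}}, or NULL to
#'   derive \code{\link{default_thresholds}} from this capture.
#' @return list with matrices \code{f0}, \code{fm}, \code{bin} and the
#'   thresholds used.
#' @export
compute_f0_fm <- function(stack, thresholds = NULL) {
  stopifnot(inherits(stack, "fluorescence_stack"))
  f0 <- stack$frames[[stack$timing$pre]]
  pulse <- stack$frames[stack$timing$pulse]
  fm <- Reduce(pmax, pulse)
  if (is.null(thresholds)) thresholds <- default_thresholds(fm)
  stopifnot(inherits(thresholds, "contribution_thresholds"))
  bin <- matrix(findInterval(fm, thresholds$edges), nrow = nrow(fm))
  list(f0 = f0, fm = fm, bin = bin, thresholds = thresholds)
}

#' Plot-level fluorescence traits
#'
#' Aggregates non-background pixels (bin > 0) to plot level: F0 and FM
#' are aggregated (mean by default) over those pixels, then
#' FV = FM - F0 and FV/FM = (FM - F0)/FM on the plot-level values.
#'
#' @param f0_map,fm_map,bin_map matrices from \code{\link{compute_f0_fm}}.
#' @param aggregate "mean" (default) or "median".
#' @return an object of class \code{fluorescence_traits}: list with
#'   \code{f0}, \code{fm}, \code{fv}, \code{fvfm}, \code{n_pixels}.
#' @export
fluorescence_traits <- function(f0_map, fm_map, bin_map,
                                aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!all(dim(f0_map) == dim(fm_map)) || !all(dim(fm_map) == dim(bin_map)))
    stop_invalid("maps must have the same shape")
  keep <- bin_map > 0 & is.finite(f0_map) & is.finite(fm_map)
  if (!any(keep)) stop_invalid("insufficient-data: zero non-background pixels")
  agg <- if (aggregate == "mean") mean else median
  f0 <- agg(f0_map[keep]); fm <- agg(fm_map[keep])
  if (fm == 0) stop_invalid("undefined-ratio: plot-level FM is zero")
  structure(list(f0 = f0, fm = fm, fv = fm - f0, fvfm = (fm - f0) / fm,
                 n_pixels = sum(keep)),
            class = "fluorescence_traits")
}

#' Read a PSII stack from a directory of frame rasters
#'
#' Expects 101 single-frame TIFF rasters named so that lexicographic
#' order is capture order, plus a \code{metadata.json} file carrying the
#' plot id, the capture timestamp, the shared intensity scale and the six
#' geotransform coefficients (one metadata file per stack, as one capture
#' is one task unit).
#'
#' @param dir directory containing the frames and metadata.
#' @return a \code{\link{fluorescence_stack}}.
#' @export
read_psii_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  lo <- meta$value_min %||% 0; hi <- meta$value_max %||% 1
  span <- if (hi > lo) hi - lo else 1
  frames <- lapply(files, function(f) {
    img <- tiff::readTIFF(f)
    img * span + lo
  })
  gt <- if (!is.null(meta$geotransform)) {
    g <- as.numeric(meta$geotransform)
    geotransform(a = g[1], b = g[2], c = g[3], d = g[4], e = g[5], f = g[6])
  } else NULL
  validate_stack(frames, gt = gt, plot_id = meta$plot_id %||% NA_character_)
}

#' Write a PSII stack as a directory of frame rasters
#'
#' Frames go to plain 32-bit TIFFs normalized by a shared intensity
#' scale; the scale, plot id and geotransform go to a single
#' \code{metadata.json} in the stack directory.
#'
#' @param stack a \code{\link{fluorescence_stack}}.
#' @param dir output directory (created).
#' @param date capture date recorded in the metadata.
#' @export
write_psii_stack <- function(stack, dir, date = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(unlist(lapply(stack$frames, range)))
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  for (i in seq_along(stack$frames)) {
    tiff::writeTIFF((stack$frames[[i]] - rng[1]) / span,
                    file.path(dir, sprintf("frame_%03d.tif", i - 1L)),
                    bits.per.sample = 32, compression = "none")
  }
  gt <- stack$gt %||% geotransform(a = 1, c = 0, e = -1, f = 0)
  jsonlite::write_json(
    list(plot_id = stack$plot_id, date = date,
         n_frames = length(stack$frames),
         value_min = rng[1], value_max = rng[2],
         geotransform = c(gt$a, gt$b, gt$c, gt$d, gt$e, gt$f)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
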