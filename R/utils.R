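#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans hclust cutree dist median quantile prcomp lm
#'   coef setNames runif rnorm complete.cases aggregate sd
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("phenofield_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' Deterministic 32-bit string/seed hash
#'
#' Combines a global integer seed with arbitrary string tags into a
#' reproducible seed below 2^31, so that every input unit of a pipeline
#' stage gets its own random substream independent of worker scheduling.
#'
#' @param seed integer global seed.
#' @param ... character tags (module name, input unit id, ...).
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in as.character(c(...))) {
    for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

## mode of a vector, deterministic tie-break by first appearance
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- table(factor(x, levels = unique(x)))
  names(tab)[which.max(tab)]
}
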