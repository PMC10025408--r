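## Variance-component estimation and repeatability for field-trial trait
## data. One trait, one collection date at a time: a linear mixed model
## with irrigation fixed and genotype, genotype x irrigation,
## rep-in-irrigation and row/column-in-(rep x irrigation) random, fitted
## by REML through lme4.

#' Fit variance components for a trait
#'
#' Model: value ~ irrigation (fixed) + (1|genotype) +
#' (1|genotype:irrigation) + (1|rep-in-irrigation) +
#' (1|row-in-(rep x irrigation)) + (1|col-in-(rep x irrigation)),
#' REML. lme4 constrains variances to be non-negative, so negative
#' estimates are truncated at zero by construction. The design counts
#' entering repeatability — treatments per genotype (n_irg) and plots per
#' genotype (n_plot) — are the modal counts across genotypes.
#'
#' @param obs data.frame with columns \code{value}, \code{genotype},
#'   \code{treatment}, \code{rep}, \code{row}, \code{col}.
#' @return an object of class \code{variance_components}: list with
#'   \code{sigma2_g}, \code{sigma2_gi}, \code{sigma2_rep},
#'   \code{sigma2_row}, \code{sigma2_col}, \code{sigma2_e}, \code{n_irg},
#'   \code{n_plot}, and the fitted \code{model}.
#' @export
fit_variance_components <- function(obs) {
  req <- c("value", "genotype", "treatment", "rep", "row", "col")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop_invalid("missing columns: ", paste(miss, collapse = ", "))
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  if (length(unique(obs$genotype)) < 2) stop_invalid("need >= 2 genotypes")
  if (length(unique(obs$treatment)) < 2) stop_invalid("need >= 2 treatments")
  if (length(unique(obs$rep)) < 2) stop_invalid("need >= 2 reps")
  d <- data.frame(value = obs$value,
                  g = factor(obs$genotype),
                  irg = factor(obs$treatment),
                  rep_irg = factor(paste(obs$treatment, obs$rep, sep = ":")),
                  row_f = factor(paste(obs$treatment, obs$rep, obs$row, sep = ":")),
                  col_f = factor(paste(obs$treatment, obs$rep, obs$col, sep = ":")))
  d$g_irg <- factor(paste(d$g, d$irg, sep = ":"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ irg + (1 | g) + (1 | g_irg) + (1 | rep_irg) +
                   (1 | row_f) + (1 | col_f),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore")))),
    error = function(e) stop_invalid("fit-failed: ", conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(term) {
    v <- vc$vcov[vc$grp == term]
    if (length(v)) max(0, v) else 0
  }
  per_geno <- split(obs, obs$genotype)
  n_irg <- as.integer(modal_value(vapply(per_geno, function(x)
    length(unique(x$treatment)), numeric(1))))
  n_plot <- as.integer(modal_value(vapply(per_geno, nrow, numeric(1))))
  structure(list(sigma2_g = getv("g"), sigma2_gi = getv("g_irg"),
                 sigma2_rep = getv("rep_irg"), sigma2_row = getv("row_f"),
                 sigma2_col = getv("col_f"),
                 sigma2_e = getv("Residual"),
                 n_irg = n_irg, n_plot = n_plot, model = fit),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("<variance_components> g=%.4g gxi=%.4g rep=%.4g ",
                     "row=%.4g col=%.4g resid=%.4g (n_irg=%d, n_plot=%d)\n"),
              x$sigma2_g, x$sigma2_gi, x$sigma2_rep, x$sigma2_row,
              x$sigma2_col, x$sigma2_e, x$n_irg, x$n_plot))
  invisible(x)
}

#' Repeatability from variance components
#'
#' r = sigma2_g / (sigma2_g + sigma2_gi / n_irg + sigma2_e / n_plot):
#' the proportion of entry-mean phenotypic variance attributable to
#' genotype.
#'
#' @param vc a \code{\link{variance_components}}, or a list with the
#'   needed fields.
#' @return r in [0, 1], or NA when the denominator is zero.
#' @examples
#' repeatability(list(sigma2_g = 2, sigma2_gi = 1, sigma2_e = 4,
#'                    n_irg = 3, n_plot = 6))  # 2/3
#' @export
repeatability <- function(vc) {
  den <- vc$sigma2_g + vc$sigma2_gi / vc$n_irg + vc$sigma2_e / vc$n_plot
  if (!is.finite(den) || den <= 0) return(NA_real_)
  vc$sigma2_g / den
}

#' Simulate a field-trial trait design
#'
#' Draws one trait under the repeatability mixed model: genotype,
#' genotype-by-irrigation and residual effects (plus optional rep, row
#' and column effects) on a randomized design of \code{n_genotypes} x
#' treatments x reps, with each rep laid out on a plot grid.
#'
#' @param n_genotypes number of genotypes.
#' @param treatments treatment labels.
#' @param n_reps replications per treatment.
#' @param sigma_g2,sigma_gi2,sigma_e2 genotype, genotype-by-irrigation
#'   and residual variances.
#' @param sigma_rep2,sigma_row2,sigma_col2 design-effect variances.
#' @param mu overall mean.
#' @param seed RNG seed.
#' @return data.frame of trait observations suitable for
#'   \code{\link{fit_variance_components}}, with the simulation truth in
#'   attribute \code{"truth"}.
#' @export
simulate_trait_design <- function(n_genotypes = 100,
                                  treatments = c("WW", "D1", "D2"),
                                  n_reps = 3, sigma_g2 = 4, sigma_gi2 = 1,
                                  sigma_e2 = 1, sigma_rep2 = 0,
                                  sigma_row2 = 0, sigma_col2 = 0,
                                  mu = 10, seed = 1L) {
  withr_seed(seed, {
    genos <- sprintf("G%03d", seq_len(n_genotypes))
    g_eff <- rnorm(n_genotypes, 0, sqrt(sigma_g2))
    names(g_eff) <- genos
    gi_eff <- matrix(rnorm(n_genotypes * length(treatments), 0, sqrt(sigma_gi2)),
                     n_genotypes, dimnames = list(genos, treatments))
    irg_eff <- setNames(seq_along(treatments) * 0.5, treatments)  # fixed
    n_cols <- ceiling(sqrt(n_genotypes))
    out <- list()
    for (tr in treatments) for (k in seq_len(n_reps)) {
      ord <- sample(genos)
      rep_e <- rnorm(1, 0, sqrt(sigma_rep2))
      rows <- ceiling(seq_along(ord) / n_cols)
      cols <- (seq_along(ord) - 1L) %% n_cols + 1L
      row_e <- rnorm(max(rows), 0, sqrt(sigma_row2))
      col_e <- rnorm(max(cols), 0, sqrt(sigma_col2))
      out[[length(out) + 1L]] <- data.frame(
        value = mu + irg_eff[tr] + g_eff[ord] + gi_eff[ord, tr] + rep_e +
          row_e[rows] + col_e[cols] + rnorm(length(ord), 0, sqrt(sigma_e2)),
        genotype = ord, treatment = tr, rep = k, row = rows, col = cols,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    n_irg <- length(treatments)
    attr(res, "truth") <- list(
      sigma_g2 = sigma_g2, sigma_gi2 = sigma_gi2, sigma_e2 = sigma_e2,
      r = sigma_g2 / (sigma_g2 + sigma_gi2 / n_irg +
                        sigma_e2 / (n_irg * n_reps)))
    res
  })
}

#' Per-date, per-trait repeatability table
#'
#' Fits the variance-component model separately for every (trait, date)
#' combination of a tidy trait table, as collection time points are
#' analyzed separately.
#'
#' @param df tidy data.frame with columns \code{value}, \code{genotype},
#'   \code{treatment}, \code{rep}, \code{row}, \code{col}, \code{date},
#'   \code{trait}.
#' @return data.frame with one row per (trait, date): variance components
#'   and \code{r}.
#' @export
repeatability_table <- function(df) {
  sp <- split(df, list(df$trait, df$date), drop = TRUE)
  rows <- lapply(names(sp), function(nm) {
    x <- sp[[nm]]
    vc <- tryCatch(fit_variance_components(x), error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    data.frame(trait = x$trait[1], date = x$date[1],
               sigma2_g = vc$sigma2_g, sigma2_gi = vc$sigma2_gi,
               sigma2_e = vc$sigma2_e, n_irg = vc$n_irg,
               n_plot = vc$n_plot, r = repeatability(vc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
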