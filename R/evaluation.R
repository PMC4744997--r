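#' Pearson product-moment correlation with an undefined flag
#'
#' Thin wrapper over the standard estimator that returns `NA` (with a
#' warning) instead of erroring when either vector is constant, and drops
#' pairs with missing values (used for species whose CV of abundance is
#' undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient, or `NA_real_` if undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_ns("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_ns("need >= 3 complete pairs, got ", length(x))
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("pearson: constant vector, correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Correlate niche axes with abundance responses
#'
#' Computes Pearson correlations between the first `components` PC scores of
#' every supplied ordination (each niche dimension, the meta-ordination, and
#' the pooled-trait baseline) and two ecological responses: mean abundance
#' and the coefficient of variation of abundance. Because PCA component signs
#' are arbitrary (a fixed sign convention is applied, but the underlying
#' orientation carries no meaning), headline comparisons use `|r|`.
#' Species with undefined CV are excluded pairwise from CV correlations.
#'
#' @param meta a [meta_ordinate()] result, or `NULL`.
#' @param dims list of [ordinate_dimension()] results, or `NULL`.
#' @param raw an [ordinate_raw()] / [pca_correlation()] result on the pooled
#'   traits, or `NULL`.
#' @param resp a `response_table` ([compute_response_stats()]).
#' @param components how many leading components per ordination (default 2).
#' @return A data frame of class `correlation_report` with columns `axis`
#'   (e.g. `"habitat.PC1"`, `"meta.PC2"`, `"raw.PC1"`), `r_mean_abundance`,
#'   `abs_r_mean_abundance`, `r_cv_abundance`, `abs_r_cv_abundance`;
#'   attribute `best` names the axis with maximal `|r|` per response.
#' @export
correlate_axes <- function(meta = NULL, dims = NULL, raw = NULL, resp,
                           components = 2L) {
  stopifnot(inherits(resp, "response_table"))
  axes <- list()
  add_axes <- function(scores, prefix) {
    if (!identical(rownames(scores), resp$species_ids)) {
      stop_ns("species mismatch between '", prefix, "' scores and responses")
    }
    for (j in seq_len(min(components, ncol(scores)))) {
      axes[[paste0(prefix, ".PC", j)]] <<- scores[, j]
    }
  }
  for (o in dims %||% list()) add_axes(o$retained_scores, o$dimension)
  if (!is.null(meta)) add_axes(meta$pca$scores, "meta")
  if (!is.null(raw)) add_axes(raw$scores, "raw")
  if (!length(axes)) stop_ns("no ordination supplied")

  n_undef <- sum(resp$undefined_cv)
  if (n_undef) {
    message("correlate_axes: ", n_undef,
            " species with undefined CV excluded pairwise from CV correlations")
  }
  rows <- lapply(names(axes), function(a) {
    rm_ <- pearson(axes[[a]], resp$mean_abundance)
    rc_ <- pearson(axes[[a]], resp$cv_abundance)
    data.frame(axis = a,
               r_mean_abundance = rm_, abs_r_mean_abundance = abs(rm_),
               r_cv_abundance = rc_, abs_r_cv_abundance = abs(rc_),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("correlation_report", "data.frame")
  attr(report, "best") <- c(
    mean_abundance = report$axis[which.max(report$abs_r_mean_abundance)],
    cv_abundance = report$axis[which.max(report$abs_r_cv_abundance)]
  )
  report
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  b <- attr(x, "best")
  cat(sprintf("best |r|: mean abundance -> %s; CV of abundance -> %s\n",
              b[["mean_abundance"]], b[["cv_abundance"]]))
  invisible(x)
}
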