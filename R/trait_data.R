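#' Recognised niche dimensions
#'
#' The five fundamental niche dimensions used to partition trait tables:
#' habitat, life history, trophic, defence and metabolic.
#'
#' @export
NICHE_DIMENSIONS <- c("habitat", "life_history", "trophic", "defence", "metabolic")

#' Construct a trait matrix for one niche dimension
#'
#' A `trait_matrix` holds one niche dimension's species-by-trait table:
#' rows are species, columns are numeric functional traits or performance
#' measures. Species are stored in canonical (lexicographic) order so that
#' tables for different dimensions align row-by-row without bookkeeping.
#'
#' @param values numeric matrix or data frame (species x traits) with row and
#'   column names, or a data frame whose first column is `species_id`.
#' @param dimension one of [NICHE_DIMENSIONS].
#' @param standardized logical; `TRUE` only for output of [standardize()].
#' @param zero_variance character vector of trait names flagged as constant
#'   (excluded from downstream ordination).
#' @return An object of class `trait_matrix` with fields `dimension`,
#'   `species_ids`, `trait_names`, `values`, `standardized`, `zero_variance`.
#' @export
trait_matrix <- function(values, dimension, standardized = FALSE,
                         zero_variance = character()) {
  dimension <- match.arg(dimension, NICHE_DIMENSIONS)
  if (is.data.frame(values)) {
    if (ncol(values) >= 2L && (is.character(values[[1L]]) || is.factor(values[[1L]]))) {
      ids <- as.character(values[[1L]])
      values <- as.matrix(values[, -1L, drop = FALSE])
      rownames(values) <- ids
    } else {
      values <- as.matrix(values)
    }
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ns("'values' must be a numeric species x trait matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_ns("empty trait table for dimension '", dimension, "'")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ns("trait matrix needs species row names and trait column names")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop_ns("duplicated species id(s) in dimension '", dimension, "': ",
            paste(unique(dup), collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_ns("missing value in dimension '", dimension, "' at species '",
            rownames(values)[bad[1L]], "', trait '", colnames(values)[bad[2L]],
            "' (use load_trait_table(impute_missing = TRUE) to column-mean impute)")
  }
  values <- values[canonical_order(rownames(values)), , drop = FALSE]
  structure(
    list(
      dimension = dimension,
      species_ids = rownames(values),
      trait_names = colnames(values),
      values = values,
      standardized = isTRUE(standardized),
      zero_variance = zero_variance
    ),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf(
    "<trait_matrix> dimension '%s': %d species x %d traits%s%s\n",
    x$dimension, length(x$species_ids), length(x$trait_names),
    if (x$standardized) " (standardized)" else "",
    if (length(x$zero_variance)) {
      paste0("; zero-variance: ", paste(x$zero_variance, collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Read a delimited trait table for one niche dimension
#'
#' Expects a header row of trait names and a first column of species
#' identifiers (conventionally named `species_id`). Field separator is
#' inferred from the extension (`.tsv` -> tab, otherwise comma) unless given.
#' Species rows are canonicalized to lexicographic order on load.
#'
#' @param path path to a CSV/TSV file.
#' @param dimension one of [NICHE_DIMENSIONS].
#' @param sep field separator; inferred from the extension by default.
#' @param impute_missing if `TRUE`, missing cells are replaced by the column
#'   mean (logged via `message()`); default `FALSE` rejects missing data.
#' @return A validated, unstandardized [trait_matrix()].
#' @export
load_trait_table <- function(path, dimension, sep = NULL, impute_missing = FALSE) {
  if (!file.exists(path)) stop_ns("trait table not found: ", path)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop_ns("empty or column-less trait table: ", path)
  }
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_ns("duplicated species id(s) in ", path, ": ",
            paste(unique(dup), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(ids, names(raw)[-1L]))
  for (j in seq_len(ncol(mat))) {
    cell <- raw[[j + 1L]]
    empty <- is.na(cell) | !nzchar(trimws(cell))
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !empty)
    if (length(bad)) {
      stop_ns("non-numeric value '", cell[bad[1L]], "' at species '",
              ids[bad[1L]], "', trait '", colnames(mat)[j], "' in ", path)
    }
    mat[, j] <- num
  }
  if (anyNA(mat)) {
    if (!impute_missing) {
      bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stop_ns("missing value at species '", rownames(mat)[bad[1L]],
              "', trait '", colnames(mat)[bad[2L]], "' in ", path,
              " (set impute_missing = TRUE to column-mean impute)")
    }
    n_imp <- sum(is.na(mat))
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (any(miss)) mat[miss, j] <- mean(mat[!miss, j])
    }
    message("load_trait_table: imputed ", n_imp, " missing cell(s) with column means in ", path)
  }
  trait_matrix(mat, dimension)
}

#' Write a trait matrix back to delimited text
#'
#' Inverse of [load_trait_table()]; `format = "%.17g"` round-trips doubles
#' bit-identically through text.
#'
#' @param tm a [trait_matrix()].
#' @param path output file; `.tsv` extension selects tab separation.
#' @param sep field separator; inferred from extension by default.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tm, path, sep = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(species_id = tm$species_ids,
                   apply(tm$values, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("species_id", tm$trait_names)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score the trait columns of a trait matrix
#'
#' Centers each trait to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1), matching a correlation-matrix PCA on the raw values.
#' Constant (zero-variance) traits cannot be scaled: they are centered,
#' flagged in `zero_variance`, and excluded from downstream ordination.
#'
#' @param tm an unstandardized [trait_matrix()] with at least 3 species.
#' @param tol standard deviations below `tol` count as zero variance.
#' @return A standardized [trait_matrix()].
#' @export
standardize <- function(tm, tol = 1e-12) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (tm$standardized) stop_ns("trait matrix is already standardized")
  n <- nrow(tm$values)
  if (n < 3L) stop_ns("standardize needs >= 3 species (sample SD unstable), got ", n)
  mu <- colMeans(tm$values)
  sd_ <- apply(tm$values, 2L, stats::sd)
  zero <- sd_ < tol
  vals <- sweep(tm$values, 2L, mu, "-")
  vals[, !zero] <- sweep(vals[, !zero, drop = FALSE], 2L, sd_[!zero], "/")
  trait_matrix(vals, tm$dimension, standardized = TRUE,
               zero_variance = tm$trait_names[zero])
}

#' Bundle per-dimension trait matrices into an assemblage
#'
#' An assemblage is a named list of [trait_matrix()] objects (2-5 niche
#' dimensions) sharing the same species in the same canonical order.
#'
#' @param tables list of trait matrices; names default to their dimensions.
#' @return An object of class `assemblage`.
#' @export
assemblage <- function(tables) {
  if (!length(tables) || !all(vapply(tables, inherits, logical(1), "trait_matrix"))) {
    stop_ns("'tables' must be a list of trait_matrix objects")
  }
  dims <- vapply(tables, function(t) t$dimension, character(1))
  if (anyDuplicated(dims)) stop_ns("duplicated niche dimensions: ",
                                   paste(dims[duplicated(dims)], collapse = ", "))
  if (length(tables) < 2L) stop_ns("an assemblage needs >= 2 niche dimensions")
  names(tables) <- dims
  ref <- tables[[1L]]$species_ids
  for (t in tables[-1L]) {
    if (!identical(t$species_ids, ref)) {
      stop_ns("species ids differ between dimensions '", dims[1L], "' and '",
              t$dimension, "'")
    }
  }
  structure(list(tables = tables, species_ids = ref), class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("<assemblage> %d species, %d niche dimensions (%d traits total)\n",
              length(x$species_ids), length(x$tables),
              sum(vapply(x$tables, function(t) length(t$trait_names), integer(1)))))
  for (t in x$tables) {
    cat(sprintf("  %-12s %d traits\n", t$dimension, length(t$trait_names)))
  }
  invisible(x)
}

#' Load an assemblage from a named set of trait-table paths
#'
#' @param paths named character vector, `dimension = path`.
#' @param ... passed to [load_trait_table()].
#' @return An [assemblage()].
#' @export
load_assemblage <- function(paths, ...) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop_ns("'paths' must be named by niche dimension")
  }
  assemblage(lapply(names(paths), function(d) load_trait_table(paths[[d]], d, ...)))
}

#' Per-species abundance statistics over repeated surveys
#'
#' Computes the mean and the coefficient of variation (CV = sample SD / mean,
#' denominator n - 1) of abundance across surveys, the response variables used
#' to evaluate niche axes. Species with zero mean abundance get an
#' undefined-CV flag (`NA`) rather than a number.
#'
#' @param abund numeric species x survey matrix (row names = species ids), or
#'   a data frame whose first column is `species_id`. Values must be >= 0;
#'   at least 2 surveys are required.
#' @return An object of class `response_table` with `species_ids`,
#'   `monthly_abundance`, `mean_abundance`, `cv_abundance`, `undefined_cv`.
#' @export
compute_response_stats <- function(abund) {
  if (is.data.frame(abund)) {
    ids <- as.character(abund[[1L]])
    abund <- as.matrix(abund[, -1L, drop = FALSE])
    rownames(abund) <- ids
  }
  if (!is.matrix(abund) || !is.numeric(abund)) {
    stop_ns("'abund' must be a numeric species x survey matrix")
  }
  if (is.null(rownames(abund))) stop_ns("abundance matrix needs species row names")
  if (ncol(abund) < 2L) stop_ns("need >= 2 surveys per species, got ", ncol(abund))
  if (anyNA(abund)) stop_ns("missing abundance values are not allowed")
  if (any(abund < 0)) {
    bad <- which(abund < 0, arr.ind = TRUE)[1L, ]
    stop_ns("negative abundance for species '", rownames(abund)[bad[1L]], "'")
  }
  abund <- abund[canonical_order(rownames(abund)), , drop = FALSE]
  m <- rowMeans(abund)
  s <- apply(abund, 1L, stats::sd)
  undef <- m == 0
  cv <- ifelse(undef, NA_real_, s / m)
  structure(
    list(species_ids = rownames(abund), monthly_abundance = abund,
         mean_abundance = unname(m), cv_abundance = unname(cv),
         undefined_cv = unname(undef)),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %d species x %d surveys (%d undefined CV)\n",
              length(x$species_ids), ncol(x$monthly_abundance),
              sum(x$undefined_cv)))
  invisible(x)
}

#' Read a species x survey abundance table
#'
#' @param path CSV/TSV with `species_id` first column, one column per survey.
#' @param sep field separator; inferred from extension by default.
#' @return A `response_table` (see [compute_response_stats()]).
#' @export
load_abundance_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_ns("abundance table not found: ", path)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  compute_response_stats(df)
}
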