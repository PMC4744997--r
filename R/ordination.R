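#' Principal component analysis of the correlation matrix
#'
#' Eigen-decomposes the Pearson correlation matrix of `X` and scores the
#' observations on the eigenvectors of z-scored data. Because the correlation
#' matrix has unit diagonal, the eigenvalues sum to the number of variables
#' and each eigenvalue equals the sample variance of its score column.
#'
#' Components are given a reproducible sign: each is oriented so its loading
#' of largest magnitude is positive (ties broken by lowest variable index).
#' Downstream comparisons should therefore use absolute correlations.
#'
#' @param X numeric observations x variables matrix (>= 3 observations,
#'   >= 2 variables, none constant).
#' @return An object of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (variables x components, unit columns), `scores`
#'   (observations x components), `prop_var`, `n_vars`, `n_obs`.
#' @export
pca_correlation <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_ns("'X' must be numeric")
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop_ns("pca_correlation needs >= 3 observations, got ", n)
  if (p < 2L) stop_ns("pca_correlation needs >= 2 variables, got ", p)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  sd_ <- apply(X, 2L, stats::sd)
  if (any(sd_ < 1e-12)) {
    stop_ns("constant variable(s): ",
            paste(colnames(X)[sd_ < 1e-12], collapse = ", "),
            " — standardize() flags and excludes these first")
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  vectors <- eg$vectors
  # sign convention: dominant loading positive, first index on (near-)ties
  for (j in seq_len(p)) {
    l <- vectors[, j]
    idx <- which(abs(l) >= max(abs(l)) - 1e-10)[1L]
    if (l[idx] < 0) vectors[, j] <- -l
  }
  dimnames(vectors) <- list(colnames(X), paste0("PC", seq_len(p)))
  scores <- Z %*% vectors
  rownames(scores) <- rownames(X)
  structure(
    list(eigenvalues = values, loadings = vectors, scores = scores,
         prop_var = values / sum(values), n_vars = p, n_obs = n),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, x$n_vars)
  cat(sprintf("<pca_result> %d obs x %d vars\n", x$n_obs, x$n_vars))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues[seq_len(k)]), collapse = " "),
      if (x$n_vars > k) "..." else "", "\n")
  cat("  prop. var. :", paste(sprintf("%.3f", x$prop_var[seq_len(k)]), collapse = " "),
      if (x$n_vars > k) "..." else "", "\n")
  invisible(x)
}

#' Ordinate one niche dimension
#'
#' Standardizes a trait matrix (dropping flagged zero-variance traits) and
#' runs [pca_correlation()], retaining the first `retained` components
#' (default 2, the dominant-axes convention for niche dimensions).
#'
#' @param tm a [trait_matrix()] (standardized or not).
#' @param retained number of components to retain (<= matrix rank).
#' @return An object of class `dimension_ordination`: `dimension`, `pca`,
#'   `retained`, `retained_scores`, `cum_prop_var` (cumulative proportion of
#'   variance of the retained components).
#' @export
ordinate_dimension <- function(tm, retained = 2L) {
  stopifnot(inherits(tm, "trait_matrix"))
  retained <- as.integer(retained)
  if (retained < 1L) stop_ns("'retained' must be >= 1")
  if (!tm$standardized) tm <- standardize(tm)
  keep <- setdiff(tm$trait_names, tm$zero_variance)
  if (length(keep) < 2L) {
    stop_ns("dimension '", tm$dimension, "' has < 2 non-constant traits")
  }
  pca <- pca_correlation(tm$values[, keep, drop = FALSE])
  rank_ <- sum(pca$eigenvalues > 1e-10)
  if (retained > rank_) {
    stop_ns("retained = ", retained, " exceeds rank ", rank_,
            " of dimension '", tm$dimension, "'")
  }
  structure(
    list(dimension = tm$dimension, pca = pca, retained = retained,
         retained_scores = pca$scores[, seq_len(retained), drop = FALSE],
         cum_prop_var = sum(pca$prop_var[seq_len(retained)])),
    class = "dimension_ordination"
  )
}

#' @export
print.dimension_ordination <- function(x, ...) {
  cat(sprintf("<dimension_ordination> '%s': %d PCs retained, %.1f%% of variance\n",
              x$dimension, x$retained, 100 * x$cum_prop_var))
  invisible(x)
}

#' Meta-ordination of per-dimension ordinations ("PCA of PCAs")
#'
#' Concatenates the retained component scores of each dimension ordination
#' into one block (species x sum of retained) and runs [pca_correlation()] on
#' it. The correlation-matrix PCA re-standardizes every input column, which is
#' what gives each niche dimension an equal chance to influence the overall
#' niche gradients regardless of its trait count or eigenvalue scale.
#'
#' @param ords list of [ordinate_dimension()] results sharing species order
#'   (>= 2 dimensions).
#' @return An object of class `meta_ordination`: `input_block`, `pca`,
#'   `dimensions`.
#' @export
meta_ordinate <- function(ords) {
  if (length(ords) < 2L ||
      !all(vapply(ords, inherits, logical(1), "dimension_ordination"))) {
    stop_ns("'ords' must be >= 2 dimension_ordination objects")
  }
  ids <- rownames(ords[[1L]]$retained_scores)
  blocks <- lapply(ords, function(o) {
    if (!identical(rownames(o$retained_scores), ids)) {
      stop_ns("species mismatch between dimensions '", ords[[1L]]$dimension,
              "' and '", o$dimension, "'")
    }
    s <- o$retained_scores
    colnames(s) <- paste0(o$dimension, ".", colnames(s))
    s
  })
  block <- do.call(cbind, blocks)
  structure(
    list(input_block = block, pca = pca_correlation(block),
         dimensions = vapply(ords, function(o) o$dimension, character(1))),
    class = "meta_ordination"
  )
}

#' @export
print.meta_ordination <- function(x, ...) {
  cat(sprintf("<meta_ordination> %d species, input block of %d axis scores (%s)\n",
              nrow(x$input_block), ncol(x$input_block),
              paste(x$dimensions, collapse = ", ")))
  print(x$pca)
  invisible(x)
}

#' Baseline ordination of all traits pooled across dimensions
#'
#' The single-stage alternative to [meta_ordinate()]: one correlation-matrix
#' PCA on the column-concatenation of every dimension's traits (the "raw"
#' all-traits analysis). Dimensions with many traits dominate this baseline,
#' which is exactly the imbalance the meta-ordination removes.
#'
#' @param asm an [assemblage()].
#' @return A [pca_correlation()] result on the pooled trait block.
#' @export
ordinate_raw <- function(asm) {
  stopifnot(inherits(asm, "assemblage"))
  blocks <- lapply(asm$tables, function(tm) {
    if (!tm$standardized) tm <- standardize(tm)
    keep <- setdiff(tm$trait_names, tm$zero_variance)
    v <- tm$values[, keep, drop = FALSE]
    colnames(v) <- paste0(tm$dimension, ".", keep)
    v
  })
  pca_correlation(do.call(cbind, blocks))
}
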