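#' Parse a newick string or file into a rooted phylogeny
#'
#' Wraps `ape::read.tree()` with an upfront structural check that reports the
#' character position of unbalanced parentheses or a missing terminal
#' semicolon. Polytomies are allowed.
#'
#' @param text newick string, or a path to a file containing one.
#' @return An `ape::phylo` object.
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(paste(text, collapse = ""))
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_ns("newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop_ns("newick parse error: ", depth, " unclosed '(' by position ", nchar(text))
  }
  if (!grepl(";\\s*$", text)) {
    stop_ns("newick parse error: missing ';' at position ", nchar(text))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop_ns("newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop_ns("newick parse error: unreadable tree")
  if (anyDuplicated(phy$tip.label)) {
    stop_ns("duplicated tip label(s): ",
            paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  phy
}

#' Restrict a phylogeny to assemblage species
#'
#' Tips absent from `species_ids` are pruned with a warning; an error is
#' raised if fewer than 2 tips remain.
#'
#' @param phy an `ape::phylo`.
#' @param species_ids character vector of assemblage species.
#' @return The pruned `phylo`.
#' @export
prune_to_assemblage <- function(phy, species_ids) {
  extra <- setdiff(phy$tip.label, species_ids)
  if (length(extra)) {
    warning("pruning ", length(extra), " tip(s) absent from the assemblage: ",
            paste(extra, collapse = ", "), call. = FALSE)
    phy <- ape::drop.tip(phy, extra)
    if (is.null(phy) || length(phy$tip.label) < 2L) {
      stop_ns("fewer than 2 tips remain after pruning")
    }
  }
  phy
}

#' Ancestral node positions by squared-change parsimony
#'
#' Places every internal node of the phylogeny in niche space so as to
#' minimize the sum over edges of squared change, per axis independently
#' (tips are fixed at their ordination scores). The minimizer satisfies a
#' linear system in which each internal node sits at the (weighted) mean of
#' its neighbours; it is solved directly. With `weighted = TRUE` each edge's
#' squared change is divided by its branch length.
#'
#' @param phy an `ape::phylo` whose tip labels all appear in `tip_scores`.
#' @param tip_scores numeric matrix (species x axes) with row names; for the
#'   usual projection, the first two meta-ordination score columns.
#' @param weighted divide squared changes by branch lengths (default
#'   `FALSE`, equal-weight parsimony).
#' @return Numeric matrix ((n_tips + n_internal) x axes) of node positions in
#'   ape node order (tips first), row names = tip labels then `node_<id>`.
#' @export
ancestral_scores <- function(phy, tip_scores, weighted = FALSE) {
  stopifnot(inherits(phy, "phylo"))
  tip_scores <- as.matrix(tip_scores)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (nnode < 1L) stop_ns("tree has no internal nodes")
  missing_ <- setdiff(phy$tip.label, rownames(tip_scores))
  if (length(missing_)) {
    stop_ns("tips without scores: ", paste(missing_, collapse = ", "))
  }
  root_children <- sum(phy$edge[, 1L] == ntip + 1L)
  if (root_children < 2L) stop_ns("unresolved root with < 2 children")
  w <- rep(1, nrow(phy$edge))
  if (weighted) {
    if (is.null(phy$edge.length)) stop_ns("weighted = TRUE needs branch lengths")
    if (any(phy$edge.length <= 0)) stop_ns("weighted = TRUE needs positive branch lengths")
    w <- 1 / phy$edge.length
  }
  k <- ncol(tip_scores)
  tipx <- tip_scores[phy$tip.label, , drop = FALSE]
  A <- matrix(0, nnode, nnode)
  B <- matrix(0, nnode, k)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L] - ntip  # parent is always internal
    ch <- phy$edge[e, 2L]
    A[p, p] <- A[p, p] + w[e]
    if (ch > ntip) {
      q <- ch - ntip
      A[q, q] <- A[q, q] + w[e]
      A[p, q] <- A[p, q] - w[e]
      A[q, p] <- A[q, p] - w[e]
    } else {
      B[p, ] <- B[p, ] + w[e] * tipx[ch, ]
    }
  }
  internal <- solve(A, B)
  out <- rbind(tipx, internal)
  rownames(out) <- c(phy$tip.label, paste0("node_", ntip + seq_len(nnode)))
  colnames(out) <- colnames(tip_scores)
  out
}

#' Niche branch lengths of a projected phylogeny
#'
#' Euclidean distance in the projection plane between the two ends of each
#' edge — the "niche branch length" drawn when a phylogeny is overlaid on a
#' continuous niche scheme.
#'
#' @param phy an `ape::phylo`.
#' @param node_scores matrix from [ancestral_scores()] (ape node order).
#' @return Numeric vector, one length per row of `phy$edge`, named
#'   `"parent->child"` using node-order row names of `node_scores`.
#' @export
niche_branch_lengths <- function(phy, node_scores) {
  stopifnot(inherits(phy, "phylo"))
  if (nrow(node_scores) != length(phy$tip.label) + phy$Nnode) {
    stop_ns("node_scores must cover every tip and internal node")
  }
  d <- sqrt(rowSums((node_scores[phy$edge[, 1L], , drop = FALSE] -
                       node_scores[phy$edge[, 2L], , drop = FALSE])^2))
  names(d) <- paste0(rownames(node_scores)[phy$edge[, 1L]], "->",
                     rownames(node_scores)[phy$edge[, 2L]])
  d
}

#' Project a phylogeny into a continuous niche scheme
#'
#' Convenience wrapper: prunes the tree to the assemblage, fixes tips at the
#' first two meta-ordination scores, reconstructs ancestral positions by
#' squared-change parsimony and computes niche branch lengths.
#'
#' @param phy an `ape::phylo` (tips = species ids; extras pruned with warning).
#' @param meta a [meta_ordinate()] result.
#' @param axes which meta components span the plane (default `1:2`).
#' @param weighted passed to [ancestral_scores()].
#' @return An object of class `niche_projection`: `tree`, `node_scores`,
#'   `branch_lengths`, `total_length`.
#' @export
project_phylogeny <- function(phy, meta, axes = 1:2, weighted = FALSE) {
  stopifnot(inherits(meta, "meta_ordination"))
  scores <- meta$pca$scores[, axes, drop = FALSE]
  phy <- prune_to_assemblage(phy, rownames(scores))
  absent <- setdiff(phy$tip.label, rownames(scores))
  if (length(absent)) stop_ns("tips without meta scores: ", paste(absent, collapse = ", "))
  ns <- ancestral_scores(phy, scores[phy$tip.label, , drop = FALSE], weighted = weighted)
  bl <- niche_branch_lengths(phy, ns)
  structure(
    list(tree = phy, node_scores = ns, branch_lengths = bl,
         total_length = sum(bl)),
    class = "niche_projection"
  )
}

#' @export
print.niche_projection <- function(x, ...) {
  cat(sprintf("<niche_projection> %d tips, %d internal nodes; total niche branch length %.4g\n",
              length(x$tree$tip.label), x$tree$Nnode, x$total_length))
  invisible(x)
}
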