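# Independent oracles, deliberately implemented with different machinery than
# the package code paths they check.

# eigenvalues of the correlation-matrix PCA via SVD of the z-scored data
oracle_pca_eigen <- function(X) {
  Z <- scale(X)
  svd(Z, nu = 0, nv = 0)$d^2 / (nrow(X) - 1)
}

# naive exhaustive best split: double loop, mean-based SS, same tie rules
# (lower predictor index, then lower threshold, strict improvement)
oracle_best_split <- function(X, Y, minbucket = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  ss <- function(M) if (nrow(M) == 0L) 0 else sum(sweep(M, 2L, colMeans(M))^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1L]) / 2) {
      left <- X[, j] < t
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      red <- ss(Y) - ss(Y[left, , drop = FALSE]) - ss(Y[!left, , drop = FALSE])
      if (is.null(best) || red > best$reduction + 1e-12) {
        best <- list(var_index = j, threshold = t, reduction = red)
      }
    }
  }
  best
}

# recursive exhaustive grower mirroring the documented stopping rules;
# returns the leaf partition as a list of row-index vectors in depth-first
# left-to-right order
oracle_grow_partition <- function(X, Y, minsplit, minbucket, cp_min,
                                  max_depth = 30L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  ss <- function(M) sum(sweep(M, 2L, colMeans(M))^2)
  root_dev <- ss(Y)
  rec <- function(idx, depth) {
    Yn <- Y[idx, , drop = FALSE]
    if (length(idx) < minsplit || depth >= max_depth ||
        ss(Yn) <= 1e-12 * max(1, root_dev)) {
      return(list(idx))
    }
    s <- oracle_best_split(X[idx, , drop = FALSE], Yn, minbucket)
    if (is.null(s) || s$reduction < cp_min * root_dev) return(list(idx))
    left <- X[idx, s$var_index] < s$threshold
    c(rec(idx[left], depth + 1L), rec(idx[!left], depth + 1L))
  }
  rec(seq_len(nrow(X)), 0L)
}

# leaf partition of a fitted regression_tree, in the same order
tree_partition <- function(tree, X) {
  g <- assign_groups(tree, X)
  unname(split(seq_len(nrow(X)), g))
}

# squared-change parsimony objective for an ape tree
parsimony_cost <- function(phy, node_scores, weights = NULL) {
  w <- weights %||% rep(1, nrow(phy$edge))
  d2 <- rowSums((node_scores[phy$edge[, 1L], , drop = FALSE] -
                   node_scores[phy$edge[, 2L], , drop = FALSE])^2)
  sum(w * d2)
}

# direct numerical minimisation of the squared-change objective over the
# internal-node coordinates (BFGS, numeric gradient)
oracle_parsimony <- function(phy, tipx, weighted = FALSE) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  k <- ncol(tipx)
  w <- if (weighted) 1 / phy$edge.length else rep(1, nrow(phy$edge))
  obj <- function(par) {
    ns <- rbind(tipx[phy$tip.label, , drop = FALSE],
                matrix(par, nnode, k))
    parsimony_cost(phy, ns, w)
  }
  init <- matrix(colMeans(tipx), nnode, k, byrow = TRUE)
  fit <- stats::optim(as.vector(init), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  matrix(fit$par, nnode, k)
}

# Gauss-Seidel iteration of the neighbour-mean fixed point
oracle_parsimony_iter <- function(phy, tipx, weighted = FALSE, tol = 1e-13) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  k <- ncol(tipx)
  w <- if (weighted) 1 / phy$edge.length else rep(1, nrow(phy$edge))
  x <- rbind(tipx[phy$tip.label, , drop = FALSE],
             matrix(colMeans(tipx), nnode, k, byrow = TRUE))
  for (iter in 1:100000) {
    delta <- 0
    for (v in ntip + seq_len(nnode)) {
      inc <- phy$edge[, 1L] == v | phy$edge[, 2L] == v
      nbr <- ifelse(phy$edge[inc, 1L] == v, phy$edge[inc, 2L], phy$edge[inc, 1L])
      new <- colSums(w[inc] * x[nbr, , drop = FALSE]) / sum(w[inc])
      delta <- max(delta, max(abs(new - x[v, ])))
      x[v, ] <- new
    }
    if (delta < tol) break
  }
  x[ntip + seq_len(nnode), , drop = FALSE]
}
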