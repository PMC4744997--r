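#' Growth and pruning parameters for multivariate regression trees
#'
#' Defaults are scaled to assemblage-sized data (tens of species): `minsplit`
#' observations to attempt a split, `minbucket` per terminal node, `cp_min`
#' minimum relative deviance improvement for a split (relative to the root
#' deviance), `max_depth` recursion cap, `cv_folds` for cross-validated
#' pruning, `seed` controlling fold assignment.
#'
#' @param minsplit integer >= 2 * minbucket.
#' @param minbucket integer >= 1.
#' @param cp_min non-negative relative improvement threshold.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(minsplit = 10L, minbucket = 3L, cp_min = 0.01,
                          max_depth = 10L, cv_folds = 10L, seed = 1L) {
  minsplit <- as.integer(minsplit); minbucket <- as.integer(minbucket)
  if (minbucket < 1L) stop_ns("minbucket must be >= 1")
  if (minsplit < 2L * minbucket) stop_ns("minsplit must be >= 2 * minbucket")
  if (cp_min < 0) stop_ns("cp_min must be >= 0")
  structure(list(minsplit = minsplit, minbucket = minbucket, cp_min = cp_min,
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "growth_params")
}

check_xy <- function(X, Y) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L, dimnames = list(NULL, "y"))
  Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y)) stop_ns("X and Y must be numeric")
  if (nrow(X) != nrow(Y)) {
    stop_ns("row mismatch: X has ", nrow(X), " rows, Y has ", nrow(Y))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  list(X = X, Y = Y)
}

node_deviance <- function(Y) {
  # within-node sum of squared deviations from column means, summed over
  # response columns (the multivariate CART impurity)
  sum(Y^2) - sum(colSums(Y)^2) / nrow(Y)
}

#' Best single split of a node, exhaustive search
#'
#' Scans every predictor and every midpoint between consecutive distinct
#' sorted values, maximizing the reduction in total within-node sum of squares
#' summed across response columns. Ties are broken toward the lower predictor
#' index, then the lower threshold, so results are deterministic. Left child
#' is `value < threshold`.
#'
#' @param X numeric predictor matrix at the node.
#' @param Y numeric response matrix (columns = responses) at the node.
#' @param minsplit minimum node size to attempt a split.
#' @param minbucket minimum child size.
#' @return `list(var, var_index, threshold, reduction)` or `NULL` when no
#'   admissible split exists.
#' @export
best_split <- function(X, Y, minsplit = 2L, minbucket = 1L) {
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  n <- nrow(X)
  if (n < minsplit || n < 2L * minbucket) return(NULL)
  ss_total <- node_deviance(Y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]
    Ys <- Y[o, , drop = FALSE]
    cut_ok <- seq_len(n - 1L) >= minbucket & (n - seq_len(n - 1L)) >= minbucket &
      xs[-n] < xs[-1L]
    if (!any(cut_ok)) next
    cum <- apply(Ys, 2L, cumsum)
    cumsq <- apply(Ys^2, 2L, cumsum)
    if (is.null(dim(cum))) { cum <- matrix(cum, ncol = ncol(Y)); cumsq <- matrix(cumsq, ncol = ncol(Y)) }
    tot <- cum[n, ]; totsq_sum <- sum(cumsq[n, ])
    i <- seq_len(n - 1L)
    left_ss <- rowSums(cumsq[i, , drop = FALSE]) -
      rowSums(cum[i, , drop = FALSE]^2) / i
    right_cnt <- n - i
    right_sum_sq <- rowSums(sweep(-cum[i, , drop = FALSE], 2L, tot, "+")^2)
    right_ss <- (totsq_sum - rowSums(cumsq[i, , drop = FALSE])) -
      right_sum_sq / right_cnt
    red <- ss_total - left_ss - right_ss
    red[!cut_ok] <- -Inf
    k <- which.max(red)  # first max: lowest threshold wins ties
    if (is.finite(red[k]) && (is.null(best) || red[k] > best$reduction + 1e-12)) {
      best <- list(var = colnames(X)[j], var_index = j,
                   threshold = unname((xs[k] + xs[k + 1L]) / 2),
                   reduction = unname(red[k]))
    }
  }
  best
}

new_leaf <- function(Y, depth) {
  list(n = nrow(Y), response_mean = colMeans(Y), deviance = node_deviance(Y),
       depth = depth, split_var = NULL, split_threshold = NULL,
       improve = NULL, left = NULL, right = NULL)
}

grow_node <- function(X, Y, params, depth, root_dev) {
  node <- new_leaf(Y, depth)
  if (node$n < params$minsplit || depth >= params$max_depth ||
      node$deviance <= 1e-12 * max(1, root_dev)) {
    return(node)
  }
  s <- best_split(X, Y, minsplit = params$minsplit, minbucket = params$minbucket)
  if (is.null(s) || s$reduction < params$cp_min * root_dev) return(node)
  go_left <- X[, s$var_index] < s$threshold
  node$split_var <- s$var
  node$split_threshold <- s$threshold
  node$improve <- s$reduction
  node$left <- grow_node(X[go_left, , drop = FALSE], Y[go_left, , drop = FALSE],
                         params, depth + 1L, root_dev)
  node$right <- grow_node(X[!go_left, , drop = FALSE], Y[!go_left, , drop = FALSE],
                          params, depth + 1L, root_dev)
  node
}

is_leaf <- function(node) is.null(node$left)

subtree_leaves <- function(node) {
  if (is_leaf(node)) 1L else subtree_leaves(node$left) + subtree_leaves(node$right)
}

subtree_risk <- function(node) {
  if (is_leaf(node)) node$deviance else subtree_risk(node$left) + subtree_risk(node$right)
}

# weakest-link criterion of an internal node, in units of the root deviance
node_g <- function(node, root_dev) {
  (node$deviance - subtree_risk(node)) / (subtree_leaves(node) - 1L) / root_dev
}

min_g <- function(node, root_dev) {
  if (is_leaf(node)) return(Inf)
  min(node_g(node, root_dev),
      min_g(node$left, root_dev), min_g(node$right, root_dev))
}

collapse_at <- function(node, gmax, root_dev, tol = 1e-12) {
  if (is_leaf(node)) return(node)
  if (node_g(node, root_dev) <= gmax + tol) {
    node$split_var <- NULL; node$split_threshold <- NULL; node$improve <- NULL
    node$left <- NULL; node$right <- NULL
    return(node)
  }
  node$left <- collapse_at(node$left, gmax, root_dev, tol)
  node$right <- collapse_at(node$right, gmax, root_dev, tol)
  node
}

# nested cost-complexity sequence: trees[[1]] is the full tree (optimal for
# cp = alphas[1] = cp_min), each subsequent tree collapses the weakest links
weakest_link_sequence <- function(root, root_dev, cp_min) {
  trees <- list(root)
  alphas <- cp_min
  cur <- root
  while (!is_leaf(cur)) {
    g <- min_g(cur, root_dev)
    cur <- collapse_at(cur, g, root_dev)
    trees[[length(trees) + 1L]] <- cur
    alphas <- c(alphas, g)
  }
  # degenerate numerical orderings collapse to monotone alphas
  alphas <- cummax(alphas)
  list(trees = trees, alphas = alphas)
}

make_cp_table <- function(seq_, root_dev) {
  data.frame(
    cp = seq_$alphas,
    n_leaves = vapply(seq_$trees, subtree_leaves, integer(1)),
    rel_error = vapply(seq_$trees, subtree_risk, numeric(1)) / root_dev
  )
}

#' Grow a multivariate-response regression tree
#'
#' Recursive binary splitting on original predictor values, minimizing the
#' within-node sum of squares summed over all response columns (for niche
#' dimensions: the retained PC scores). Growth stops at `minsplit`,
#' `minbucket`, `max_depth`, or when the best split improves the total
#' deviance by less than `cp_min` of the root deviance. The cost-complexity
#' (weakest-link) pruning sequence is computed on the training data and
#' stored as `cp_table`.
#'
#' @param X numeric predictor matrix (species x traits).
#' @param Y numeric response matrix (species x responses) or vector.
#' @param params a [growth_params()].
#' @return An object of class `regression_tree`: `root`, `root_deviance`,
#'   `cp_table`, `params`, `predictor_names`, `response_names`.
#' @export
grow_tree <- function(X, Y, params = growth_params()) {
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  root_dev <- node_deviance(Y)
  root <- if (root_dev <= 0) new_leaf(Y, 0L) else grow_node(X, Y, params, 0L, root_dev)
  seq_ <- weakest_link_sequence(root, max(root_dev, .Machine$double.eps), params$cp_min)
  structure(
    list(root = root, root_deviance = root_dev,
         cp_table = make_cp_table(seq_, max(root_dev, .Machine$double.eps)),
         params = params, predictor_names = colnames(X),
         response_names = colnames(Y), n = nrow(X)),
    class = "regression_tree"
  )
}

#' Number of terminal nodes of a regression tree
#' @param tree a `regression_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) subtree_leaves(tree$root)

#' Prune a regression tree at a cost-complexity value
#'
#' Collapses every weakest link whose criterion does not exceed `cp`
#' (in root-deviance units), returning the member of the nested pruning
#' sequence optimal at that complexity.
#'
#' @param tree a `regression_tree`.
#' @param cp cost-complexity threshold.
#' @return A pruned `regression_tree` (cp_table preserved).
#' @export
prune_tree <- function(tree, cp) {
  root_dev <- max(tree$root_deviance, .Machine$double.eps)
  root <- tree$root
  while (!is_leaf(root) && min_g(root, root_dev) <= cp + 1e-12) {
    root <- collapse_at(root, min_g(root, root_dev), root_dev)
  }
  out <- tree
  out$root <- root
  out
}

route_rows <- function(node, X) {
  # returns the terminal node (list) index path per row via recursive split
  assign_rec <- function(node, idx, out_env) {
    if (is_leaf(node)) {
      out_env$counter <- out_env$counter + 1L
      out_env$groups[idx] <- out_env$counter
      out_env$means[[out_env$counter]] <- node$response_mean
      return(invisible(NULL))
    }
    go_left <- X[idx, node$split_var] < node$split_threshold
    assign_rec(node$left, idx[go_left], out_env)
    assign_rec(node$right, idx[!go_left], out_env)
  }
  env <- new.env()
  env$counter <- 0L
  env$groups <- integer(nrow(X))
  env$means <- list()
  assign_rec(node, seq_len(nrow(X)), env)
  list(groups = env$groups, means = env$means)
}

tree_vars <- function(node) {
  if (is_leaf(node)) return(character())
  unique(c(node$split_var, tree_vars(node$left), tree_vars(node$right)))
}

#' Route species to terminal-node groups
#'
#' Each observation follows the split rules (`value < threshold` goes left) to
#' exactly one leaf. Leaves are numbered depth-first, left before right, so
#' group labels match the dendrogram reading order used in niche codes.
#'
#' @param tree a (typically pruned) `regression_tree`.
#' @param X predictor matrix containing every trait the tree splits on.
#' @return Integer group labels in `1..n_leaves(tree)`, named by row names.
#' @export
assign_groups <- function(tree, X) {
  X <- as.matrix(X)
  need <- tree_vars(tree$root)
  missing_ <- setdiff(need, colnames(X))
  if (length(missing_)) {
    stop_ns("X lacks split variable(s): ", paste(missing_, collapse = ", "))
  }
  g <- route_rows(tree$root, X)$groups
  names(g) <- rownames(X)
  g
}

#' Predict leaf response means
#'
#' @param object a `regression_tree`.
#' @param newdata predictor matrix.
#' @param ... unused.
#' @return Matrix (rows of `newdata` x response columns) of leaf means.
#' @export
predict.regression_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  r <- route_rows(object$root, X)
  out <- do.call(rbind, r$means)[r$groups, , drop = FALSE]
  rownames(out) <- rownames(X)
  colnames(out) <- object$response_names
  out
}

#' Cross-validated cost-complexity pruning with the 1-SE rule
#'
#' Estimates the cross-validated relative error of each member of the
#' weakest-link pruning sequence by K-fold cross-validation (folds drawn from
#' `params$seed`; each fold's tree is grown and pruned on the training part,
#' held-out squared error accumulated per observation). Selects the largest
#' complexity whose CV error does not exceed the minimum CV error plus one
#' standard error of that minimum (the 1-SE rule) and returns the main tree
#' pruned at that complexity.
#'
#' @param tree a `regression_tree` from [grow_tree()].
#' @param X,Y the training data the tree was grown from.
#' @param params a [growth_params()]; defaults to the tree's own.
#' @return A pruned `regression_tree`; `cp_table` gains `xerror` and `xstd`
#'   columns, and `selected_cp` records the 1-SE choice.
#' @export
cv_prune_1se <- function(tree, X, Y, params = tree$params) {
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  n <- nrow(X)
  K <- params$cv_folds
  if (n < K) {
    stop_ns("n = ", n, " observations < cv_folds = ", K,
            "; use fewer folds")
  }
  root_dev <- max(tree$root_deviance, .Machine$double.eps)
  seq_main <- weakest_link_sequence(tree$root, root_dev, params$cp_min)
  m <- length(seq_main$alphas)
  # evaluation complexities: geometric means of adjacent thresholds
  a <- seq_main$alphas
  betas <- c(sqrt(a[-m] * a[-1L]), Inf)
  if (m == 1L) betas <- Inf

  folds <- with_seed(params$seed, sample(rep_len(seq_len(K), n)))
  E <- matrix(0, n, m)
  for (k in seq_len(K)) {
    test <- folds == k
    ft <- grow_tree(X[!test, , drop = FALSE], Y[!test, , drop = FALSE], params)
    fdev <- max(ft$root_deviance, .Machine$double.eps)
    fseq <- weakest_link_sequence(ft$root, fdev, params$cp_min)
    for (j in seq_len(m)) {
      sel <- max(which(fseq$alphas <= betas[j] + 1e-12), 1L)
      r <- route_rows(fseq$trees[[sel]], X[test, , drop = FALSE])
      pred <- do.call(rbind, r$means)[r$groups, , drop = FALSE]
      E[test, j] <- rowSums((Y[test, , drop = FALSE] - pred)^2)
    }
  }
  xerror <- colSums(E) / root_dev
  xstd <- apply(E, 2L, stats::sd) * sqrt(n) / root_dev
  best <- which.min(xerror)
  ok <- xerror <= xerror[best] + xstd[best]
  sel <- max(which(ok))  # largest cp (fewest leaves) within 1 SE
  out <- tree
  out$root <- seq_main$trees[[sel]]
  out$cp_table <- cbind(make_cp_table(seq_main, root_dev),
                        xerror = xerror, xstd = xstd)
  out$selected_cp <- seq_main$alphas[sel]
  out$pruned <- TRUE
  out
}

node_outline <- function(node, indent = "") {
  if (is_leaf(node)) {
    return(sprintf("%s* leaf n=%d dev=%.4g mean=(%s)\n", indent, node$n,
                   node$deviance,
                   paste(sprintf("%.3g", node$response_mean), collapse = ", ")))
  }
  paste0(
    sprintf("%s%s < %.6g ? n=%d dev=%.4g\n", indent, node$split_var,
            node$split_threshold, node$n, node$deviance),
    node_outline(node$left, paste0(indent, "  ")),
    node_outline(node$right, paste0(indent, "  "))
  )
}

#' @export
print.regression_tree <- function(x, ...) {
  cat(sprintf("<regression_tree> n=%d, %d responses (%s), %d leaves%s\n",
              x$n, length(x$response_names),
              paste(x$response_names, collapse = ", "), n_leaves(x),
              if (isTRUE(x$pruned)) sprintf(", pruned at cp=%.4g", x$selected_cp) else ""))
  cat(node_outline(x$root))
  invisible(x)
}

#' Fit and prune a niche-dimension tree
#'
#' Convenience wrapper for the per-dimension clustering step: responses are
#' the dimension's retained PC scores, predictors are its original
#' (unstandardized) trait values, and the tree is grown then pruned by
#' [cv_prune_1se()]. With `mode = "per_axis"`, one univariate tree is fit per
#' retained component instead (a list is returned).
#'
#' @param tm the dimension's [trait_matrix()] (raw values used as predictors).
#' @param ord the matching [ordinate_dimension()] result.
#' @param params a [growth_params()].
#' @param mode `"multivariate"` (one tree, summed SS over score columns;
#'   default) or `"per_axis"`.
#' @return A pruned `regression_tree`, or a list of them for `"per_axis"`.
#' @export
niche_tree <- function(tm, ord, params = growth_params(),
                       mode = c("multivariate", "per_axis")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tm, "trait_matrix"), inherits(ord, "dimension_ordination"))
  if (!identical(tm$species_ids, rownames(ord$retained_scores))) {
    stop_ns("species mismatch between trait matrix and ordination for '",
            tm$dimension, "'")
  }
  X <- tm$values
  fit1 <- function(Y) cv_prune_1se(grow_tree(X, Y, params), X, Y, params)
  if (mode == "multivariate") {
    fit1(ord$retained_scores)
  } else {
    lapply(seq_len(ncol(ord$retained_scores)), function(j) {
      fit1(ord$retained_scores[, j, drop = FALSE])
    })
  }
}
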