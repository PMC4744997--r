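toy_X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                dimnames = list(sprintf("s%d", 1:6), "size"))
toy_Y <- c(0, 0, 0, 5, 5, 5)

test_that("best_split finds the hand-computed optimum", {
  s <- best_split(toy_X, toy_Y, minsplit = 2, minbucket = 1)
  expect_equal(s$threshold, 6.5)
  expect_equal(s$reduction, 37.5)   # root SS = 6 * 2.5^2, children pure
  expect_identical(s$var, "size")

  # additivity over response columns: duplicated response doubles the gain
  s2 <- best_split(toy_X, cbind(toy_Y, toy_Y), minsplit = 2, minbucket = 1)
  expect_equal(s2$threshold, 6.5)
  expect_equal(s2$reduction, 75)

  # no admissible split on a constant predictor
  expect_null(best_split(matrix(rep(1, 6), ncol = 1), toy_Y,
                         minsplit = 2, minbucket = 1))
})

test_that("best_split equals the brute-force oracle on random fixtures", {
  for (seed in 1:12) {
    n <- 8
    X <- with_seed_local(seed, matrix(rnorm(n * 2), n, 2,
                                      dimnames = list(NULL, c("a", "b"))))
    Y <- with_seed_local(seed + 100, matrix(rnorm(n * 2), n, 2))
    for (mb in c(1L, 2L)) {
      mine <- best_split(X, Y, minsplit = 2, minbucket = mb)
      orac <- oracle_best_split(X, Y, minbucket = mb)
      expect_equal(mine$var_index, orac$var_index)
      expect_equal(mine$threshold, orac$threshold)
      expect_equal(mine$reduction, orac$reduction, tolerance = 1e-10)
    }
  }
})

test_that("grow_tree basics: constant response, planted split, root deviance", {
  gp <- growth_params(minsplit = 2, minbucket = 1, cp_min = 0.01, seed = 1)
  t0 <- grow_tree(toy_X, rep(2, 6), gp)
  expect_equal(n_leaves(t0), 1L)

  t1 <- grow_tree(toy_X, toy_Y, gp)
  expect_equal(n_leaves(t1), 2L)
  expect_identical(t1$root$split_var, "size")
  expect_equal(t1$root_deviance, sum((toy_Y - mean(toy_Y))^2))

  expect_error(grow_tree(toy_X, c(1, 2)), "row mismatch")
})

test_that("grow_tree equals the exhaustive recursive oracle on small fixtures", {
  gp <- growth_params(minsplit = 4, minbucket = 2, cp_min = 0, max_depth = 30,
                      seed = 1)
  for (seed in 1:10) {
    n <- sample(6:12, 1)
    p <- sample(1:3, 1)
    X <- with_seed_local(seed * 3, matrix(rnorm(n * p), n, p,
                                          dimnames = list(NULL, letters[seq_len(p)])))
    Y <- with_seed_local(seed * 3 + 1, matrix(rnorm(n * 2), n, 2))
    tr <- grow_tree(X, Y, gp)
    expect_identical(
      tree_partition(tr, X),
      oracle_grow_partition(X, Y, minsplit = 4, minbucket = 2, cp_min = 0)
    )
  }
})

test_that("assign_groups routes deterministically and partitions", {
  gp <- growth_params(minsplit = 2, minbucket = 1, seed = 1)
  t1 <- grow_tree(toy_X, toy_Y, gp)
  expect_equal(unname(assign_groups(t1, toy_X)), c(1, 1, 1, 2, 2, 2))

  t0 <- grow_tree(toy_X, rep(1, 6), gp)
  expect_equal(unname(assign_groups(t0, toy_X)), rep(1L, 6))

  # partition: every observation in exactly one group, labels 1..n_leaves
  sim <- simulate_assemblage(peak_world(5, 40L, 3L))
  tm <- sim$assemblage$tables$habitat
  tr <- niche_tree(tm, ordinate_dimension(tm))
  g <- assign_groups(tr, tm$values)
  expect_length(g, 40L)
  expect_setequal(unique(g), seq_len(n_leaves(tr)))

  expect_error(assign_groups(t1, matrix(1, 2, 1, dimnames = list(NULL, "zz"))),
               "lacks split variable")
})

test_that("cv_prune_1se: degenerate input, errors, determinism", {
  gp <- growth_params(minsplit = 2, minbucket = 1, cv_folds = 5, seed = 7)
  t0 <- grow_tree(toy_X, rep(2, 6), gp)
  p0 <- cv_prune_1se(t0, toy_X, rep(2, 6), gp)
  expect_equal(n_leaves(p0), 1L)

  sim <- simulate_assemblage(peak_world(3, 40L, 3L))
  tm <- sim$assemblage$tables$habitat
  ord <- ordinate_dimension(tm)
  tr <- grow_tree(tm$values, ord$retained_scores)
  a <- cv_prune_1se(tr, tm$values, ord$retained_scores)
  b <- cv_prune_1se(tr, tm$values, ord$retained_scores)
  expect_identical(a$cp_table, b$cp_table)          # seed determinism
  expect_identical(a$selected_cp, b$selected_cp)

  small <- growth_params(cv_folds = 50, seed = 1)
  expect_error(cv_prune_1se(tr, tm$values, ord$retained_scores, small),
               "fewer folds")
})

test_that("pruning is monotone and 1-SE never exceeds the min-CV tree", {
  for (seed in c(2, 9, 17)) {
    sim <- simulate_assemblage(peak_world(seed, 45L, 3L))
    tm <- sim$assemblage$tables$habitat
    ord <- ordinate_dimension(tm)
    tr <- grow_tree(tm$values, ord$retained_scores)
    pr <- cv_prune_1se(tr, tm$values, ord$retained_scores)
    ct <- pr$cp_table
    expect_true(all(diff(ct$cp) >= -1e-12))          # cp non-decreasing
    expect_true(all(diff(ct$n_leaves) <= 0))         # leaves non-increasing
    expect_true(all(diff(ct$rel_error) >= -1e-12))
    min_cv_leaves <- ct$n_leaves[which.min(ct$xerror)]
    expect_lte(n_leaves(pr), min_cv_leaves)
    # the selected tree is a member of the nested sequence
    expect_true(n_leaves(pr) %in% ct$n_leaves)
  }
})

test_that("duplicating a response column changes neither splits nor pruning", {
  sim <- simulate_assemblage(peak_world(4, 40L, 3L))
  tm <- sim$assemblage$tables$habitat
  ord <- ordinate_dimension(tm)
  Y <- ord$retained_scores
  Y2 <- cbind(Y, Y)
  gp <- growth_params(seed = 5)
  a <- cv_prune_1se(grow_tree(tm$values, Y, gp), tm$values, Y, gp)
  b <- cv_prune_1se(grow_tree(tm$values, Y2, gp), tm$values, Y2, gp)
  expect_identical(tree_partition(a, tm$values), tree_partition(b, tm$values))
  expect_equal(a$cp_table$cp, b$cp_table$cp, tolerance = 1e-10)
})

test_that("well-separated planted clusters are usually recovered exactly", {
  # light version of the acceptance calibration (20 seeds); the full
  # 100-seed criterion lives in test-acceptance.R
  leaves <- vapply(1:20, function(seed) {
    sim <- simulate_assemblage(peak_world(seed, 60L, 4L))
    tm <- sim$assemblage$tables$habitat
    n_leaves(niche_tree(tm, ordinate_dimension(tm)))
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(leaves)))), 4L)  # modal = truth
  expect_gte(mean(leaves == 4L), 0.5)
  expect_true(all(leaves >= 3L & leaves <= 8L))
})
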