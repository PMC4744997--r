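test_that("pca_correlation handles degenerate correlation structures", {
  # two perfectly correlated variables: rank 1
  x <- c(1, 2, 3, 4)
  p1 <- pca_correlation(cbind(a = x, b = 2 * x + 1))
  expect_equal(p1$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p1$prop_var[1], 1)

  # exactly uncorrelated variables: identity correlation matrix
  p2 <- pca_correlation(cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)))
  expect_equal(p2$eigenvalues, c(1, 1))

  expect_error(pca_correlation(cbind(a = 1:5, b = rep(2, 5))), "standardize")
  expect_error(pca_correlation(matrix(1:4, 2, 2)), ">= 3 observations")
})

test_that("pca_correlation matches an independent SVD oracle and its invariants", {
  for (seed in 1:5) {
    X <- with_seed_local(seed, matrix(rnorm(18), 6, 3))
    colnames(X) <- c("a", "b", "c")
    p <- pca_correlation(X)
    expect_equal(p$eigenvalues, oracle_pca_eigen(X), tolerance = 1e-8)
    expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-8)
    # unit-norm loadings, score variance = eigenvalue, orthogonal scores
    expect_equal(unname(colSums(p$loadings^2)), rep(1, 3), tolerance = 1e-10)
    expect_equal(unname(apply(p$scores, 2, var)), p$eigenvalues, tolerance = 1e-8)
    ctr <- scale(p$scores, scale = FALSE)
    off <- crossprod(ctr)[upper.tri(diag(3))]
    expect_lt(max(abs(off)), 1e-6)
    # sign convention: dominant loading positive
    expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  }
})

test_that("pca_correlation agrees with vegan on a shared fixture", {
  X <- with_seed_local(99, matrix(rnorm(80), 20, 4,
                                  dimnames = list(NULL, letters[1:4])))
  p <- pca_correlation(X)
  v <- vegan::rda(X, scale = TRUE)
  expect_equal(p$eigenvalues, unname(v$CA$eig), tolerance = 1e-8)
})

test_that("row and column permutations behave as expected", {
  X <- with_seed_local(3, matrix(rnorm(40), 10, 4,
                                 dimnames = list(sprintf("s%02d", 1:10),
                                                 letters[1:4])))
  p <- pca_correlation(X)
  perm <- sample(10)
  pp <- pca_correlation(X[perm, ])
  expect_equal(pp$scores, p$scores[perm, ])       # equivariance
  pc <- pca_correlation(X[, c(3, 1, 4, 2)])
  expect_equal(pc$eigenvalues, p$eigenvalues, tolerance = 1e-10)
})

test_that("ordinate_dimension retains dominant components", {
  tm2 <- random_tm(8, 2, seed = 5)
  o2 <- ordinate_dimension(tm2)
  expect_equal(o2$cum_prop_var, 1)                 # 2 traits, 2 PCs: all of it

  # planted single factor: all traits = shared factor + small noise
  f <- with_seed_local(11, rnorm(20))
  X <- with_seed_local(12, sapply(1:5, function(j) f + 0.05 * rnorm(20)))
  o1 <- ordinate_dimension(make_tm(X, "trophic"))
  expect_gt(o1$pca$prop_var[1], 0.9)

  expect_error(ordinate_dimension(tm2, retained = 3), "rank")
  # zero-variance traits flagged by standardize are excluded
  tmz <- make_tm(cbind(rnorm(6), rep(1, 6), rnorm(6)))
  expect_silent(oz <- ordinate_dimension(tmz))
  expect_equal(oz$pca$n_vars, 2L)
})

test_that("meta_ordinate equalizes dimensions and recovers planted gradients", {
  sim <- simulate_assemblage(sim_config(seed = 8))
  ords <- lapply(sim$assemblage$tables, ordinate_dimension)
  meta <- meta_ordinate(ords)
  expect_equal(ncol(meta$input_block), 10L)
  expect_equal(sum(meta$pca$eigenvalues), 10, tolerance = 1e-8)

  # identical score pairs in every dimension: rank-2 input
  o1 <- ords[[1]]
  clones <- lapply(names(ords), function(d) {
    o <- o1; o$dimension <- d
    o
  })
  m2 <- meta_ordinate(clones)
  expect_equal(sum(m2$pca$prop_var[1:2]), 1, tolerance = 1e-8)

  # planted cross-dimension gradient dominates the meta-ordination
  simg <- simulate_assemblage(sim_config(
    n_species = 60L, n_groups = 1L, gradient_strength = 3, seed = 21))
  mg <- meta_ordinate(lapply(simg$assemblage$tables, ordinate_dimension))
  expect_gt(abs(cor(mg$pca$scores[, 1], simg$gradient)), 0.9)

  # mismatched species error
  bad <- ords
  rownames(bad[[2]]$retained_scores)[1] <- "zz"
  expect_error(meta_ordinate(bad), "species mismatch")
})

test_that("ordinate_raw pools all dimensions through the same engine", {
  sim <- simulate_assemblage(sim_config(seed = 13))
  raw <- ordinate_raw(sim$assemblage)
  expect_equal(raw$n_vars, 38L)
  expect_equal(sum(raw$eigenvalues), 38, tolerance = 1e-8)
  expect_identical(rownames(raw$scores), sim$assemblage$species_ids)
})
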