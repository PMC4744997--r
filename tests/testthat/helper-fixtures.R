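# small programmatic fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick trait_matrix from a bare numeric matrix
make_tm <- function(values, dimension = "habitat", ids = NULL, traits = NULL) {
  ids <- ids %||% sprintf("sp%02d", seq_len(nrow(values)))
  traits <- traits %||% sprintf("%s_t%d", dimension, seq_len(ncol(values)))
  dimnames(values) <- list(ids, traits)
  trait_matrix(values, dimension)
}

random_tm <- function(n, p, dimension = "habitat", seed = 1) {
  with_seed_local(seed, make_tm(matrix(rnorm(n * p), n, p), dimension))
}

# local equivalent of the package-internal seed guard
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

write_csv_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# two-dimension synthetic config used throughout CART calibration tests:
# the pure adaptive-peak world (no cross-dimension gradient)
peak_world <- function(seed, n_species, n_groups, n_traits = 6L,
                       peak_separation = 6) {
  sim_config(
    n_species = n_species, dimensions = c("habitat", "life_history"),
    n_traits = c(n_traits, n_traits), n_groups = c(n_groups, n_groups),
    peak_separation = peak_separation, gradient_strength = 0, seed = seed
  )
}
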