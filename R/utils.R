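#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals (CV folds, simulators) never perturb the
#' user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locale-independent lexicographic order (radix sort on byte values).
#' @keywords internal
canonical_order <- function(x) order(x, method = "radix")

#' Abbreviation used to label hierarchy levels in composite-tree exports:
#' first character of the dimension label, upper-cased ("habitat" -> "H").
#' @keywords internal
dimension_initial <- function(dimension) {
  toupper(substr(dimension, 1L, 1L))
}

stop_ns <- function(...) stop(..., call. = FALSE)
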