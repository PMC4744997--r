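#' Combine per-dimension groups into hierarchical niche codes
#'
#' A niche code is the ordered tuple of a species' group labels, one per
#' niche dimension, taken in the hierarchy order (default habitat, life
#' history, trophic, defence, metabolic). The hierarchy order fixes how codes
#' read and where categories sit in the composite dendrogram, but distances
#' between categories are not interpretable and occupancy counts do not
#' depend on the order.
#'
#' @param groups named list, `dimension -> named integer vector`
#'   (species -> group label), e.g. from [assign_groups()].
#' @param hierarchy_order character vector of dimension names; defaults to
#'   the canonical order of [NICHE_DIMENSIONS] restricted to those present.
#' @return Integer matrix (species x dimensions, class `niche_codes`) with
#'   row names = species, column names = dimensions in hierarchy order.
#' @export
assign_niche_codes <- function(groups, hierarchy_order = NULL) {
  if (!length(groups) || is.null(names(groups))) {
    stop_ns("'groups' must be a named list of per-dimension group vectors")
  }
  hierarchy_order <- hierarchy_order %||%
    intersect(NICHE_DIMENSIONS, names(groups))
  if (!length(hierarchy_order)) hierarchy_order <- names(groups)
  missing_ <- setdiff(hierarchy_order, names(groups))
  if (length(missing_)) {
    stop_ns("hierarchy names dimension(s) with no groups: ",
            paste(missing_, collapse = ", "))
  }
  species <- sort(names(groups[[hierarchy_order[1L]]]), method = "radix")
  code <- matrix(NA_integer_, length(species), length(hierarchy_order),
                 dimnames = list(species, hierarchy_order))
  for (d in hierarchy_order) {
    g <- groups[[d]]
    absent <- setdiff(species, names(g))
    if (length(absent)) {
      stop_ns("species missing from dimension '", d, "': ",
              paste(absent, collapse = ", "))
    }
    code[, d] <- as.integer(g[species])
  }
  if (anyNA(code) || any(code < 1L)) stop_ns("group labels must be positive integers")
  structure(code, class = c("niche_codes", class(code)))
}

#' Render niche codes as strings
#'
#' @param codes a `niche_codes` matrix.
#' @param style `"tuple"` for `"2,4,2,1,3"`, `"prefixed"` for
#'   `"H2.L4.T2.D1.M3"` (dimension-initial prefixes).
#' @return Character vector named by species.
#' @export
format_niche_codes <- function(codes, style = c("tuple", "prefixed")) {
  style <- match.arg(style)
  if (style == "tuple") {
    out <- apply(codes, 1L, paste, collapse = ",")
  } else {
    ini <- dimension_initial(colnames(codes))
    out <- apply(codes, 1L, function(r) paste0(ini, r, collapse = "."))
  }
  out
}

#' Enumerate the cross-product niche space
#'
#' The number of potential niches is the product of the per-dimension group
#' (terminal-node) counts. When that product is no larger than
#' `max_enumerate`, the full code list is materialized in lexicographic
#' order (first dimension slowest).
#'
#' @param leaf_counts named integer vector of per-dimension group counts
#'   (all >= 1).
#' @param max_enumerate cap on materializing the code matrix.
#' @return `list(potential, codes)` where `codes` is an integer matrix
#'   (potential x dimensions) or `NULL` if above the cap.
#' @export
enumerate_niche_space <- function(leaf_counts, max_enumerate = 1e5) {
  counts <- as.integer(leaf_counts)
  if (!length(counts) || anyNA(counts) || any(counts < 1L)) {
    stop_ns("all group counts must be integers >= 1")
  }
  potential <- prod(counts)
  codes <- NULL
  if (potential <= max_enumerate) {
    grid <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
    codes <- as.matrix(grid[, rev(seq_along(counts)), drop = FALSE])
    dimnames(codes) <- list(NULL, names(leaf_counts))
  }
  list(potential = potential, codes = codes)
}

#' Occupancy of the niche space
#'
#' Maps species niche codes onto the cross-product space: which potential
#' codes are occupied (and by whom), which are vacant, and which hold
#' multiple species. Vacant codes are either non-viable trait combinations or
#' viable-but-unoccupied niches; no attempt is made to distinguish the two.
#'
#' @param codes a `niche_codes` matrix ([assign_niche_codes()]).
#' @param leaf_counts named per-dimension group counts; defaults to the
#'   per-dimension maxima observed in `codes`.
#' @return An object of class `niche_classification`: `hierarchy_order`,
#'   `codes`, `potential`, `occupied` (named list code-string -> species),
#'   `n_occupied`, `vacant_count`, `multi_occupied`.
#' @export
occupancy <- function(codes, leaf_counts = NULL) {
  if (!inherits(codes, "niche_codes")) {
    # accept a bare integer matrix with species row names and dimension
    # column names (e.g. a row-subset of a niche_codes matrix)
    if (!is.matrix(codes) || is.null(rownames(codes)) || is.null(colnames(codes))) {
      stop_ns("'codes' must be a niche_codes matrix (see assign_niche_codes)")
    }
    storage.mode(codes) <- "integer"
    class(codes) <- c("niche_codes", class(codes))
  }
  leaf_counts <- leaf_counts %||% apply(codes, 2L, max)
  if (any(apply(codes, 2L, max) > as.integer(leaf_counts))) {
    stop_ns("codes exceed the supplied per-dimension group counts")
  }
  potential <- prod(as.integer(leaf_counts))
  keys <- format_niche_codes(codes)
  occ <- split(rownames(codes), keys)
  occ <- lapply(occ, function(s) sort(s, method = "radix"))
  occ <- occ[sort(names(occ), method = "radix")]
  structure(
    list(hierarchy_order = colnames(codes), codes = codes,
         leaf_counts = stats::setNames(as.integer(leaf_counts), colnames(codes)),
         potential = potential, occupied = occ, n_occupied = length(occ),
         vacant_count = potential - length(occ),
         multi_occupied = occ[vapply(occ, length, integer(1)) > 1L]),
    class = "niche_classification"
  )
}

#' @export
print.niche_classification <- function(x, ...) {
  cat(sprintf(
    "<niche_classification> %d species; hierarchy %s\n  %d potential niches, %d occupied, %d vacant; %d multi-occupied\n",
    nrow(x$codes), paste(x$hierarchy_order, collapse = " > "),
    x$potential, x$n_occupied, x$vacant_count, length(x$multi_occupied)))
  invisible(x)
}

#' Build the composite niche dendrogram
#'
#' Nests the per-dimension groupings in hierarchy order into one composite
#' tree: each level splits on the next dimension's groups, each root-to-tip
#' path is a niche code, and each tip is annotated as occupied (with its
#' species) or vacant.
#'
#' @param leaf_counts named per-dimension group counts in hierarchy order,
#'   or a named list of pruned `regression_tree`s (counts taken via
#'   [n_leaves()]).
#' @param occ optional `niche_classification` supplying occupancy annotations.
#' @return An object of class `composite_tree`: a recursive node structure
#'   (`dimension`, `children` keyed by group label) whose tips carry `code`,
#'   `label`, `species`, `occupied`.
#' @export
build_composite_tree <- function(leaf_counts, occ = NULL) {
  if (is.list(leaf_counts) &&
      all(vapply(leaf_counts, inherits, logical(1), "regression_tree"))) {
    leaf_counts <- vapply(leaf_counts, n_leaves, integer(1))
  }
  if (!length(leaf_counts) || is.null(names(leaf_counts))) {
    stop_ns("'leaf_counts' must be a named vector (hierarchy order) or list of trees")
  }
  counts <- as.integer(leaf_counts)
  if (any(counts < 1L)) stop_ns("all group counts must be >= 1")
  dims <- names(leaf_counts)
  occ_map <- if (!is.null(occ)) occ$occupied else list()
  ini <- dimension_initial(dims)
  build <- function(level, code) {
    if (level > length(dims)) {
      key <- paste(code, collapse = ",")
      species <- occ_map[[key]] %||% character()
      return(list(tip = TRUE, code = code,
                  label = paste0(ini, code, collapse = "."),
                  species = species, occupied = length(species) > 0L))
    }
    children <- lapply(seq_len(counts[level]), function(g) build(level + 1L, c(code, g)))
    names(children) <- paste0(ini[level], seq_len(counts[level]))
    list(tip = FALSE, dimension = dims[level], children = children)
  }
  structure(
    list(root = build(1L, integer()), hierarchy_order = dims,
         leaf_counts = stats::setNames(counts, dims),
         n_tips = prod(counts)),
    class = "composite_tree"
  )
}

#' @export
print.composite_tree <- function(x, ...) {
  cat(sprintf("<composite_tree> hierarchy %s; %d tips\n",
              paste(x$hierarchy_order, collapse = " > "), x$n_tips))
  invisible(x)
}

composite_tips <- function(node, acc = list()) {
  if (node$tip) return(c(acc, list(node)))
  for (ch in node$children) acc <- composite_tips(ch, acc)
  acc
}

#' Export the composite tree as a labeled newick string
#'
#' Tip labels are `H2.L4.T2.D1.M3|species_a,species_b` for occupied tips and
#' `...|VACANT` for vacant ones; vacant tips can be suppressed to keep the
#' string small (a fully vacant internal branch is then dropped entirely).
#'
#' @param ct a `composite_tree`.
#' @param include_vacant keep vacant tips (default `FALSE`).
#' @return A single newick string (with trailing `;`), or `NA_character_` if
#'   nothing remains after suppressing vacant tips.
#' @export
composite_newick <- function(ct, include_vacant = FALSE) {
  stopifnot(inherits(ct, "composite_tree"))
  esc <- function(s) gsub("[(),;:\\s]", "_", s, perl = TRUE)
  rec <- function(node) {
    if (node$tip) {
      if (!node$occupied && !include_vacant) return(NULL)
      ann <- if (node$occupied) paste(node$species, collapse = ",") else "VACANT"
      return(esc(paste0(node$label, "|", ann)))
    }
    parts <- Filter(Negate(is.null), lapply(node$children, rec))
    if (!length(parts)) return(NULL)
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  s <- rec(ct$root)
  if (is.null(s)) return(NA_character_)
  paste0(s, ";")
}

#' Export the composite tree as an indented text outline
#'
#' @param ct a `composite_tree`.
#' @param include_vacant include vacant tips (default `FALSE`).
#' @return Character vector of outline lines.
#' @export
composite_outline <- function(ct, include_vacant = FALSE) {
  rec <- function(node, name, depth) {
    pad <- strrep("  ", depth)
    if (node$tip) {
      if (!node$occupied && !include_vacant) return(character())
      ann <- if (node$occupied) paste(node$species, collapse = ", ") else "VACANT"
      return(sprintf("%s%s: %s", pad, node$label, ann))
    }
    kid_lines <- unlist(lapply(names(node$children), function(nm) {
      rec(node$children[[nm]], nm, depth + 1L)
    }))
    if (!length(kid_lines)) return(character())
    c(sprintf("%s[%s] %s", pad, node$dimension, name), kid_lines)
  }
  unlist(lapply(names(ct$root$children), function(nm) {
    rec(ct$root$children[[nm]], nm, 0L)
  }))
}
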