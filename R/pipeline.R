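#' Configuration of an end-to-end niche-scheme run
#'
#' @param traits named character vector or list, `dimension = path`, of
#'   trait-table files (>= 2 dimensions).
#' @param abundance optional path to a species x survey abundance table.
#' @param newick optional path to a newick phylogeny.
#' @param retained PCs retained per dimension (default 2).
#' @param growth a [growth_params()]; its `seed` is overridden per dimension
#'   from `seed`.
#' @param hierarchy_order dimension order for niche codes; default is the
#'   canonical order of [NICHE_DIMENSIONS].
#' @param seed master seed for the run.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(traits, abundance = NULL, newick = NULL, retained = 2L,
                       growth = growth_params(), hierarchy_order = NULL,
                       seed = 1L, out_dir = NULL) {
  traits <- as.list(traits)
  if (length(traits) < 2L || is.null(names(traits))) {
    stop_ns("'traits' must be >= 2 paths named by niche dimension")
  }
  for (p in c(unlist(traits), abundance, newick)) {
    if (!file.exists(p)) stop_ns("input file not found: ", p)
  }
  structure(
    list(traits = traits, abundance = abundance, newick = newick,
         retained = as.integer(retained), growth = growth,
         hierarchy_order = hierarchy_order, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a JSON file
#'
#' Flat JSON with the [run_config()] fields; `growth` may be an object of
#' [growth_params()] fields. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  gp <- do.call(growth_params, as.list(cfg$growth %||% list()))
  run_config(
    traits = vapply(as.list(cfg$traits), resolve, character(1)),
    abundance = resolve(cfg$abundance), newick = resolve(cfg$newick),
    retained = cfg$retained %||% 2L, growth = gp,
    hierarchy_order = cfg$hierarchy_order,
    seed = cfg$seed %||% 1L, out_dir = cfg$out_dir
  )
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_manifest <- function(cfg, out_dir, stage) {
  cfg_flat <- list(
    stage = stage, traits = cfg$traits, abundance = cfg$abundance,
    newick = cfg$newick, retained = cfg$retained,
    growth = unclass(cfg$growth), hierarchy_order = cfg$hierarchy_order,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("nichescheme"))
  )
  cfg_flat$config_hash <- sum(utf8ToInt(paste(deparse(cfg_flat), collapse = "")))
  write_json_out(cfg_flat, file.path(out_dir, paste0("manifest_", stage, ".json")))
}

write_scores_csv <- function(scores, path) {
  df <- data.frame(species_id = rownames(scores),
                   as.data.frame(scores, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

load_inputs <- function(cfg) {
  asm <- load_assemblage(unlist(cfg$traits))
  resp <- if (!is.null(cfg$abundance)) load_abundance_table(cfg$abundance)
  if (!is.null(resp) && !identical(resp$species_ids, asm$species_ids)) {
    stop_ns("[load] abundance species do not match trait-table species")
  }
  phy <- if (!is.null(cfg$newick)) parse_newick(cfg$newick)
  list(asm = asm, resp = resp, phy = phy)
}

#' Run the continuous niche scheme end to end
#'
#' Loads and validates trait tables, ordinates each niche dimension,
#' meta-ordinates ("PCA of PCAs"), and — when inputs are supplied —
#' correlates axes with abundance responses (including the pooled-trait
#' baseline) and projects the phylogeny into the meta plane. All outputs are
#' deterministic: rerunning an identical config writes byte-identical files.
#'
#' @param cfg a [run_config()] or path to a JSON config.
#' @return Invisibly, a list: `ordinations`, `meta`, `raw`, `report`
#'   (or `NULL`), `projection` (or `NULL`).
#' @export
run_continuous <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  inp <- load_inputs(cfg)
  ords <- lapply(inp$asm$tables, ordinate_dimension, retained = cfg$retained)
  meta <- meta_ordinate(ords)
  raw <- ordinate_raw(inp$asm)
  report <- if (!is.null(inp$resp)) {
    correlate_axes(meta = meta, dims = ords, raw = raw, resp = inp$resp,
                   components = cfg$retained)
  }
  projection <- if (!is.null(inp$phy)) project_phylogeny(inp$phy, meta)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (o in ords) {
      write_scores_csv(o$retained_scores,
                       file.path(cfg$out_dir, paste0("scores_", o$dimension, ".csv")))
    }
    write_scores_csv(meta$pca$scores[, seq_len(cfg$retained), drop = FALSE],
                     file.path(cfg$out_dir, "meta_scores.csv"))
    write_json_out(
      list(
        per_dimension = lapply(ords, function(o) {
          list(dimension = o$dimension, retained = o$retained,
               cum_prop_var = o$cum_prop_var,
               eigenvalues = o$pca$eigenvalues)
        }),
        meta_eigenvalues = meta$pca$eigenvalues,
        meta_prop_var = meta$pca$prop_var
      ),
      file.path(cfg$out_dir, "ordination_summary.json")
    )
    if (!is.null(report)) {
      utils::write.csv(report, file.path(cfg$out_dir, "correlations.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (!is.null(projection)) {
      write_scores_csv(projection$node_scores,
                       file.path(cfg$out_dir, "projection_node_scores.csv"))
      ape::write.tree(projection$tree,
                      file.path(cfg$out_dir, "projection_tree.nwk"))
    }
    write_manifest(cfg, cfg$out_dir, "continuous")
  }
  invisible(list(ordinations = ords, meta = meta, raw = raw,
                 report = report, projection = projection))
}

#' Run the discrete niche classification end to end
#'
#' Loads trait tables, ordinates each dimension, fits and 1-SE-prunes a
#' multivariate regression tree per dimension (responses: retained PC scores;
#' predictors: original trait values; fold seed derived from the run seed),
#' assigns species groups, combines them into hierarchical niche codes, and
#' enumerates occupied and vacant niches.
#'
#' @param cfg a [run_config()] or path to a JSON config.
#' @return Invisibly, a list: `ordinations`, `trees`, `groups`, `codes`,
#'   `classification`, `composite`.
#' @export
run_discrete <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  inp <- load_inputs(cfg)
  ords <- lapply(inp$asm$tables, ordinate_dimension, retained = cfg$retained)
  dims <- names(inp$asm$tables)
  trees <- vector("list", length(dims)); names(trees) <- dims
  groups <- vector("list", length(dims)); names(groups) <- dims
  for (i in seq_along(dims)) {
    gp <- cfg$growth
    gp$seed <- cfg$seed + i  # per-dimension fold seed, derived from run seed
    trees[[i]] <- niche_tree(inp$asm$tables[[i]], ords[[i]], gp)
    groups[[i]] <- assign_groups(trees[[i]], inp$asm$tables[[i]]$values)
  }
  hierarchy <- cfg$hierarchy_order %||% intersect(NICHE_DIMENSIONS, dims)
  codes <- assign_niche_codes(groups, hierarchy)
  cls <- occupancy(codes, vapply(trees[hierarchy], n_leaves, integer(1)))
  composite <- build_composite_tree(trees[hierarchy], occ = cls)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(species_id = rownames(codes),
                 as.data.frame(unclass(codes), check.names = FALSE),
                 niche_code = format_niche_codes(codes, "prefixed"),
                 check.names = FALSE),
      file.path(cfg$out_dir, "niche_codes.csv"), row.names = FALSE, quote = FALSE
    )
    write_json_out(
      list(hierarchy_order = cls$hierarchy_order,
           leaf_counts = as.list(cls$leaf_counts),
           potential = cls$potential, n_occupied = cls$n_occupied,
           vacant_count = cls$vacant_count, occupied = cls$occupied),
      file.path(cfg$out_dir, "occupancy.json")
    )
    write_json_out(lapply(trees, function(t) t$cp_table),
                   file.path(cfg$out_dir, "cp_tables.json"))
    writeLines(unlist(lapply(dims, function(d) {
      c(paste0("== ", d, " =="), node_outline(trees[[d]]$root))
    })), file.path(cfg$out_dir, "trees.txt"))
    nwk <- composite_newick(composite, include_vacant = FALSE)
    if (!is.na(nwk)) writeLines(nwk, file.path(cfg$out_dir, "composite_tree.nwk"))
    writeLines(composite_outline(composite),
               file.path(cfg$out_dir, "composite_outline.txt"))
    write_manifest(cfg, cfg$out_dir, "discrete")
  }
  invisible(list(ordinations = ords, trees = trees, groups = groups,
                 codes = codes, classification = cls, composite = composite))
}

#' Write a synthetic assemblage to disk as pipeline inputs
#'
#' Materializes a [simulate_assemblage()] result as the delimited files the
#' pipeline consumes (one trait CSV per dimension plus an abundance CSV), so
#' synthetic runs exercise the same ingestion path as real data.
#'
#' @param sim a `synthetic_assemblage`.
#' @param dir output directory (created if missing).
#' @return Named list of written paths: `traits` (named by dimension),
#'   `abundance`.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_assemblage"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traits <- vapply(sim$assemblage$tables, function(tm) {
    p <- file.path(dir, paste0("traits_", tm$dimension, ".csv"))
    write_trait_table(tm, p)
    p
  }, character(1))
  ab <- file.path(dir, "abundance.csv")
  m <- sim$response$monthly_abundance
  utils::write.csv(
    data.frame(species_id = rownames(m),
               apply(m, 2L, function(v) sprintf("%.17g", v)),
               check.names = FALSE),
    ab, row.names = FALSE, quote = FALSE
  )
  list(traits = traits, abundance = ab)
}
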