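Package: nichescheme
Title: Continuous and Discrete Niche Schemes from Multi-Dimensional Trait Data
Version: 0.1.0
Authors@R:
    person("Kai", "Fisher", email = "kfisher@example.org", role = c("aut", "cre"))
Description: Builds niche schemes for species assemblages from functional trait
    and ecological performance data partitioned into five niche dimensions
    (habitat, life history, trophic, defence, metabolic). Provides a
    correlation-matrix PCA engine, per-dimension ordinations and a two-stage
    meta-ordination ("PCA of PCAs") yielding a continuous niche scheme; a
    multivariate-response regression tree (CART) with cost-complexity pruning,
    cross-validation and the 1-SE rule yielding per-dimension species groups; a
    hierarchical niche classification with composite-dendrogram and
    vacant-niche enumeration; projection of phylogenies into niche space via
    squared-change parsimony; evaluation of niche axes against abundance and
    its coefficient of variation; and a synthetic-assemblage generator with
    adaptive-peak trait structure and planted response correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
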