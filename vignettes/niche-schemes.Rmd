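---
title: "Building continuous and discrete niche schemes from multi-dimensional trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building continuous and discrete niche schemes from multi-dimensional trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(nichescheme)
```

## The problem

A species' niche has several distinct facets: where it can live (habitat),
how it schedules reproduction (life history), what and how it eats
(trophic), how it avoids enemies (defence), and how it budgets energy
(metabolic). Trait compilations for whole assemblages mix variables from all
of these facets, and a single ordination of the pooled table is dominated by
whichever facet happens to contribute the most (or the most correlated)
variables — in fish data, typically body-shape morphometrics. `nichescheme`
implements a two-track methodology that treats the five dimensions as
first-class units:

* a **continuous scheme**: ordinate each dimension separately, retain its
  dominant axes, then ordinate the retained axes together, so each dimension
  gets an equal chance to shape the overall niche gradients; and
* a **discrete scheme**: cluster species within each dimension with a
  regression tree on that dimension's dominant axes, then cross the
  per-dimension groups into hierarchical niche codes, which makes *vacant*
  niches (trait combinations realised by no species) enumerable.

## The continuous scheme

Each dimension's species-by-trait matrix is z-scored per trait (sample SD,
denominator $n-1$) and decomposed by eigenanalysis of the Pearson
correlation matrix $R$: eigenvalues $\lambda_1 \ge \lambda_2 \ge \dots$,
unit-norm loadings $v_j$, and species scores $Z v_j$ with $Z$ the z-scored
data. Because $\mathrm{tr}(R) = p$, eigenvalues sum to the number of
non-constant traits and $\lambda_j / p$ is the proportion of variance
explained; both are asserted as invariants in the test suite. The first two
components of each dimension are retained by default (`retained = 2`); the
retention count is configurable because the right choice depends on the
scheme's intended application.

The **meta-ordination** (`meta_ordinate()`) concatenates the retained score
columns of all dimensions — for five dimensions, a species × 10 block — and
applies the same correlation-matrix PCA to it. The inner PCA re-standardises
every input column, which is precisely what equalises the dimensions: a
dimension's influence no longer depends on its trait count or eigenvalue
scale. The pooled-trait baseline (`ordinate_raw()`, a single PCA of all
traits) is kept available through the same engine so the two approaches can
be compared on any data set.

**Signs.** PCA components are orientation-free. For reproducibility, each
component is flipped so that its largest-magnitude loading is positive (ties
broken toward the lowest variable index); all downstream comparisons of
correlations use $|r|$, so no scientific claim ever rests on a sign.

**Degeneracies.** Constant traits cannot be z-scored: `standardize()` flags
them (`zero_variance`) and ordinations exclude them. Eigenvalues below
`1e-10` count as null rank; requesting more retained components than the
rank is an error rather than a silent truncation.

## The discrete scheme

For each dimension a **multivariate-response regression tree** is grown from
scratch (`grow_tree()`): responses are the dimension's retained PC scores,
predictors are the *original* trait values (so each split is a readable
trait threshold), and the split criterion is the reduction in within-node
sum of squares summed over the response columns. The search is exhaustive
over every predictor and every midpoint between consecutive distinct values;
ties break toward the lower predictor index, then the lower threshold, so
the fit is deterministic. Whether to fit one multivariate tree or one tree
per axis was an open choice; the default is a single multivariate tree
because the scheme needs exactly one group count per dimension, with a
`mode = "per_axis"` escape hatch in `niche_tree()`.

Trees are pruned by cost-complexity (weakest-link) pruning with K-fold
cross-validation and the **1-SE rule** (`cv_prune_1se()`): among the nested
pruning sequence, select the largest complexity whose cross-validated error
is within one standard error of the minimum. The standard error is computed
from per-observation CV squared-error contributions (the rpart convention);
fold assignment is drawn from the `seed` in `growth_params()` and restored
afterwards, so identical seeds give identical prunings. Growth defaults
(`minsplit = 10`, `minbucket = 3`, `cp_min = 0.01`, 10 folds) are scaled to
assemblage-sized data of a few dozen species; the canonical defaults of
larger-data implementations (`minsplit = 20`, `minbucket = 7`) would leave
almost no admissible splits at $n \approx 56$.

Terminal nodes are numbered depth-first, left (below threshold) before
right, matching the reading order of a plotted dendrogram; these ordinals
are the per-dimension group labels. `assign_niche_codes()` stacks them in a
fixed hierarchy — habitat, life history, trophic, defence, metabolic by
default — into one code per species, e.g. `2,4,2,1,3`. The hierarchy order
changes how codes read and where categories sit in the composite dendrogram
(`build_composite_tree()`), but never the occupancy accounting; distances
between categories in the composite tree are not interpretable, and the test
suite asserts the invariance. The potential niche space is the product of
the per-dimension leaf counts (`enumerate_niche_space()`); `occupancy()`
reports which codes are occupied, by whom, and how many are vacant. Vacant
tips are retained (flagged) in exports because vacancy detection is a
primary use of the scheme; no attempt is made to distinguish non-viable from
viable-but-unoccupied combinations, since no criterion for that distinction
exists in the data.

## Projecting a phylogeny into niche space

`project_phylogeny()` overlays a phylogeny on the continuous scheme: tips
are pinned to their meta-ordination scores (first two components by
default), and internal nodes are placed by **squared-change parsimony** —
positions minimising the sum over edges of squared change, per axis
independently. The minimiser satisfies a linear system in which every
internal node is the (weighted) mean of its neighbours; the package solves
it directly, and the tests check it against both a numerical optimiser and a
Gauss–Seidel iteration. Reconstruction is unweighted by default — the common
default for this method, and the sensible one when the plotted figure gives
no branch lengths — with `weighted = TRUE` dividing squared changes by
branch length. Edge lengths of the projected tree ("niche branch lengths")
are Euclidean distances in the projection plane, so they are invariant to
rotation and translation of the ordination, as asserted in the tests.

## Evaluating niche axes

`compute_response_stats()` reduces a species × survey abundance matrix to a
mean and a coefficient of variation (CV = sample SD / mean). The CV uses the
$n-1$ denominator because a year of monthly surveys is a sample of the
annual process. Species with zero mean abundance get an explicit
undefined-CV flag, not a number, and are excluded pairwise (with a logged
count) from CV correlations. `correlate_axes()` then reports Pearson's $r$
and $|r|$ between every axis — each dimension's retained PCs, the
meta-ordination's, and the pooled-trait baseline's — and the two responses.
Abundance is used untransformed, and no p-values are attached by default.

## The synthetic world

`simulate_assemblage()` generates the structure the methods assume so every
stage is testable offline:

* **Adaptive peaks.** Per dimension, `n_groups` peak centres are placed
  evenly on a circle inside a random 2-D subspace of trait space, with
  radius chosen so the *minimum* pairwise distance is exactly
  `peak_separation * noise_sd`; species are assigned to peaks multinomially
  (every peak occupied at least once) and scattered with isotropic Gaussian
  noise. Defaults mirror the reference scale: 56 species, five dimensions
  with 8+8+8+7+7 = 38 traits, peak counts (4, 5, 6, 2, 6), separation 6.
* **Inter-block correlation.** A latent standard-normal gradient loads on
  every trait block with weight `gradient_strength` (default 0.5), giving
  the cross-dimension correlation real assemblages show.
* **Planted response.** Mean abundance is lognormal
  (`abundance_sigma = 1`; ecological abundances are right-skewed) over 12
  monthly surveys with multiplicative survey noise
  (`survey_sigma = 0.2`). The log-scale correlation with the gradient is
  calibrated in closed form,
  $\rho_{\log} = \rho \sqrt{e^{\sigma^2}(1 + v_F) - 1} / \sigma$ with $v_F$
  the survey-mean noise variance, so the *natural-scale* population
  correlation between the gradient and computed mean abundance equals
  `response_rho` exactly.

What the generator does **not** emulate: measurement error and missing
cells, categorical or ordinal trait codings, non-elliptic (e.g. curved or
nested) trait clusters, phylogenetic autocorrelation between the trait
blocks and the abundance response, and count-valued (zero-inflated)
abundances. A green test on synthetic data therefore establishes that the
algorithms do what they claim under clustered, noisy, correlated continuous
traits — not that any particular empirical assemblage satisfies those
assumptions.

`simulate_phylogeny()` complements this with a pure-birth topology whose
traits evolve as Brownian motion plus Ornstein–Uhlenbeck attraction toward
lineage-assigned peaks; peak assignments switch along branches, so distant
clades converge on shared peaks — the pattern a niche projection is meant to
reveal. With `attraction = 0` the process reduces exactly to Brownian
motion.

## Calibration findings and known limitations

Two properties asserted in the acceptance suite fail honestly, and the
analyses are worth recording because they are statements about the method,
not about bugs (both were verified against independent implementations):

* **Exact recovery of planted group counts is not reliable at separation 6.**
  The tree's responses (PC scores) are deterministic linear functions of its
  predictors (the traits). Splits beyond the planted peaks therefore capture
  genuinely predictable within-peak score variation and *reduce*
  cross-validated error, and the 1-SE band does not reliably bridge the gap:
  at separation 6 with 15 species per group, the planted count is the
  *modal* outcome (about 70% of seeds) but over-splitting by one or two
  leaves is common. An independent reference CART implementation makes the
  same choices on identical data. Exact recovery does hold in the
  separation-≫-noise limit (the tests use separation 1000). Practically:
  pruned leaf counts should be read as resolution choices, not as estimates
  of a true number of clusters.
* **Natural-scale correlation recovery carries a small positive bias.** The
  sample Pearson correlation between a Gaussian axis and a lognormal
  ($\sigma = 1$) abundance is finite-sample biased upward (about +0.02 at
  $n = 200$, vanishing by $n = 5000$) even though the generator's population
  correlation is exact. Planted-correlation checks at a few hundred species
  should expect that bias.

Other limitations: trees are fit per dimension independently (no shared
penalisation across dimensions); the composite dendrogram's size is the
product of leaf counts and becomes unwieldy for fine-grained groupings; and
the newick export of the composite tree replaces structural characters in
labels (including the comma between co-occupant species) with underscores
to stay parseable.

## A worked run

```{r, eval = FALSE}
sim <- simulate_assemblage(sim_config(seed = 1))
paths <- write_synthetic_inputs(sim, tempfile("run_"))
cfg <- run_config(paths$traits, abundance = paths$abundance,
                  seed = 1, out_dir = "out")
cont <- run_continuous(cfg)   # ordinations, meta-ordination, correlations
disc <- run_discrete(cfg)     # trees, niche codes, occupancy, composite tree
disc$classification
```

Outputs are plain CSV/JSON/newick plus a manifest recording the
configuration and seed; reruns with identical configuration are
byte-identical, which the acceptance suite asserts.
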