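# nichescheme

Build **niche schemes** — standardized summaries of where species sit in
multi-dimensional niche space — from functional trait and ecological
performance data. The package is aimed at community ecologists working with
assemblage-level trait compilations (fish, plants, invertebrates, ...) who
want to go beyond a single pooled ordination and treat the fundamental niche
dimensions — **habitat, life history, trophic, defence, metabolic** — as
first-class units of analysis.

Two complementary schemes are produced from per-dimension species × trait
tables:

* **Continuous scheme.** A correlation-matrix PCA per dimension (eigenvalues
  λ₁ ≥ λ₂ ≥ ..., scores Zvⱼ on z-scored data), retaining the two dominant
  components; the retained scores of all dimensions then feed a second
  correlation-matrix PCA — a *meta-ordination* ("PCA of PCAs") whose inner
  re-standardization gives every dimension an equal chance to shape the
  overall niche gradients, regardless of trait counts.
* **Discrete scheme.** Per dimension, a from-scratch **multivariate-response
  regression tree** (responses = retained PC scores, predictors = original
  trait values, split criterion = summed within-node SS) pruned by
  cost-complexity with K-fold cross-validation and the **1-SE rule**. The
  terminal nodes define species groups; groups are stacked in a fixed
  hierarchy (habitat → life history → trophic → defence → metabolic) into
  **niche codes** such as `2,4,2,1,3`, and the cross-product space
  ∏ (leaf counts) is enumerated to reveal occupied, multiply-occupied and
  **vacant** niches.

Also included: projection of a phylogeny into the continuous scheme by
**squared-change parsimony** (internal nodes at the weighted mean of their
neighbours; edge lengths = Euclidean "niche branch lengths"), evaluation of
niche axes against mean abundance and its coefficient of variation, and a
synthetic-assemblage generator with adaptive-peak structure and planted
response correlations for end-to-end testing without any data download.

## Worked example

```r
library(nichescheme)

sim   <- simulate_assemblage(sim_config(seed = 1))   # 56 species, 38 traits
paths <- write_synthetic_inputs(sim, "demo")         # CSVs, as a real run would use
cfg   <- run_config(paths$traits, abundance = paths$abundance, seed = 1)

cont <- run_continuous(cfg)
cont$meta
#> <meta_ordination> 56 species, input block of 10 axis scores (habitat, life_history, trophic, defence, metabolic)
#> <pca_result> 56 obs x 10 vars
#>   eigenvalues: 1.826 1.467 1.237 1.155 1.044 ...
#>   prop. var. : 0.183 0.147 0.124 0.116 0.104 ...
```

The meta-ordination's first axis explains 18.3% of the 10-column score
block — with this seed the five synthetic dimensions are nearly independent,
so no single gradient dominates; a strong cross-dimension gradient
(`gradient_strength` high) concentrates this instead.

```r
head(cont$report, 3)
#>              axis r_mean_abundance abs_r_mean_abundance r_cv_abundance abs_r_cv_abundance
#>       habitat.PC1         0.218470             0.218470        0.05953            0.05953
#>       habitat.PC2         0.146344             0.146344       -0.11891            0.11891
#>  life_history.PC1        -0.148848             0.148848        0.22546            0.22546
```

Each row correlates one niche axis (per-dimension, meta, or pooled-trait
baseline `raw.PC*`) with mean abundance and its CV across the 12 monthly
surveys; `|r|` is the headline number because PCA component signs are
arbitrary.

```r
disc <- run_discrete(cfg)
disc$classification
#> <niche_classification> 56 species; hierarchy habitat > life_history > trophic > defence > metabolic
#>   3600 potential niches, 56 occupied, 3544 vacant; 0 multi-occupied

head(format_niche_codes(disc$codes), 2)
#>       sp001       sp002
#> "2,5,3,5,2" "4,4,2,4,6"
```

3600 is the product of the five pruned-tree leaf counts for this seed; with
56 species every code here is singly occupied and the remaining 3544
combinations are vacant — either non-viable or simply unrealised.
`composite_newick()` / `composite_outline()` export the composite dendrogram
with occupied tips labelled `H2.L5.T3.D5.M2|sp001` and vacant tips flagged.

With `out_dir` set, `run_continuous()`/`run_discrete()` write scores,
correlations, niche codes, occupancy, cp tables, tree outlines, newick
exports and a run manifest; reruns with the same config and seed are
byte-identical. A command-line wrapper lives at `inst/cli/nichescheme.R`
(`Rscript nichescheme.R discrete --config run.json`).

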