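# oralung

Oral-taxa-aware diversity analysis of lung microbiota.

Bronchoalveolar lavage fluid (BALF) is a low-biomass specimen, and a large
share of its 16S signal can be bacteria washed down from the oral cavity.
When BALF communities are compared between disease groups — here
ANCA-associated vasculitis (AAV) versus sarcoidosis — oral admixture can
create, mask, or reverse apparent diversity differences. `oralung` is an R
package for running that comparison with the oral contribution made
explicit, aimed at researchers analyzing family- or genus-rank OTU tables
from lung specimens.

## What it computes

* **α-diversity**: inverse Simpson, `D = 1/Σ pᵢ²` (effective number of
  taxa); **β-diversity**: Morisita–Horn dissimilarity
  `1 − 2Σxᵢyᵢ / ((dₓ + d_y)·XY)` with `dₓ = Σxᵢ²/X²`; between-taxa Jaccard
  distances for heatmap ordering.
* **Oral taxa selection** from HMP-style prevalence tables: *inhabitant*
  taxa of a subsite (detected in strictly over 98% of specimens — the
  smallest prevalence whose Wilson-score 95% lower bound exceeds 0.95 at
  realistic subsite sample sizes) and *vagrant* taxa (over 5% of subjects
  in any oral subsite), plus the threshold-stability curve that singles
  out the hard palate.
* **Taxa-selection effect scoring** — the package's core procedure: the
  observed statistic (standardized Mann-Whitney U between diseases, or the
  OLS slope of diversity on the BVAS activity score among AAV samples) is
  placed on the empirical distribution of the same statistic over 2,000
  equal-size taxa subsets drawn without replacement from all detected
  taxa; the result is a percentile rank in [0, 100], with sex-stratified
  re-analysis to expose confounded selections.
* **Inference**: permutation Mann-Whitney tests (exact enumeration when
  feasible), case-resampling bootstrap CIs for the diversity-on-BVAS
  slope, and single-predictor PERMANOVA (Gower-centered pseudo-F,
  identity-permutation p-values, complete-case per predictor).
* **Clustering**: complete linkage on Morisita–Horn for samples, single
  linkage on Jaccard for taxa; cluster cuts, ordered heatmap matrices,
  Newick export.
* **Synthetic cohorts**: a Dirichlet-multinomial generator
  (`makeCohort()`, `presetScenarios()`) that plants known group effects,
  BVAS slopes, sex confounding, and a one-family "monopoly" cluster at the
  study's scale (16 AAV / 21 sarcoidosis, 144 families, median depth
  ~15,000 reads), so every stage is testable without downloads.

Data containers are Bioconductor-style S4: `OtuTable` extends
`SummarizedExperiment` (taxa × samples, clinical covariates in `colData`),
with `PrevalenceTable`, `TaxaSet`, `DissimilarityMatrix` and typed result
objects alongside. I/O covers TSV and BIOM count tables, TSV metadata and
prevalence tables, Newick dendrograms, and JSON result records.

## Worked example

Simulate a cohort in which AAV communities are less even than sarcoidosis
ones *only within the 11 oral inhabitant families*, select the inhabitant
set from a synthetic prevalence table, and score the selection:

```r
library(oralung)

co <- makeCohort(presetScenarios()$oral_effect, seed = 42)
co$table
#> OtuTable: 144 taxa (family rank) x 37 samples
#>   total reads: 823,255; per-sample median: 16,960
#>   metadata: disease, sex, smoking, age, bvas, balf_macrophage_pct, ...

prev <- makePrevalenceTable(
  plantedInhabitant = list(hard_palate = co$truth$inhabitantTaxa),
  plantedVagrant = co$truth$oralTaxa, seed = 43)
inh <- inhabitantTaxa(prev, "hard_palate")
inh
#> TaxaSet: 11 taxa (family rank), provenance inhabitant:hard_palate@>0.98
#>   Actinomycetaceae, Carnobacteriaceae, Fusobacteriaceae, Gemellaceae, ...

res <- nullEcdf(co$table, inh, statistic = "standardized_U",
                nDraws = 2000, seed = 44)
res
#> NullEcdfResult (standardized_U): observed -5.1504, percentile rank 0.7%
#>   k = 11 taxa, 2000 draws (0 discarded), ties 'le'

d <- sampleDiversity(co$table)
permutationMWU(d, co$metadata$disease, nPerm = 10000, seed = 45)
#> Permutation Mann-Whitney: U = 79, z = -2.728, p = 0.007399 (10000 permutations)
```

Reading the output: on the inhabitant subset the standardized U is −5.15,
and only 0.7% of random 11-taxon subsets produce a statistic that small —
the diversity difference is specific to the selected oral set, matching the
planted truth. The whole-table permutation test (p ≈ 0.007) picks up the
same signal diluted across all 144 families.

`runAnalysis(config)` orchestrates the full three-arm pipeline (all taxa /
restrict to inhabitant / exclude vagrant) from an R list or YAML config,
writing diversity tables, percentile ranks, PERMANOVA grids
(`reportTable2()`), dissimilarity matrices and Newick dendrograms to an
output directory, fully reproducible from one seed.

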