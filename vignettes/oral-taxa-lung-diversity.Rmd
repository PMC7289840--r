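---
title: "Oral-taxa-aware diversity analysis of lung microbiota: models and design choices"
author: "oralung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oral-taxa-aware diversity analysis of lung microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralung)
```

## The problem

Bronchoalveolar lavage fluid (BALF) is a low-biomass specimen: a large share
of its 16S signal can be bacteria washed down from the mouth rather than a
resident lung community. When two patient groups — here ANCA-associated
vasculitis (AAV) and sarcoidosis — are compared on BALF community diversity,
any apparent difference may be created, masked, or reversed by that oral
admixture. `oralung` implements a workflow that makes the oral contribution
explicit: define oral taxa from healthy-population prevalence data, re-run
the diversity comparison on the oral subset and on its complement, and score
how much the *choice of taxa set* itself moved the statistic.

The package operates on family- or genus-rank count tables
(`OtuTable`, a `SummarizedExperiment` with taxa as rows), per-sample
clinical covariates (disease, sex, smoking, age, the BVAS vasculitis
activity score, BALF differential-cell percentages), and an HMP-style
prevalence table (`PrevalenceTable`: per oral subsite, the number of
specimens in which each taxon was detected).

## Diversity measures

Within-sample diversity is the inverse Simpson index
$D = 1/\sum_i p_i^2$, where $p_i$ are within-sample relative abundances.
It is reported in effective-number-of-taxa units: $D \in [1, S]$ with
$D = S$ exactly for a uniform community over $S$ taxa. The Simpson family
is comparatively robust to variation in sequencing effort, which matters
for BALF libraries whose depths span an order of magnitude.

One wording ambiguity deserves a note: "inverse Simpson" is occasionally
used for $1/(1-\lambda)$, the inverse of the Gini–Simpson index, rather
than the conventional $1/\lambda$ with $\lambda = \sum p_i^2$. The package
defaults to $1/\lambda$ and exposes the other reading behind
`inverseSimpson(..., gini = TRUE)`; all shipped analyses use the default.

Between-sample dissimilarity is Morisita–Horn,

$$D_{xy} = 1 - \frac{2\sum_i x_i y_i}{(d_x + d_y)\,XY}, \qquad
  d_x = \frac{\sum_i x_i^2}{X^2},\; X = \sum_i x_i,$$

the abundance-based Horn variant standard in ecology texts; it is 0 for
identical relative compositions (including $x$ vs $2x$) and 1 for disjoint
supports. Between-*taxa* distances for heatmap ordering are Jaccard
distances on presence/absence patterns across samples. Two taxa absent
everywhere are put at distance 0 (identical empty sets) and reported as
degenerate, which keeps the single-linkage ordering defined. Values within
$10^{-12}$ outside $[0,1]$ are clipped; anything beyond errors.

## Selecting oral taxa from prevalence data

Two nested notions of "oral taxon" are derived from healthy-subject
prevalence across the nine oral/oropharynx subsites:

* **Inhabitant** taxa of a subsite: detected in strictly more than 98% of
  that subsite's specimens. The threshold is not arbitrary: for subsite
  sample sizes in the low hundreds, ~98% is the smallest prevalence whose
  Wilson-score 95% lower confidence bound still exceeds 0.95
  (`minPrevalenceForLowerBound()`; at $n = 242$ the minimal qualifying
  fraction is 237/242 ≈ 0.979, and at $n = 250$ it is exactly 0.98).
  `stabilityCurve()` tabulates how the selected count shrinks as the
  threshold rises to 99.5% and flags subsites whose count at 98% equals the
  count at 99% — the stability rule that singles out the hard palate,
  whose 11 inhabitant families anchor the restricted analyses.
* **Vagrant** taxa: detected in strictly more than 5% of subjects in any
  oral subsite (per-subsite prevalence, unioned across subsites — the
  conservative, larger exclusion set; a pooled-denominator alternative sits
  behind `pooled = TRUE`). Excluding vagrants is the "noise reduction" arm:
  what remains is the community that plausibly does not come from the mouth.

Both rules use strict inequalities, matching their "over 98%" / "over 5%"
definitions; `strict = FALSE` switches to weak inequalities. The prevalence
denominator is whatever the table carries (specimens or subjects); state it
when assembling the table.

## Scoring a taxa-selection effect: the random-subset null

Restricting to 11 inhabitant families or excluding 96 vagrant families
changes any statistic computed downstream — but so would restricting to
*any* 11 or 48 taxa. The package's core procedure quantifies the
selection-specific part: compute the observed statistic on the chosen set,
then rebuild the same statistic for (by default) 2,000 equal-cardinality
taxa sets drawn uniformly **without replacement from all detected taxa**
(not from the complement), and report the observed value's percentile rank
on the empirical distribution of the null draws.

Two statistics are supported:

* `standardized_U`: $z = (U - n_1 n_2/2)/\sqrt{\mathrm{Var}(U)}$ for the
  between-disease difference in per-sample inverse Simpson, with midranks
  and the standard tie-correction in the variance (diversity values are
  effectively continuous, but synthetic edge cases need defined behavior).
* `ols_slope`: the least-squares slope of inverse Simpson on BVAS, AAV
  samples only (BVAS is defined only for the vasculitis group).

Percentile ranks use the step-ECDF "$\le$" convention,
$100 \cdot \#\{\text{draws} \le \text{observed}\}/n$; with 2,000 draws the
resolution is 0.05 points. Strict-"<" and midrank conventions are
available (`ties =`), since reported ranks at ties depend on this choice.
Draws that leave fewer than two usable samples in a group (or a constant
BVAS vector) are discarded and counted; if more than 10% of draws are
discarded the table is declared too sparse and the analysis errors rather
than returning a rank built on a distorted null. A rank near 0 or 100
means the chosen set carries a signal that random sets of the same size do
not; `stratifiedNullEcdf()` repeats the whole procedure within levels of a
covariate (typically sex) to check whether that signal merely rides on a
confounder — a confounded effect pulls back toward 50 under
stratification.

## Resampling inference

* **Permutation Mann-Whitney**: the permutation statistic is $U$ itself
  (under label permutation the standardized $U$ is an affine function of
  $U$, so p-values coincide, and the all-ties case stays defined). All
  $\binom{n}{n_1}$ assignments are enumerated when at most 20,000,
  otherwise 10,000 Monte Carlo permutations with the add-one convention.
  Two-sided p doubles the smaller tail, capped at 1 — the permutation
  distribution of $U$ need not be symmetric after conditioning on ties.
* **Bootstrap slope CI**: case resampling of $(x_i, y_i)$ pairs, 2,000
  replicates, percentile interval. Replicates with constant resampled
  BVAS are discarded and counted. A known limitation, documented rather
  than hidden: at the study's $n = 16$ AAV samples, first-order bootstrap
  intervals undercover — about 90% empirical coverage for a nominal 95%,
  for percentile and BCa flavors alike, and equally for covering 0 under
  independence. Coverage reaches its nominal level at moderately larger
  $n$ (the package's validation measures ≈93–95% at $n = 64$). Slope
  point estimates are unaffected.
* **PERMANOVA**: single-predictor, on the Gower-centered inner-product
  matrix $G$ of $-\tfrac12 d_{ij}^2$ with hat matrix $H$ of
  $[1, \text{predictor}]$:
  $F = [\mathrm{tr}(HGH)/df_m]\,/\,[\mathrm{tr}((I-H)G(I-H))/df_r]$.
  In the univariate Euclidean case this reduces exactly to the one-way
  ANOVA or regression F (a test asserts agreement to $10^{-10}$, and an
  independent implementation, `vegan::adonis2`, is cross-checked on
  Morisita–Horn matrices). The p-value permutes sample identities (rows
  and columns of $D$ jointly), 9,999 permutations, add-one convention.
  Missing predictor values trigger complete-case subsetting of the matrix,
  one predictor at a time — so each column of the resulting factor table
  carries its own $n$. No multi-factor sequential decomposition is
  attempted; the factor grid is deliberately one-at-a-time.

Permutation and draw counts (10,000 / 9,999 / 2,000) are declared
defaults, not inferences; every function takes explicit counts and seeds,
and identical seeds reproduce results bit-for-bit.

## Clustering and heatmap ordering

Sample dendrograms use complete linkage on Morisita–Horn; taxa orderings
use single linkage on between-taxa Jaccard. Agglomeration is
`stats::hclust`, which breaks equal-height ties deterministically by pair
index, so leaf orders are reproducible for a given input ordering; leaf
order is the natural agglomeration order with no optimal-leaf-ordering
rotation. `cutClusters()` requires an explicit `k` or height — the
package does not guess where a "large cluster" begins. Ordered
relative-abundance matrices export as TSV and dendrograms as Newick.

## The synthetic cohort generator

Validation needs data whose truth is known. `makeCohort()` draws cohorts
with the statistical structure the analysis assumes, at the study's scale
by default: 16 AAV and 21 sarcoidosis samples, 144 families of which 96
are oral (11 inhabitant-grade), log-normal depths with median 15,000 reads
(sdlog 0.78, matching an IQR spanning roughly 8,500–24,000), and BALF
metadata including one sample with missing differential-cell percentages
(so complete-case handling is exercised at $n = 36$).

Each sample's target composition mixes a lung block and an oral block at
the contamination fraction (default 0.3); the oral block is 60%
inhabitant-grade taxa. Block compositions come from a geometric base
abundance profile power-tilted so that the block's inverse Simpson equals
its target exactly — planted effects (disease differences in a chosen
block, a sex-driven effect, or a whole-table BVAS slope of −0.2 per point)
are therefore exact at the composition level. The realized composition is
Dirichlet with concentration $\theta \cdot p$ ($\theta = 400$), and counts
are multinomial at the drawn depth — the standard overdispersed
Dirichlet-multinomial community model. The tilt construction, rather than
a symmetric Dirichlet concentration ramp, is what makes the planted
BVAS–diversity relation linear enough for mean-slope recovery within
±0.05 at $n = 16$; a symmetric-concentration link is strongly nonlinear in
the relevant range. Count noise attenuates planted diversity relations
slightly (the measurement-level slope is about −0.197 for a planted
−0.2), which is why CI-calibration checks target the measurement-level
estimand.

Preset scenarios (`presetScenarios()`) cover one headline analysis each:
`null`, `oral_effect` (AAV less even, only in the 11 inhabitant taxa),
`nonoral_effect` (AAV more even, only in the lung block — the direction
that puts the vagrant-excluded rank in the upper tail), `bvas_slope`,
`monopoly_cluster` (11 samples, 9 of them sarcoidosis, whose lung block is
85% one family — recovered as a dendrogram cluster after vagrant
exclusion), and `sex_confounded` (the inhabitant-block signal depends on
sex, with sex imbalanced 70%/25% male across diseases — strong enough to
fake a disease effect, while keeping every sex-by-disease cell large
enough to stratify).

`makePrevalenceTable()` plants inhabitant taxa at prevalence 0.995 by
default. This sits deliberately above the nominal 0.99: with binomial
detection at exactly 0.99 and $n = 200$, the drawn prevalence falls at or
below the strict 98% cutoff ~14% of the time, so planted-truth recovery
would be a coin-flip property, not a test.

What the generator does **not** emulate: real taxonomic covariance
structure, batch and extraction-kit contamination, sequencing error, or
compositional correlations between oral and lung blocks. Passing tests
demonstrate that the statistical machinery recovers planted truth under
the model's assumptions — not that those assumptions hold for any
particular real BALF dataset.

## Numerical and degenerate-input policy

* Zero-total samples are an error at ingest; created by taxa subsetting,
  they are retained and flagged, and each downstream statistic applies its
  own rule (diversity `NA`, dissimilarity matrices exclude them with a
  message, null-ECDF draws discard affected statistics).
* OTUs with no name at the target rank aggregate into a reserved
  `__unassigned__` label, kept by default so per-sample totals are
  conserved; `dropUnassigned` removes them. Whether unassigned taxa
  belong in diversity is genuinely open; both behaviors are supported.
* All Monte Carlo procedures take explicit integer seeds; stratified
  analyses derive per-stratum seeds as `seed + level index`; the
  U-statistic and slope null distributions use independent seeds.

## Problem sizes used in validation

The shipped validation suite exercises: 200 null cohorts for
percentile-rank uniformity (400 draws each; Kolmogorov–Smirnov distance
below 0.1), 100 cohorts each for permutation and PERMANOVA p-value
uniformity, 500 cohorts for mean slope recovery at $n = 16$, 400
replicates for bootstrap coverage at $n = 64$ (against a 300-replicate
estimand batch), 50 seeds each for the planted-effect direction and
sex-stratification scenarios, and full 2,000-draw ECDFs in the
reproduction script. These sizes keep Monte Carlo error comfortably below
the asserted tolerances.
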