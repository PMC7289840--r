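#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.RANKS <- c("family", "genus", "otu")
.UNASSIGNED <- "__unassigned__"
.CLIP_TOL <- 1e-12

#' OtuTable: a count table at one taxonomic rank
#'
#' An `OtuTable` holds a nonnegative integer count matrix (taxa as rows,
#' samples as columns, following the `SummarizedExperiment` convention),
#' per-sample metadata in `colData`, and the taxonomic rank of the rows.
#' Samples whose total count is zero are rejected at ingest; subsetting by a
#' taxa set may create zero-total samples, which are retained but flagged in
#' `metadata(x)$zero_total_samples` so each downstream statistic can apply
#' its own rule.
#'
#' @slot rank character(1); one of `"family"`, `"genus"`, `"otu"`.
#' @export
setClass("OtuTable",
  contains = "SummarizedExperiment",
  representation(rank = "character")
)

setValidity("OtuTable", function(object) {
  msg <- character()
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, sprintf("rank must be one of: %s", paste(.RANKS, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts))) msg <- c(msg, "counts contain NA")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts contain negative entries")
      if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts are not integer-valued")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon labels must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' PrevalenceTable: per-subsite taxon detection counts
#'
#' HMP-style prevalence data: for each (subsite, taxon) pair, the number of
#' specimens in which the taxon was detected (read count > 0) and the total
#' number of specimens for that subsite.
#'
#' @slot data data.frame with columns `subsite`, `taxon`, `detected`, `total`.
#' @slot rank taxonomic rank of the taxa.
#' @export
setClass("PrevalenceTable",
  representation(data = "data.frame", rank = "character")
)

setValidity("PrevalenceTable", function(object) {
  msg <- character()
  d <- object@data
  need <- c("subsite", "taxon", "detected", "total")
  if (!all(need %in% names(d)))
    return(sprintf("data must have columns: %s", paste(need, collapse = ", ")))
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, sprintf("rank must be one of: %s", paste(.RANKS, collapse = ", ")))
  if (any(d$total < 1)) msg <- c(msg, "total must be >= 1")
  if (any(d$detected < 0) || any(d$detected > d$total))
    msg <- c(msg, "detected must satisfy 0 <= detected <= total")
  if (anyDuplicated(d[, c("subsite", "taxon")]))
    msg <- c(msg, "duplicated (subsite, taxon) rows")
  if (length(msg)) msg else TRUE
})

#' TaxaSet: a named set of taxon labels with provenance
#'
#' @slot labels character vector of unique taxon labels.
#' @slot rank taxonomic rank of the labels.
#' @slot provenance character(1) describing where the set came from, e.g.
#'   `"inhabitant:hard_palate@0.98"`, `"vagrant@0.05"`,
#'   `"random_draw:seed=7,index=12"`, or `"manual"`.
#' @export
setClass("TaxaSet",
  representation(labels = "character", rank = "character", provenance = "character")
)

setValidity("TaxaSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, sprintf("rank must be one of: %s", paste(.RANKS, collapse = ", ")))
  if (length(object@provenance) != 1L) msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' DissimilarityMatrix: pairwise dissimilarities with ids and a metric name
#'
#' Symmetric, zero-diagonal, entries in `[0, 1]` for the supported metrics
#' (`morisita_horn` between samples, `jaccard_taxa` between taxa). Values in
#' `(-1e-12, 0)` or `(1, 1 + 1e-12)` are clipped at construction; anything
#' beyond is an error.
#'
#' @slot values symmetric numeric matrix with dimnames.
#' @slot metric character(1).
#' @export
setClass("DissimilarityMatrix",
  representation(values = "matrix", metric = "character")
)

setValidity("DissimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column ids must be present and identical")
  if (any(is.na(v))) msg <- c(msg, "NA entries")
  else {
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > .CLIP_TOL)) msg <- c(msg, "diagonal must be zero")
    if (any(v < 0)) msg <- c(msg, "entries must be nonnegative")
    if (object@metric %in% c("morisita_horn", "jaccard_taxa") && any(v > 1))
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(object@metric) != 1L) msg <- c(msg, "metric must be a single string")
  if (length(msg)) msg else TRUE
})

#' WilsonInterval: Wilson score confidence interval for a binomial proportion
#'
#' @slot k successes; @slot n trials; @slot conf confidence level;
#' @slot lower,upper interval bounds in `[0, 1]`.
#' @export
setClass("WilsonInterval",
  representation(k = "numeric", n = "numeric", conf = "numeric",
                 lower = "numeric", upper = "numeric")
)

#' StabilityCurve: taxa counts per subsite over a grid of prevalence thresholds
#'
#' @slot data data.frame with columns `subsite`, `threshold`, `count`.
#' @slot stableSubsites subsites whose count at threshold 0.98 equals the
#'   count at 0.99 (the stability rule used to pick the hard palate).
#' @export
setClass("StabilityCurve",
  representation(data = "data.frame", stableSubsites = "character")
)

#' NullEcdfResult: percentile rank of a statistic on a random-taxa-subset null
#'
#' The observed statistic is computed on a user-supplied taxa set; the null
#' distribution is the same statistic over `nDraws` equal-cardinality taxa
#' subsets drawn uniformly without replacement from all detected taxa.
#'
#' @slot statisticKind `"standardized_U"` or `"ols_slope"`.
#' @slot observed observed statistic.
#' @slot nullDraws statistics of the non-degenerate random draws.
#' @slot percentileRank percentile rank in `[0, 100]`.
#' @slot k cardinality of the drawn sets.
#' @slot nDraws number of draws requested.
#' @slot nDiscarded degenerate draws discarded.
#' @slot seed integer seed used (NA if none supplied).
#' @slot stratum optional stratum label, e.g. `"sex=female"`.
#' @slot ties tie convention used for the rank (`"le"`, `"lt"`, `"mid"`).
#' @export
setClass("NullEcdfResult",
  representation(statisticKind = "character", observed = "numeric",
                 nullDraws = "numeric", percentileRank = "numeric",
                 k = "integer", nDraws = "integer", nDiscarded = "integer",
                 seed = "integer", stratum = "character", ties = "character")
)

#' PermutationTestResult: permutation Mann-Whitney test
#'
#' @slot statistic standardized U (z) on the observed labelling (NA when the
#'   variance is zero); @slot u the Mann-Whitney U for the first group;
#' @slot pValue two-sided p; @slot nPermutations number of Monte Carlo
#'   permutations, or `NA` with `exact = TRUE` for full enumeration;
#' @slot exact logical; @slot seed integer seed (NA if none).
#' @export
setClass("PermutationTestResult",
  representation(statistic = "numeric", u = "numeric", pValue = "numeric",
                 nPermutations = "integer", exact = "logical", seed = "integer")
)

#' SlopeEstimate: OLS slope with bootstrap confidence interval
#'
#' @slot beta slope (diversity units per BVAS point); @slot ciLower,ciUpper
#'   bootstrap CI bounds; @slot nBoot replicates used; @slot nDiscarded
#'   constant-x replicates discarded; @slot method CI flavour;
#' @slot conf confidence level; @slot seed integer seed (NA if none).
#' @export
setClass("SlopeEstimate",
  representation(beta = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 nBoot = "integer", nDiscarded = "integer", method = "character",
                 conf = "numeric", seed = "integer")
)

#' PermanovaResult: single-predictor PERMANOVA on a dissimilarity matrix
#'
#' @slot pseudoF pseudo-F from the Gower-centered inner-product matrix;
#' @slot pValue permutation p (add-one convention); @slot nPermutations
#'   permutations used; @slot dfModel,dfResidual degrees of freedom;
#' @slot predictor predictor name; @slot completeCaseN samples retained after
#'   complete-case filtering; @slot seed integer seed (NA if none).
#' @export
setClass("PermanovaResult",
  representation(pseudoF = "numeric", pValue = "numeric",
                 nPermutations = "integer", dfModel = "integer",
                 dfResidual = "integer", predictor = "character",
                 completeCaseN = "integer", seed = "integer")
)

#' CohortScenario: parameters of the synthetic BALF cohort generator
#'
#' Defaults emulate the study conditions of a two-disease BALF cohort:
#' 16 AAV and 21 sarcoidosis samples, 144 families of which 96 are oral
#' (11 inhabitant-grade), log-normal sequencing depth with median ~15,000
#' reads, and an oral-contamination mixing weight per sample.
#'
#' @slot nAav,nSarc group sizes.
#' @slot nTaxaTotal total number of taxa (families) in the table.
#' @slot nOral number of oral ("vagrant"-grade) taxa, inhabitants included.
#' @slot nInhabitant number of inhabitant-grade oral taxa.
#' @slot contaminationFraction per-sample mixing weight of the oral community.
#' @slot lungDiversity,oralDiversity,inhabitantDiversity baseline inverse
#'   Simpson targets of the lung block, the non-inhabitant oral block, and the
#'   inhabitant block.
#' @slot groupEffectLocation `"oral_only"`, `"nonoral_only"`, `"global"`, `"none"`.
#' @slot groupEffectSize difference (AAV minus sarcoidosis) in the target
#'   inverse Simpson of the affected block.
#' @slot slopeBvasDiversity planted linear effect of BVAS on whole-table
#'   inverse Simpson (AAV only); 0 disables it.
#' @slot baseDiversityAll whole-table inverse Simpson at BVAS = 0 when the
#'   BVAS slope is planted.
#' @slot depthMeanlog,depthSdlog log-normal depth parameters.
#' @slot theta Dirichlet overdispersion: composition ~ Dirichlet(theta * p).
#' @slot monopolyN,monopolyDominance monopoly cluster: number of samples
#'   (0 disables) and the dominant taxon's share of the lung block.
#' @slot sexConfounded when TRUE the inhabitant-block diversity depends on sex
#'   (not disease) and sex is imbalanced across diseases.
#' @slot seed integer seed.
#' @export
setClass("CohortScenario",
  representation(
    nAav = "integer", nSarc = "integer", nTaxaTotal = "integer",
    nOral = "integer", nInhabitant = "integer",
    contaminationFraction = "numeric",
    lungDiversity = "numeric", oralDiversity = "numeric",
    inhabitantDiversity = "numeric",
    groupEffectLocation = "character", groupEffectSize = "numeric",
    slopeBvasDiversity = "numeric", baseDiversityAll = "numeric",
    depthMeanlog = "numeric", depthSdlog = "numeric", theta = "numeric",
    monopolyN = "integer", monopolyDominance = "numeric",
    sexConfounded = "logical", seed = "integer"
  )
)

setValidity("CohortScenario", function(object) {
  msg <- character()
  if (object@nAav < 2L || object@nSarc < 2L) msg <- c(msg, "need >= 2 samples per group")
  if (object@nInhabitant > object@nOral) msg <- c(msg, "nInhabitant > nOral")
  if (object@nOral >= object@nTaxaTotal) msg <- c(msg, "nOral must be < nTaxaTotal")
  if (object@contaminationFraction < 0 || object@contaminationFraction > 1)
    msg <- c(msg, "contaminationFraction must lie in [0, 1]")
  if (!object@groupEffectLocation %in% c("oral_only", "nonoral_only", "global", "none"))
    msg <- c(msg, "unknown groupEffectLocation")
  if (object@monopolyN > object@nAav + object@nSarc)
    msg <- c(msg, "monopoly cluster larger than the cohort")
  if (object@monopolyN > 0L && object@monopolyN > object@nSarc + 2L)
    msg <- c(msg, "monopoly cluster larger than the sarcoidosis group allows")
  if (object@monopolyDominance < 0 || object@monopolyDominance > 1)
    msg <- c(msg, "monopolyDominance must lie in [0, 1]")
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (length(msg)) msg else TRUE
})
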