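## End-to-end orchestration of the three analysis arms: all detected taxa,
## restrict to the oral "inhabitant" set, exclude the oral "vagrant" set.

.ARMS <- c("all", "inhabitant", "exclude_vagrant")

.asConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(scenario = NULL, counts = NULL, countsFormat = "tsv",
                   metadata = NULL, prevalence = NULL,
                   rank = "family", arms = .ARMS,
                   inhabitantSubsite = "hard_palate",
                   vagrantThreshold = 0.05, inhabitantThreshold = 0.98,
                   nDraws = 2000, nPerm = 10000, nPermPermanova = 9999,
                   nBoot = 2000, seed = 1,
                   predictors = c("disease", "bvas", "age", "sex"),
                   outDir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  badArms <- setdiff(cfg$arms, .ARMS)
  if (length(badArms)) stop("unknown arm(s): ", paste(badArms, collapse = ", "))
  if (is.null(cfg$scenario) && is.null(cfg$counts))
    stop("config must name either a preset scenario or a counts file")
  cfg
}

.armTable <- function(x, arm, inhabitant, vagrant) {
  switch(arm,
    all = x,
    inhabitant = subsetTaxa(x, inhabitant, mode = "restrict"),
    exclude_vagrant = subsetTaxa(x, vagrant, mode = "exclude"))
}

#' Run the full three-arm analysis pipeline
#'
#' For each requested arm (all taxa / restrict to inhabitant / exclude
#' vagrant) computes: per-sample inverse Simpson; the permutation
#' Mann-Whitney test between diseases; the BVAS slope with bootstrap CI (AAV
#' samples); the random-taxa-subset ECDF percentile ranks for both
#' statistics, with sex stratification (selection arms only — on all
#' detected taxa there is no selection to score); the Morisita-Horn matrix;
#' single-predictor PERMANOVAs over the configured predictors; and the dual
#' dendrograms with the ordered relative-abundance matrix. All randomness
#' derives from the config seed, so a rerun with the same config reproduces
#' every number.
#'
#' @param config an R list or the path to a YAML file. Fields: `scenario`
#'   (preset name, see [presetScenarios()]) or `counts`/`countsFormat`/
#'   `metadata` input paths; `prevalence` (TSV path; defaults to a synthetic
#'   table matched to the scenario's planted oral taxa); `rank`; `arms`;
#'   `inhabitantSubsite`; `inhabitantThreshold`; `vagrantThreshold`;
#'   `nDraws`; `nPerm`; `nPermPermanova`; `nBoot`; `seed`; `predictors`;
#'   `outDir` (optional; written as JSON/TSV/Newick files when set).
#' @return a report list: `$config`, `$taxaSets`, and one entry per arm with
#'   the results above. If an arm fails its error is recorded in
#'   `$<arm>$error` and the other arms still complete.
#' @export
runAnalysis <- function(config) {
  cfg <- .asConfig(config)

  if (!is.null(cfg$scenario)) {
    sc <- presetScenarios()[[cfg$scenario]]
    if (is.null(sc)) stop("unknown preset scenario: ", cfg$scenario)
    cohort <- makeCohort(sc, seed = cfg$seed)
    tab <- cohort$table
    prev <- if (is.null(cfg$prevalence)) {
      makePrevalenceTable(
        plantedInhabitant = stats::setNames(
          list(cohort$truth$inhabitantTaxa), cfg$inhabitantSubsite),
        plantedVagrant = cohort$truth$oralTaxa,
        rank = taxRank(tab), seed = cfg$seed + 1L)
    } else readPrevalenceTable(cfg$prevalence, rank = taxRank(tab))
  } else {
    tab <- readOtuTable(cfg$counts, format = cfg$countsFormat, rank = cfg$rank)
    if (!is.null(cfg$metadata)) {
      md <- readSampleMetadata(cfg$metadata)
      SummarizedExperiment::colData(tab) <- .joinSampleData(md, colnames(tab))
    }
    if (is.null(cfg$prevalence)) stop("a prevalence table is required for real input")
    prev <- readPrevalenceTable(cfg$prevalence, rank = cfg$rank)
  }

  inhabitant <- inhabitantTaxa(prev, cfg$inhabitantSubsite,
                               threshold = cfg$inhabitantThreshold)
  vagrant <- vagrantTaxa(prev, threshold = cfg$vagrantThreshold)
  report <- list(config = cfg,
                 taxaSets = list(inhabitant = inhabitant, vagrant = vagrant))

  meta <- as.data.frame(SummarizedExperiment::colData(tab))
  for (arm in cfg$arms) {
    report[[arm]] <- tryCatch(
      .runArm(tab, arm, inhabitant, vagrant, meta, cfg),
      error = function(e) list(error = conditionMessage(e)))
  }

  if (!is.null(cfg$outDir)) .writeReport(report, cfg$outDir)
  failed <- vapply(cfg$arms, function(a) !is.null(report[[a]]$error), logical(1))
  if (any(failed))
    warning("arm(s) failed: ", paste(cfg$arms[failed], collapse = ", "))
  report
}

.runArm <- function(tab, arm, inhabitant, vagrant, meta, cfg) {
  armTab <- .armTable(tab, arm, inhabitant, vagrant)
  out <- list(nTaxa = nrow(armTab))
  div <- sampleDiversity(armTab)
  out$diversity <- div

  ok <- !is.na(div) & !is.na(meta$disease)
  out$mwu <- permutationMWU(div[ok], meta$disease[ok],
                            nPerm = cfg$nPerm, seed = cfg$seed + 11L)

  if ("bvas" %in% names(meta)) {
    aav <- ok & meta$disease == "AAV" & !is.na(meta$bvas)
    if (sum(aav) >= 3)
      out$slope <- olsSlopeBootstrap(div[aav], meta$bvas[aav],
                                     nBoot = cfg$nBoot, seed = cfg$seed + 12L)
  }

  if (arm != "all") {
    obsSet <- if (arm == "inhabitant") inhabitant else
      taxaSet(taxonLabels(armTab), rank = taxRank(armTab),
              provenance = sprintf("exclude:%s", provenance(vagrant)))
    out$uRank <- nullEcdf(tab, obsSet, statistic = "standardized_U",
                          nDraws = cfg$nDraws, seed = cfg$seed + 13L)
    out$uRankBySex <- stratifiedNullEcdf(tab, obsSet,
                                         statistic = "standardized_U",
                                         stratum = "sex",
                                         nDraws = cfg$nDraws,
                                         seed = cfg$seed + 14L)
    if ("bvas" %in% names(meta)) {
      out$slopeRank <- nullEcdf(tab, obsSet, statistic = "ols_slope",
                                nDraws = cfg$nDraws, seed = cfg$seed + 15L)
    }
  }

  mh <- morisitaHornMatrix(armTab)
  out$morisitaHorn <- mh
  out$permanova <- list()
  for (pv in intersect(cfg$predictors, names(meta))) {
    pred <- stats::setNames(meta[[pv]], rownames(meta))
    if (pv == "bvas") pred[is.na(meta$disease) | meta$disease != "AAV"] <- NA
    out$permanova[[pv]] <- tryCatch(
      permanova(mh, pred, nPerm = cfg$nPermPermanova,
                seed = cfg$seed + 16L, name = pv),
      error = function(e) list(error = conditionMessage(e)))
  }

  keep <- setdiff(colnames(armTab), flaggedSamples(armTab))
  clTab <- if (length(keep) < ncol(armTab))
    otuTable(otuCounts(armTab)[, keep, drop = FALSE], rank = taxRank(armTab))
  else armTab
  out$sampleDend <- hierarchicalCluster(mh, linkage = "complete")
  out$taxaDend <- hierarchicalCluster(jaccardBetweenTaxa(clTab), linkage = "single")
  out$ordered <- orderedHeatmapMatrix(clTab, out$sampleDend, out$taxaDend)
  out
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  writeTaxaSet(report$taxaSets$inhabitant, file.path(outDir, "inhabitant_taxa.txt"))
  writeTaxaSet(report$taxaSets$vagrant, file.path(outDir, "vagrant_taxa.txt"))
  for (arm in intersect(cfg$arms, names(report))) {
    a <- report[[arm]]
    if (!is.null(a$error)) next
    base <- file.path(outDir, arm)
    rec <- list(
      arm = arm, n_taxa = a$nTaxa, seed = cfg$seed,
      mwu = list(z = a$mwu@statistic, u = a$mwu@u, p = a$mwu@pValue),
      slope = if (!is.null(a$slope))
        list(beta = a$slope@beta, ci = c(a$slope@ciLower, a$slope@ciUpper)),
      u_percentile_rank = if (!is.null(a$uRank)) a$uRank@percentileRank,
      u_percentile_rank_by_sex = if (!is.null(a$uRankBySex))
        lapply(a$uRankBySex, function(r) r@percentileRank),
      slope_percentile_rank = if (!is.null(a$slopeRank)) a$slopeRank@percentileRank,
      permanova = lapply(a$permanova, function(p)
        if (is.list(p)) p else list(pseudo_F = p@pseudoF, p = p@pValue,
                                    n = p@completeCaseN)))
    jsonlite::write_json(rec, paste0(base, "_results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.table(
      data.frame(sample_id = names(a$diversity), inverse_simpson = a$diversity),
      paste0(base, "_diversity.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeDissimilarity(a$morisitaHorn, paste0(base, "_morisita_horn.tsv"))
    exportNewick(a$sampleDend, paste0(base, "_samples.nwk"))
    exportNewick(a$taxaDend, paste0(base, "_taxa.nwk"))
    writeOrderedMatrix(a$ordered$matrix, paste0(base, "_heatmap_matrix.tsv"))
  }
  invisible(outDir)
}

#' Tabulate PERMANOVA p-values across predictors
#'
#' Emits the predictor-per-column p-value grid of the all-taxa arm (one row
#' per report), with the complete-case n of each cell, mirroring the usual
#' beta-diversity factor table.
#'
#' @param ... one or more report lists from [runAnalysis()] (e.g. family and
#'   genus runs); names become the row labels, defaulting to the rank.
#' @param arm which arm's PERMANOVA grid to tabulate (default `"all"`).
#' @param path optional TSV output path.
#' @return a `data.frame`: rows = reports, columns `<predictor>_p` and
#'   `<predictor>_n`.
#' @export
reportTable2 <- function(..., arm = "all", path = NULL) {
  reports <- list(...)
  if (length(reports) == 1 && is.null(reports[[1]]$config))
    reports <- reports[[1]]
  nm <- names(reports)
  if (is.null(nm)) nm <- rep("", length(reports))
  rows <- list()
  for (i in seq_along(reports)) {
    rp <- reports[[i]]
    pm <- rp[[arm]]$permanova
    if (is.null(pm)) stop("report ", i, " has no PERMANOVA results for arm ", arm)
    row <- list(rank = if (nzchar(nm[i])) nm[i] else rp$config$rank)
    for (pv in names(pm)) {
      if (is.list(pm[[pv]])) {
        row[[paste0(pv, "_p")]] <- NA_real_
        row[[paste0(pv, "_n")]] <- NA_integer_
      } else {
        row[[paste0(pv, "_p")]] <- pm[[pv]]@pValue
        row[[paste0(pv, "_n")]] <- pm[[pv]]@completeCaseN
      }
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
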