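## Synthetic cohort and prevalence-table generators. The cohort model is
## Dirichlet-multinomial: each sample has a target composition built from a
## lung block and an oral block (mixed at the contamination fraction), the
## realized composition is Dirichlet(theta * target), and counts are
## multinomial at a log-normal depth. Planted effects act on the inverse
## Simpson of block compositions via a power tilt, so the planted diversity
## values are exact at the composition level.

.INHABITANT_FAMILIES <- c(
  "Actinomycetaceae", "Carnobacteriaceae", "Fusobacteriaceae", "Gemellaceae",
  "Lachnospiraceae", "Neisseriaceae", "Pasteurellaceae", "Porphyromonadaceae",
  "Prevotellaceae", "Streptococcaceae", "Veillonellaceae")

.ORAL_SUBSITES <- c(
  "saliva", "attached_keratinized_gingiva", "buccal_mucosa", "hard_palate",
  "palatine_tonsils", "subgingival_plaque", "supragingival_plaque",
  "throat", "tongue_dorsum")

## Power-tilt a positive weight vector q so that the inverse Simpson of
## normalize(q^gamma) equals `target`; gamma = 0 gives the uniform
## composition (diversity = length(q)), large gamma concentrates on the
## largest weight (diversity -> 1).
.tiltToDiversity <- function(q, target) {
  m <- length(q)
  if (target >= m) return(rep(1 / m, m))
  if (target <= 1) stop("target diversity must exceed 1")
  f <- function(g) {
    p <- q^g
    p <- p / sum(p)
    1 / sum(p^2) - target
  }
  hi <- 1
  while (f(hi) > 0 && hi < 4096) hi <- hi * 2
  g <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  p <- q^g
  p / sum(p)
}

.rdirichlet <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  if (sum(x) == 0) stop("degenerate Dirichlet draw")
  x / sum(x)
}

#' Define a synthetic cohort scenario
#'
#' Defaults mirror the study conditions the package is validated against:
#' 16 AAV vs 21 sarcoidosis BALF samples, 144 families of which 96 are oral
#' (11 of inhabitant grade), oral contamination weight 0.3, and log-normal
#' sequencing depth with median ~15,000 reads. See [CohortScenario-class]
#' for the meaning of each parameter and [presetScenarios()] for the named
#' scenarios used in validation.
#'
#' @param nAav,nSarc group sizes.
#' @param nTaxaTotal,nOral,nInhabitant taxa-block sizes.
#' @param contaminationFraction oral mixing weight in `[0, 1]`.
#' @param lungDiversity,oralDiversity,inhabitantDiversity baseline inverse
#'   Simpson targets per block.
#' @param groupEffectLocation where the disease effect acts.
#' @param groupEffectSize AAV-minus-sarcoidosis difference in the affected
#'   block's target diversity.
#' @param slopeBvasDiversity planted whole-table diversity-per-BVAS slope.
#' @param baseDiversityAll whole-table diversity at BVAS 0 when the slope is
#'   planted.
#' @param depthMeanlog,depthSdlog log-normal depth parameters.
#' @param theta Dirichlet overdispersion (higher = less compositional noise).
#' @param monopolyN,monopolyDominance monopoly-cluster size (0 = off) and the
#'   dominant family's share of the lung block in those samples.
#' @param sexConfounded plant the inhabitant-block effect through sex instead
#'   of disease, with sex imbalanced across diseases.
#' @param seed integer seed.
#' @return a [CohortScenario-class].
#' @export
cohortScenario <- function(nAav = 16, nSarc = 21, nTaxaTotal = 144,
                           nOral = 96, nInhabitant = 11,
                           contaminationFraction = 0.3,
                           lungDiversity = 8, oralDiversity = 6,
                           inhabitantDiversity = 6,
                           groupEffectLocation = c("none", "oral_only",
                                                   "nonoral_only", "global"),
                           groupEffectSize = 0,
                           slopeBvasDiversity = 0, baseDiversityAll = 8,
                           depthMeanlog = log(15000), depthSdlog = 0.78,
                           theta = 400,
                           monopolyN = 0, monopolyDominance = 0.85,
                           sexConfounded = FALSE, seed = 1) {
  groupEffectLocation <- match.arg(groupEffectLocation)
  obj <- new("CohortScenario",
    nAav = as.integer(nAav), nSarc = as.integer(nSarc),
    nTaxaTotal = as.integer(nTaxaTotal), nOral = as.integer(nOral),
    nInhabitant = as.integer(nInhabitant),
    contaminationFraction = contaminationFraction,
    lungDiversity = lungDiversity, oralDiversity = oralDiversity,
    inhabitantDiversity = inhabitantDiversity,
    groupEffectLocation = groupEffectLocation,
    groupEffectSize = groupEffectSize,
    slopeBvasDiversity = slopeBvasDiversity,
    baseDiversityAll = baseDiversityAll,
    depthMeanlog = depthMeanlog, depthSdlog = depthSdlog, theta = theta,
    monopolyN = as.integer(monopolyN), monopolyDominance = monopolyDominance,
    sexConfounded = sexConfounded, seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "CohortScenario", function(object) {
  cat(sprintf("CohortScenario: %d AAV + %d sarcoidosis, %d taxa (%d oral, %d inhabitant)\n",
              object@nAav, object@nSarc, object@nTaxaTotal, object@nOral,
              object@nInhabitant))
  cat(sprintf("  effect: %s (size %g); BVAS slope %g; contamination %g; monopoly n = %d%s\n",
              object@groupEffectLocation, object@groupEffectSize,
              object@slopeBvasDiversity, object@contaminationFraction,
              object@monopolyN,
              if (object@sexConfounded) "; sex-confounded" else ""))
})

.scenarioLabels <- function(sc) {
  nInh <- sc@nInhabitant
  inh <- if (nInh <= length(.INHABITANT_FAMILIES))
    .INHABITANT_FAMILIES[seq_len(nInh)]
  else c(.INHABITANT_FAMILIES,
         sprintf("InhabitantFamily%02d", seq_len(nInh - length(.INHABITANT_FAMILIES))))
  nOther <- sc@nOral - nInh
  oralOther <- if (nOther > 0) sprintf("OralFamily%02d", seq_len(nOther)) else character()
  nLung <- sc@nTaxaTotal - sc@nOral
  lung <- c("Erythrobacteraceae",
            if (nLung > 1) sprintf("LungFamily%02d", seq_len(nLung - 1)) else character())
  list(inhabitant = inh, oralOther = oralOther, lung = lung)
}

#' Generate a synthetic BALF cohort
#'
#' Draws one cohort from a [CohortScenario-class]: per sample, a target
#' composition is assembled from a lung block and an oral block (itself 60%
#' inhabitant-grade, 40% other oral taxa) mixed at the contamination
#' fraction; planted diversity targets (group effects, sex confounding, the
#' BVAS slope) are imposed exactly on the relevant composition by a power
#' tilt; the realized composition is Dirichlet(theta * target) and counts
#' are multinomial at a log-normal depth. Clinical metadata (sex, smoking,
#' age, BVAS for AAV, BALF differential-cell percentages with one sample
#' left missing) are generated alongside.
#'
#' @param scenario a [CohortScenario-class].
#' @param seed optional seed overriding `scenario@seed`.
#' @return list with `table` (an [OtuTable-class] at family rank, metadata in
#'   `colData`), `metadata` (the same as a `data.frame`), and `truth` (every
#'   planted parameter and per-sample target).
#' @export
makeCohort <- function(scenario, seed = NULL) {
  sc <- scenario
  validObject(sc)
  set.seed(if (is.null(seed)) sc@seed else seed)
  lab <- .scenarioLabels(sc)
  taxa <- c(lab$inhabitant, lab$oralOther, lab$lung)
  n <- sc@nAav + sc@nSarc
  ids <- sprintf("S%02d", seq_len(n))
  disease <- c(rep("AAV", sc@nAav), rep("sarcoidosis", sc@nSarc))

  ## metadata
  ## sex-confounded: strong imbalance, but every sex x disease cell keeps
  ## enough expected members for a stratified analysis to be feasible
  if (sc@sexConfounded) {
    pMale <- ifelse(disease == "AAV", 0.7, 0.25)
  } else {
    pMale <- rep(0.3, n)
  }
  sex <- ifelse(stats::runif(n) < pMale, "male", "female")
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
  age <- round(ifelse(disease == "AAV", stats::rnorm(n, 77, 5),
                      stats::rnorm(n, 60, 12)))
  age <- pmin(pmax(age, 18), 95)
  bvas <- ifelse(disease == "AAV",
                 pmin(pmax(round(stats::rnorm(n, 14, 7)), 0), 28), NA_real_)

  ## monopoly membership: mostly sarcoidosis (9 of 11 at the default size)
  monopoly <- rep(FALSE, n)
  if (sc@monopolyN > 0) {
    nSarcPick <- min(sc@nSarc, ceiling(sc@monopolyN * 9 / 11))
    nAavPick <- sc@monopolyN - nSarcPick
    monopoly[sample(which(disease == "sarcoidosis"), nSarcPick)] <- TRUE
    if (nAavPick > 0) monopoly[sample(which(disease == "AAV"), nAavPick)] <- TRUE
  }

  ## per-sample block diversity targets
  nInh <- sc@nInhabitant; nOth <- sc@nOral - nInh; nLung <- sc@nTaxaTotal - sc@nOral
  jit <- function(base, m) {
    t <- base * exp(stats::rnorm(n, 0, 0.08))
    pmin(pmax(t, 1.1), m * 0.95)
  }
  effInh <- effLung <- rep(0, n)
  if (sc@groupEffectLocation %in% c("oral_only", "global"))
    effInh[disease == "AAV"] <- sc@groupEffectSize
  if (sc@groupEffectLocation %in% c("nonoral_only", "global"))
    effLung[disease == "AAV"] <- sc@groupEffectSize
  inhBase <- sc@inhabitantDiversity + effInh
  if (sc@sexConfounded)
    inhBase <- ifelse(sex == "male", 2.5, 7)
  inhTarget <- jit(inhBase, nInh)
  oralTarget <- jit(sc@oralDiversity, max(nOth, 2))
  lungTarget <- jit(sc@lungDiversity + effLung, nLung)

  qInh <- 0.85^(seq_len(nInh) - 1)
  qOth <- if (nOth > 0) 0.85^(seq_len(nOth) - 1) else numeric()
  qLung <- 0.85^(seq_len(nLung) - 1)

  depth <- pmax(1000, round(stats::rlnorm(n, sc@depthMeanlog, sc@depthSdlog)))
  counts <- matrix(0, nrow = sc@nTaxaTotal, ncol = n,
                   dimnames = list(taxa, ids))
  fullTarget <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    inhComp <- .tiltToDiversity(qInh, inhTarget[i])
    othComp <- if (nOth > 0) .tiltToDiversity(qOth, oralTarget[i]) else numeric()
    oralComp <- if (nOth > 0) c(0.6 * inhComp, 0.4 * othComp) else inhComp
    if (monopoly[i]) {
      lungComp <- c(sc@monopolyDominance,
                    (1 - sc@monopolyDominance) * qLung[-1] / sum(qLung[-1]))
    } else {
      lungComp <- .tiltToDiversity(qLung, lungTarget[i])
    }
    p <- c(sc@contaminationFraction * oralComp,
           (1 - sc@contaminationFraction) * lungComp)
    ## whole-table tilt when a BVAS slope is planted
    if (sc@slopeBvasDiversity != 0) {
      targetAll <- sc@baseDiversityAll +
        if (disease[i] == "AAV") sc@slopeBvasDiversity * bvas[i] else 0
      targetAll <- max(targetAll, 1.2)
      pos <- p > 0
      p[pos] <- .tiltToDiversity(p[pos], targetAll)
      fullTarget[i] <- targetAll
    }
    pReal <- .rdirichlet(sc@theta * p)
    counts[, i] <- stats::rmultinom(1, size = depth[i], prob = pReal)
  }

  meta <- data.frame(
    disease = disease, sex = sex, smoking = smoking, age = age, bvas = bvas,
    row.names = ids, stringsAsFactors = FALSE)
  ## BALF differential-cell percentages; one sarcoidosis sample left missing
  cellMeans <- ifelse(disease == "AAV", 1, 2)
  mns <- list(c(0.50, 0.15, 0.30, 0.05), c(0.60, 0.35, 0.03, 0.02))
  cells <- t(vapply(seq_len(n), function(i)
    .rdirichlet(30 * mns[[cellMeans[i]]]) * 100, numeric(4)))
  colnames(cells) <- c("balf_macrophage_pct", "balf_lymphocyte_pct",
                       "balf_neutrophil_pct", "balf_eosinophil_pct")
  missIdx <- utils::tail(which(disease == "sarcoidosis"), 1)
  cells[missIdx, ] <- NA_real_
  meta <- cbind(meta, as.data.frame(cells))

  ## zero-count rows can occur at finite depth; that is fine (detected set
  ## downstream is taxa with positive total)
  tab <- suppressWarnings(otuTable(counts, rank = "family", taxaAreRows = TRUE,
                                   sampleData = meta))
  truth <- list(
    scenario = sc,
    inhabitantTaxa = lab$inhabitant,
    oralTaxa = c(lab$inhabitant, lab$oralOther),
    lungTaxa = lab$lung,
    monopolySamples = ids[monopoly],
    monopolyTaxon = "Erythrobacteraceae",
    inhabitantTarget = stats::setNames(inhTarget, ids),
    lungTarget = stats::setNames(lungTarget, ids),
    fullTarget = stats::setNames(fullTarget, ids),
    depth = stats::setNames(depth, ids))
  list(table = tab, metadata = meta, truth = truth)
}

#' Generate a synthetic HMP-style prevalence table
#'
#' A synthetic stand-in for the HMP DACC oral prevalence data: per subsite,
#' detection counts are binomial draws at planted prevalences — inhabitant
#' taxa at `inhabitantPrevalence` (default 0.995) in their own subsite,
#' planted vagrant (and off-subsite inhabitant) taxa at a uniform prevalence
#' in `vagrantRange`, and background taxa below the vagrant cutoff.
#'
#' @param nSubjects specimens per subsite.
#' @param subsites subsite names (default: the nine oral/oropharynx subsites).
#' @param plantedInhabitant named list, subsite -> character vector of taxa.
#' @param plantedVagrant character vector of vagrant-grade taxa.
#' @param nBackground number of sub-cutoff background taxa.
#' @param inhabitantPrevalence,vagrantRange,backgroundPrevalence planted
#'   detection probabilities (all in `[0, 1]`).
#' @param rank taxonomic rank to declare.
#' @param seed optional integer seed.
#' @return a [PrevalenceTable-class].
#' @export
makePrevalenceTable <- function(nSubjects = 200, subsites = .ORAL_SUBSITES,
                                plantedInhabitant = list(),
                                plantedVagrant = character(),
                                nBackground = 40,
                                inhabitantPrevalence = 0.995,
                                vagrantRange = c(0.1, 0.5),
                                backgroundPrevalence = 0.02,
                                rank = "family", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(inhabitantPrevalence, vagrantRange, backgroundPrevalence) < 0) ||
      any(c(inhabitantPrevalence, vagrantRange, backgroundPrevalence) > 1))
    stop("prevalences must lie in [0, 1]")
  allInh <- unique(unlist(plantedInhabitant))
  bg <- if (nBackground > 0) sprintf("BackgroundFamily%02d", seq_len(nBackground)) else character()
  taxa <- unique(c(allInh, plantedVagrant, bg))
  rows <- list()
  for (s in subsites) {
    own <- plantedInhabitant[[s]]
    p <- numeric(length(taxa))
    names(p) <- taxa
    p[taxa %in% c(allInh, plantedVagrant)] <-
      stats::runif(sum(taxa %in% c(allInh, plantedVagrant)),
                   vagrantRange[1], vagrantRange[2])
    p[taxa %in% bg] <- backgroundPrevalence
    if (length(own)) p[own] <- inhabitantPrevalence
    rows[[s]] <- data.frame(
      subsite = s, taxon = taxa,
      detected = stats::rbinom(length(taxa), nSubjects, p),
      total = nSubjects, stringsAsFactors = FALSE)
  }
  prevalenceTable(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                  rank = rank)
}

#' Named preset scenarios
#'
#' One scenario per headline analysis the package validates end-to-end:
#' `"null"` (no planted structure), `"oral_effect"` (disease signal only in
#' the inhabitant taxa, AAV less even), `"nonoral_effect"` (signal only in
#' the non-oral lung block, AAV more even), `"bvas_slope"` (whole-table
#' diversity falls 0.2 per BVAS point in AAV), `"monopoly_cluster"` (11
#' samples, mostly sarcoidosis, with one family monopolizing the lung
#' block), `"sex_confounded"` (the inhabitant-block signal rides on sex,
#' which is imbalanced across diseases).
#'
#' @return named list of [CohortScenario-class] objects.
#' @export
presetScenarios <- function() {
  list(
    null = cohortScenario(),
    oral_effect = cohortScenario(groupEffectLocation = "oral_only",
                                 groupEffectSize = -3),
    nonoral_effect = cohortScenario(groupEffectLocation = "nonoral_only",
                                    groupEffectSize = 3),
    bvas_slope = cohortScenario(slopeBvasDiversity = -0.2),
    monopoly_cluster = cohortScenario(monopolyN = 11),
    sex_confounded = cohortScenario(sexConfounded = TRUE)
  )
}
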