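## The random-taxa-subset null: score the effect of selecting a specific
## taxa set by the percentile rank of the observed statistic on an ECDF of
## the same statistic computed over equal-cardinality random taxa draws.

#' Standardized Mann-Whitney U statistic
#'
#' \eqn{z = (U - n_1 n_2/2) / \sqrt{\mathrm{Var}(U)}} where `U` is the
#' Mann-Whitney statistic for the first group level (midranks at ties) and
#' the variance carries the standard tie-correction term
#' \eqn{n_1 n_2/12\,[(N+1) - \sum(t^3 - t)/(N(N-1))]}.
#'
#' @param values numeric vector.
#' @param groups two-level factor (or coercible); the first level is the
#'   "first" group whose large values push `z` positive.
#' @return the standardized U (z).
#' @export
standardizedU <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) == 0)) stop("a group is empty")
  if (any(is.na(values))) stop("values contain NA")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  N <- n1 + n2
  r <- rank(values)
  U <- sum(r[groups == levels(groups)[1]]) - n1 * (n1 + 1) / 2
  t <- table(values)
  tieterm <- sum(t^3 - t) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tieterm)
  if (v <= 0) stop("zero variance: all values identical")
  (U - n1 * n2 / 2) / sqrt(v)
}

.mwuU <- function(r, idx1, n1) sum(r[idx1]) - n1 * (n1 + 1) / 2

#' Percentile rank of an observed statistic on a set of null draws
#'
#' Default convention: step ECDF with ties counted as "less or equal",
#' `100 * #\{draws <= observed\} / n`. Alternatives: `"lt"` (strict) and
#' `"mid"` (half-weight at ties).
#'
#' @param observed observed statistic.
#' @param nullDraws nonempty numeric vector of null statistics.
#' @param ties tie convention.
#' @return percentile rank in `[0, 100]`.
#' @examples
#' percentileRank(50, 1:99)  # 50.505...
#' @export
percentileRank <- function(observed, nullDraws, ties = c("le", "lt", "mid")) {
  ties <- match.arg(ties)
  if (length(nullDraws) == 0) stop("nullDraws is empty")
  n <- length(nullDraws)
  100 * switch(ties,
    le  = sum(nullDraws <= observed) / n,
    lt  = sum(nullDraws < observed) / n,
    mid = (sum(nullDraws < observed) + 0.5 * sum(nullDraws == observed)) / n)
}

## Per-draw statistic engines operating on a samples x taxa count matrix.
## Return NA for a degenerate draw (too few usable samples / constant x).
.statStandardizedU <- function(cts, cols, group) {
  sub <- cts[, cols, drop = FALSE]
  tot <- rowSums(sub)
  ok <- tot > 0 & !is.na(group)
  g <- droplevels(group[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) return(NA_real_)
  div <- 1 / (rowSums(sub[ok, , drop = FALSE]^2) / tot[ok]^2)
  if (length(unique(div)) == 1) return(NA_real_)
  standardizedU(div, g)
}

.statOlsSlope <- function(cts, cols, bvas) {
  sub <- cts[, cols, drop = FALSE]
  tot <- rowSums(sub)
  ok <- tot > 0 & !is.na(bvas)
  if (sum(ok) < 3) return(NA_real_)
  x <- bvas[ok]
  if (stats::var(x) == 0) return(NA_real_)
  div <- 1 / (rowSums(sub[ok, , drop = FALSE]^2) / tot[ok]^2)
  stats::cov(x, div) / stats::var(x)
}

#' Random-taxa-subset null ECDF for a taxa-selection effect
#'
#' Computes the observed statistic (standardized U for the between-disease
#' difference in per-sample inverse Simpson, or the OLS slope of inverse
#' Simpson on BVAS among AAV samples) on the supplied taxa set, then draws
#' `nDraws` taxa subsets of the same cardinality uniformly without
#' replacement from all detected taxa, recomputes the statistic per draw, and
#' reports the percentile rank of the observed value on the resulting ECDF.
#'
#' Draws yielding fewer than 2 usable samples in a group (or a constant/too
#' short BVAS vector for the slope) are discarded and counted; if more than
#' 10% of draws are discarded the table is considered too sparse and an
#' error is raised.
#'
#' @param x an [OtuTable-class] whose `colData` carries `disease` (and `bvas`
#'   for the slope statistic).
#' @param observedSet a [TaxaSet-class]; its cardinality after intersection
#'   with the table's taxa fixes `k`.
#' @param statistic `"standardized_U"` or `"ols_slope"`.
#' @param nDraws number of random draws (default 2000).
#' @param seed integer seed for the draws (optional but recommended).
#' @param stratumFilter optional named list, e.g. `list(sex = "female")`,
#'   restricting the analysis to matching samples before anything else.
#' @param ties percentile-rank tie convention, see [percentileRank()].
#' @return a [NullEcdfResult-class].
#' @export
nullEcdf <- function(x, observedSet,
                     statistic = c("standardized_U", "ols_slope"),
                     nDraws = 2000, seed = NULL, stratumFilter = NULL,
                     ties = c("le", "lt", "mid")) {
  statistic <- match.arg(statistic)
  ties <- match.arg(ties)
  stopifnot(is(observedSet, "TaxaSet"))
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  if (!"disease" %in% names(meta)) stop("colData needs a 'disease' column")

  keep <- rep(TRUE, ncol(x))
  stratum <- NA_character_
  if (!is.null(stratumFilter)) {
    for (nm in names(stratumFilter))
      keep <- keep & !is.na(meta[[nm]]) & meta[[nm]] == stratumFilter[[nm]]
    stratum <- paste(names(stratumFilter), unlist(stratumFilter),
                     sep = "=", collapse = ",")
  }
  cts <- t(otuCounts(x)[, keep, drop = FALSE])  # samples x taxa
  meta <- meta[keep, , drop = FALSE]

  detected <- colnames(cts)[colSums(cts) > 0]
  obsLabels <- intersect(observedSet@labels, colnames(cts))
  k <- length(obsLabels)
  if (k < 1) stop("observed taxa set shares no taxa with the table")
  if (k > length(detected)) stop("k exceeds the number of detected taxa")

  if (statistic == "standardized_U") {
    group <- factor(meta$disease, levels = c("AAV", "sarcoidosis"))
    statFun <- function(cols) .statStandardizedU(cts, cols, group)
  } else {
    if (!"bvas" %in% names(meta)) stop("colData needs 'bvas' for ols_slope")
    bvas <- ifelse(!is.na(meta$disease) & meta$disease == "AAV",
                   meta$bvas, NA_real_)
    statFun <- function(cols) .statOlsSlope(cts, cols, bvas)
  }

  observed <- statFun(obsLabels)
  if (is.na(observed)) stop("observed statistic is degenerate on this table")

  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(nDraws), function(i)
    statFun(sample(detected, k, replace = FALSE)), numeric(1))
  bad <- is.na(draws)
  if (mean(bad) > 0.10)
    stop(sprintf("table too sparse: %d of %d draws degenerate",
                 sum(bad), nDraws))
  if (any(bad))
    message(sum(bad), " degenerate draw(s) discarded")
  draws <- draws[!bad]

  new("NullEcdfResult",
      statisticKind = statistic, observed = observed, nullDraws = draws,
      percentileRank = percentileRank(observed, draws, ties),
      k = as.integer(k), nDraws = as.integer(nDraws),
      nDiscarded = as.integer(sum(bad)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      stratum = stratum, ties = ties)
}

#' Stratified random-taxa-subset null
#'
#' Repeats the full [nullEcdf()] procedure within each level of a metadata
#' column (e.g. `sex`), reporting one [NullEcdfResult-class] per usable
#' level. Levels with fewer than 2 usable samples per disease group are
#' skipped with a message. Each level uses an independent derived seed
#' (`seed + level index`).
#'
#' @inheritParams nullEcdf
#' @param stratum name of the `colData` column to stratify by.
#' @return named list of [NullEcdfResult-class], one per analyzed level.
#' @export
stratifiedNullEcdf <- function(x, observedSet,
                               statistic = c("standardized_U", "ols_slope"),
                               stratum = "sex", nDraws = 2000, seed = NULL,
                               ties = c("le", "lt", "mid")) {
  statistic <- match.arg(statistic)
  ties <- match.arg(ties)
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  if (!stratum %in% names(meta)) stop("no such colData column: ", stratum)
  levelsHere <- sort(unique(stats::na.omit(meta[[stratum]])))
  out <- list()
  for (i in seq_along(levelsHere)) {
    lv <- levelsHere[i]
    res <- tryCatch(
      nullEcdf(x, observedSet, statistic = statistic, nDraws = nDraws,
               seed = if (is.null(seed)) NULL else seed + i,
               stratumFilter = stats::setNames(list(lv), stratum),
               ties = ties),
      error = function(e) {
        message("skipping stratum ", stratum, "=", lv, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[paste0(stratum, "=", lv)]] <- res
  }
  out
}

setMethod("show", "NullEcdfResult", function(object) {
  cat(sprintf("NullEcdfResult (%s%s): observed %.4f, percentile rank %.1f%%\n",
              object@statisticKind,
              if (is.na(object@stratum)) "" else paste0(", ", object@stratum),
              object@observed, object@percentileRank))
  cat(sprintf("  k = %d taxa, %d draws (%d discarded), ties '%s'\n",
              object@k, object@nDraws, object@nDiscarded, object@ties))
})

#' Export a NullEcdfResult
#'
#' Writes a JSON record (observed, rank, k, draws requested, seed, stratum)
#' and, alongside it, the raw null draws as a one-column TSV for audit.
#'
#' @param x a [NullEcdfResult-class].
#' @param path JSON output path; draws go to `<path>.draws.tsv`.
#' @return `path`, invisibly.
#' @export
writeNullEcdfResult <- function(x, path) {
  rec <- list(statistic = x@statisticKind, observed = x@observed,
              percentile_rank = x@percentileRank, k = x@k,
              n_draws = x@nDraws, n_discarded = x@nDiscarded,
              seed = x@seed, stratum = x@stratum, ties = x@ties)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(null_draw = x@nullDraws),
                     paste0(path, ".draws.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
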