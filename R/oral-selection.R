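## Selection of oral "inhabitant" and "vagrant" taxa from an HMP-style
## prevalence table, with the Wilson-score justification of the prevalence
## cutoff and the threshold-stability curve.

#' Wilson score confidence interval for a binomial proportion
#'
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'            {1 + z^2/n}}
#' with \eqn{\hat p = k/n} and \eqn{z} the standard-normal quantile at
#' `(1 + conf)/2`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param conf confidence level in `(0, 1)`.
#' @return a [WilsonInterval-class].
#' @examples
#' wilsonInterval(98, 100)  # lower bound ~0.930
#' @export
wilsonInterval <- function(k, n, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0, 1)")
  z <- stats::qnorm((1 + conf) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  new("WilsonInterval", k = k, n = n, conf = conf,
      lower = max(0, (centre - half) / denom),
      upper = min(1, (centre + half) / denom))
}

setMethod("show", "WilsonInterval", function(object) {
  cat(sprintf("Wilson %d/%d: %.4f, %g%% CI [%.4f, %.4f]\n",
              object@k, object@n, object@k / object@n,
              100 * object@conf, object@lower, object@upper))
})

#' Smallest prevalence whose Wilson lower bound clears a target
#'
#' Scans integer success counts `k = 0..n` for the smallest fraction `k/n`
#' whose Wilson `conf`-level lower bound exceeds `targetLb`. This is the rule
#' that motivates a 98% prevalence cutoff for "inhabitant" membership: at HMP
#' subsite sample sizes, a taxon seen in ~98% of specimens is the least
#' prevalent one whose binomial probability still exceeds 0.95 with 95%
#' confidence.
#'
#' @param n subsite sample size.
#' @param targetLb lower-bound target (default 0.95).
#' @param conf Wilson confidence level (default 0.95).
#' @return a list with `attainable` (logical), `k`, and `fraction` (`k/n`;
#'   both `NA` when no `k <= n` clears the target — small `n` is a result,
#'   not an error).
#' @export
minPrevalenceForLowerBound <- function(n, targetLb = 0.95, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  # Wilson lower bound is monotone increasing in k for fixed n
  for (k in 0:n) {
    if (wilsonInterval(k, n, conf)@lower > targetLb)
      return(list(attainable = TRUE, k = k, fraction = k / n))
  }
  list(attainable = FALSE, k = NA_integer_, fraction = NA_real_)
}

.provThreshold <- function(tag, threshold, strict)
  sprintf("%s@%s%g", tag, if (strict) ">" else ">=", threshold)

#' Inhabitant taxa of an oral subsite
#'
#' Taxa detected in over `threshold` (strictly, matching the "over 98%" rule;
#' `strict = FALSE` switches to `>=`) of the specimens of one subsite.
#'
#' @param prev a [PrevalenceTable-class].
#' @param subsite subsite name.
#' @param threshold prevalence cutoff (default 0.98).
#' @param strict strict (`>`) or weak (`>=`) inequality.
#' @return a [TaxaSet-class] with provenance `"inhabitant:<subsite>@><thr>"`.
#' @export
inhabitantTaxa <- function(prev, subsite, threshold = 0.98, strict = TRUE) {
  fr <- prevalenceOf(prev, subsite)
  keep <- if (strict) fr > threshold else fr >= threshold
  taxaSet(names(fr)[keep], rank = prev@rank,
          provenance = .provThreshold(paste0("inhabitant:", subsite),
                                      threshold, strict))
}

#' Vagrant taxa across oral subsites
#'
#' Oral-site taxa detected in over `threshold` (default 5%) of subjects.
#' By default prevalence is computed per subsite and the qualifying taxa are
#' unioned across subsites (any-site detection; the conservative, larger
#' exclusion set). `pooled = TRUE` instead pools detected/total over the
#' subsites before thresholding.
#'
#' @param prev a [PrevalenceTable-class].
#' @param subsites subsites to consider (default: all in the table).
#' @param threshold prevalence cutoff (default 0.05).
#' @param strict strict (`>`) or weak (`>=`) inequality.
#' @param pooled pool specimens across subsites instead of unioning.
#' @return a [TaxaSet-class] with provenance `"vagrant@><thr>"`.
#' @export
vagrantTaxa <- function(prev, subsites = NULL, threshold = 0.05,
                        strict = TRUE, pooled = FALSE) {
  if (is.null(subsites)) subsites <- unique(prev@data$subsite)
  if (length(subsites) == 0) stop("subsites must be nonempty")
  unknown <- setdiff(subsites, prev@data$subsite)
  if (length(unknown)) stop("unknown subsite(s): ", paste(unknown, collapse = ", "))
  d <- prev@data[prev@data$subsite %in% subsites, ]
  if (pooled) {
    det <- tapply(d$detected, d$taxon, sum)
    tot <- tapply(d$total, d$taxon, sum)
    fr <- det / tot
    keep <- if (strict) fr > threshold else fr >= threshold
    labels <- names(fr)[keep]
  } else {
    fr <- d$detected / d$total
    keep <- if (strict) fr > threshold else fr >= threshold
    labels <- unique(d$taxon[keep])
  }
  taxaSet(sort(labels), rank = prev@rank,
          provenance = .provThreshold("vagrant", threshold, strict))
}

#' Stability of inhabitant counts over a threshold grid
#'
#' Counts, per subsite, the taxa whose prevalence clears each threshold in an
#' increasing grid (default 0.98 to 0.995 in steps of 0.005). A subsite whose
#' count at 0.98 equals its count at 0.99 is flagged stable — the rule that
#' singled out the hard palate.
#'
#' @param prev a [PrevalenceTable-class].
#' @param subsites subsites to tabulate (default: all).
#' @param thresholds increasing prevalence grid.
#' @param strict inequality convention, as in [inhabitantTaxa()].
#' @return a [StabilityCurve-class].
#' @export
stabilityCurve <- function(prev, subsites = NULL,
                           thresholds = seq(0.98, 0.995, by = 0.005),
                           strict = TRUE) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (is.null(subsites)) subsites <- unique(prev@data$subsite)
  grid <- expand.grid(subsite = subsites, threshold = thresholds,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(s, t)
    length(inhabitantTaxa(prev, s, t, strict = strict)),
    grid$subsite, grid$threshold)
  stable <- character()
  if (all(c(0.98, 0.99) %in% round(thresholds, 10))) {
    for (s in subsites) {
      c98 <- grid$count[grid$subsite == s & abs(grid$threshold - 0.98) < 1e-9]
      c99 <- grid$count[grid$subsite == s & abs(grid$threshold - 0.99) < 1e-9]
      if (length(c98) && length(c99) && c98 == c99) stable <- c(stable, s)
    }
  }
  new("StabilityCurve", data = grid, stableSubsites = stable)
}

setMethod("show", "StabilityCurve", function(object) {
  cat(sprintf("StabilityCurve: %d subsites x %d thresholds\n",
              length(unique(object@data$subsite)),
              length(unique(object@data$threshold))))
  if (length(object@stableSubsites))
    cat("  stable (count at 0.98 == count at 0.99):",
        paste(object@stableSubsites, collapse = ", "), "\n")
})
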