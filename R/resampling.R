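## Permutation Mann-Whitney tests, bootstrap CI for the diversity-on-BVAS
## slope, and single-predictor PERMANOVA on a dissimilarity matrix.

#' Permutation Mann-Whitney U test
#'
#' Two-sided p-value from the permutation distribution of the Mann-Whitney U
#' (midranks at ties; the standardized U is an affine function of U under
#' label permutation, so U itself is the permutation statistic). When the
#' number of distinct group assignments `choose(n, n1)` is at most
#' `exactCap`, the distribution is enumerated exactly; otherwise `nPerm`
#' Monte Carlo permutations are used with the add-one correction. Two-sided p
#' doubles the smaller tail, capped at 1.
#'
#' @param values numeric vector.
#' @param groups two-level factor (or coercible).
#' @param nPerm Monte Carlo permutations (default 10000).
#' @param seed integer seed for the Monte Carlo path.
#' @param exactIfFeasible enumerate when feasible (default TRUE).
#' @param exactCap assignment-count cap for exact enumeration (default 20000).
#' @return a [PermutationTestResult-class].
#' @export
permutationMWU <- function(values, groups, nPerm = 10000, seed = NULL,
                           exactIfFeasible = TRUE, exactCap = 20000) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("need two nonempty groups")
  n1 <- sum(groups == levels(groups)[1])
  N <- length(values)
  r <- rank(values)
  idx1 <- which(groups == levels(groups)[1])
  uObs <- .mwuU(r, idx1, n1)
  z <- tryCatch(standardizedU(values, groups), error = function(e) NA_real_)

  exact <- exactIfFeasible && choose(N, n1) <= exactCap
  if (exact) {
    uAll <- utils::combn(N, n1, function(ix) .mwuU(r, ix, n1))
    pLo <- mean(uAll <= uObs)
    pHi <- mean(uAll >= uObs)
    p <- min(1, 2 * min(pLo, pHi))
    nPermOut <- NA_integer_
  } else {
    if (!is.null(seed)) set.seed(seed)
    uPerm <- vapply(seq_len(nPerm),
                    function(i) .mwuU(r, sample.int(N, n1), n1), numeric(1))
    pLo <- (1 + sum(uPerm <= uObs)) / (nPerm + 1)
    pHi <- (1 + sum(uPerm >= uObs)) / (nPerm + 1)
    p <- min(1, 2 * min(pLo, pHi))
    nPermOut <- as.integer(nPerm)
  }
  new("PermutationTestResult", statistic = z, u = uObs, pValue = p,
      nPermutations = nPermOut, exact = exact,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Permutation Mann-Whitney: U = %g, z = %.3f, p = %.4g (%s)\n",
              object@u, object@statistic, object@pValue,
              if (object@exact) "exact enumeration"
              else sprintf("%d permutations", object@nPermutations)))
})

#' OLS slope with a case-resampling bootstrap confidence interval
#'
#' The slope is `cov(x, y) / var(x)`. The CI is the percentile bootstrap over
#' case resamples (pairs `(x_i, y_i)` drawn with replacement); replicates
#' whose resampled `x` is constant are discarded and counted.
#'
#' @param y response (diversity) vector.
#' @param x predictor (BVAS) vector, not constant, `length >= 3`.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param method CI flavour; only `"percentile"` is implemented.
#' @return a [SlopeEstimate-class].
#' @export
olsSlopeBootstrap <- function(y, x, nBoot = 2000, seed = NULL, conf = 0.95,
                              method = "percentile") {
  method <- match.arg(method, "percentile")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations")
  if (stats::var(x) == 0) stop("constant predictor")
  beta <- stats::cov(x, y) / stats::var(x)
  if (!is.null(seed)) set.seed(seed)
  betas <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    ix <- sample.int(n, n, replace = TRUE)
    xv <- stats::var(x[ix])
    if (xv == 0) next
    betas[b] <- stats::cov(x[ix], y[ix]) / xv
  }
  disc <- sum(is.na(betas))
  if (disc) message(disc, " constant-x bootstrap replicate(s) discarded")
  betas <- betas[!is.na(betas)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(betas, c(alpha, 1 - alpha)))
  new("SlopeEstimate", beta = beta, ciLower = ci[1], ciUpper = ci[2],
      nBoot = as.integer(nBoot), nDiscarded = as.integer(disc),
      method = method, conf = conf,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "SlopeEstimate", function(object) {
  cat(sprintf("Slope %.4g (%g%% %s bootstrap CI: %.4g to %.4g; %d replicates)\n",
              object@beta, 100 * object@conf, object@method,
              object@ciLower, object@ciUpper, object@nBoot))
})

#' Single-predictor PERMANOVA on a dissimilarity matrix
#'
#' Gower construction: \eqn{A = -\frac12 d_{ij}^2}, \eqn{G} the
#' double-centered \eqn{A}; with the hat matrix \eqn{H} of the design
#' `[1, predictor coding]`,
#' \deqn{F = \frac{\mathrm{tr}(HGH)/df_m}{\mathrm{tr}((I-H)G(I-H))/df_r}.}
#' The p-value permutes sample identities (rows and columns of `D` jointly),
#' one predictor at a time, with the add-one convention. Samples with a
#' missing predictor value are removed (complete-case) from both dimensions
#' of `D` first.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param predictor vector aligned to `D`'s ids: by names when named,
#'   positionally otherwise. Character/factor predictors are dummy-coded;
#'   numeric ones enter as a single column.
#' @param nPerm permutations (default 9999).
#' @param seed integer seed.
#' @param name predictor name for reporting.
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(D, predictor, nPerm = 9999, seed = NULL,
                      name = deparse(substitute(predictor))) {
  stopifnot(is(D, "DissimilarityMatrix"))
  v <- dissValues(D)
  ids <- rownames(v)
  if (!is.null(names(predictor))) {
    if (!all(ids %in% names(predictor)))
      stop("predictor names do not cover the matrix ids")
    predictor <- predictor[ids]
  } else if (length(predictor) != nrow(v)) {
    stop("predictor length does not match the matrix")
  }
  ok <- !is.na(predictor)
  v <- v[ok, ok, drop = FALSE]
  predictor <- predictor[ok]
  n <- nrow(v)
  if (n < 3) stop("fewer than 3 complete cases")
  if (is.character(predictor)) predictor <- factor(predictor)
  if (is.factor(predictor)) {
    predictor <- droplevels(predictor)
    if (nlevels(predictor) < 2) stop("predictor constant after complete-case filtering")
    dfm <- nlevels(predictor) - 1L
    X <- stats::model.matrix(~predictor)
  } else {
    if (stats::var(predictor) == 0) stop("predictor constant after complete-case filtering")
    dfm <- 1L
    X <- cbind(1, predictor)
  }
  dfr <- n - dfm - 1L

  A <- -0.5 * v^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  H <- X %*% solve(crossprod(X), t(X))
  # H symmetric idempotent: tr(HGH) = tr(GH) = sum(G * H)
  fFrom <- function(Gp) {
    ssm <- sum(Gp * H)
    ssr <- sum(diag(Gp)) - ssm
    (ssm / dfm) / (ssr / dfr)
  }
  fObs <- fFrom(G)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    if (fFrom(G[p, p]) >= fObs) ge <- ge + 1L
  }
  new("PermanovaResult", pseudoF = fObs,
      pValue = (1 + ge) / (1 + nPerm),
      nPermutations = as.integer(nPerm), dfModel = dfm,
      dfResidual = as.integer(dfr), predictor = name,
      completeCaseN = as.integer(n),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf(
    "PERMANOVA [%s]: pseudo-F(%d, %d) = %.4f, p = %.4g (%d permutations, n = %d)\n",
    object@predictor, object@dfModel, object@dfResidual, object@pseudoF,
    object@pValue, object@nPermutations, object@completeCaseN))
})
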