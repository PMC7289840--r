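## Simpson-family alpha-diversity and the two dissimilarities used downstream:
## Morisita-Horn between samples, Jaccard between taxa presence patterns.

.clip01 <- function(v, what = "dissimilarity") {
  if (any(v < -.CLIP_TOL | v > 1 + .CLIP_TOL, na.rm = TRUE))
    stop(what, " outside [0, 1] beyond floating tolerance")
  pmin(pmax(v, 0), 1)
}

#' Simpson concentration index
#'
#' `simpsonIndex` returns the Simpson concentration \eqn{\lambda = \sum p_i^2};
#' `inverseSimpson` returns \eqn{1/\lambda} (the conventional inverse Simpson,
#' in effective-number-of-taxa units), or \eqn{1/(1-\lambda)} when
#' `gini = TRUE` (the inverse Gini-Simpson reading; see the vignette for why
#' both are offered).
#'
#' @param counts nonnegative count vector with at least one positive entry.
#' @return `simpsonIndex`: a value in `[0, 1]`; `inverseSimpson`: a value in
#'   `[1, S]` for `S` taxa with positive count.
#' @examples
#' inverseSimpson(c(10, 10, 10, 10))  # uniform over 4 taxa -> 4
#' @export
simpsonIndex <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector: Simpson index undefined")
  sum((counts / tot)^2)
}

#' @rdname simpsonIndex
#' @param gini use the inverse Gini-Simpson variant `1/(1 - lambda)`.
#' @export
inverseSimpson <- function(counts, gini = FALSE) {
  lam <- simpsonIndex(counts)
  if (gini) {
    if (lam >= 1) stop("single-taxon community: inverse Gini-Simpson undefined")
    1 / (1 - lam)
  } else 1 / lam
}

#' Per-sample alpha-diversity of an OtuTable
#'
#' @param x an [OtuTable-class].
#' @param index `"inverse_simpson"` or `"simpson"`.
#' @param gini variant switch passed to [inverseSimpson()].
#' @return named numeric vector over samples; zero-total (flagged) samples
#'   get `NA` with a message.
#' @export
sampleDiversity <- function(x, index = c("inverse_simpson", "simpson"),
                            gini = FALSE) {
  index <- match.arg(index)
  cts <- otuCounts(x)
  tot <- colSums(cts)
  out <- rep(NA_real_, ncol(cts))
  names(out) <- colnames(cts)
  ok <- tot > 0
  if (any(!ok))
    message("diversity undefined (zero total) for: ",
            paste(colnames(cts)[!ok], collapse = ", "))
  lam <- colSums((cts[, ok, drop = FALSE] /
                    rep(tot[ok], each = nrow(cts)))^2)
  out[ok] <- switch(index,
    simpson = lam,
    inverse_simpson = if (gini) 1 / (1 - lam) else 1 / lam)
  out
}

#' Morisita-Horn dissimilarity between two count vectors
#'
#' The abundance-based Horn variant
#' \deqn{D = 1 - \frac{2\sum x_i y_i}{(d_x + d_y)\,XY},\qquad
#'       d_x = \sum x_i^2 / X^2,\; X = \sum x_i,}
#' the common "Morisita-Horn" of ecology texts. Equals 0 for identical
#' relative compositions and 1 for disjoint supports.
#'
#' @param x,y equal-length nonnegative count vectors with positive totals.
#' @return dissimilarity in `[0, 1]`.
#' @export
morisitaHorn <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors of unequal length")
  if (any(c(x, y) < 0)) stop("counts must be nonnegative")
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0)
    stop("zero-total count vector (code: zero_total_sample)")
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  .clip01(1 - 2 * sum(x * y) / ((dx + dy) * X * Y), "Morisita-Horn")
}

#' Pairwise Morisita-Horn matrix over samples
#'
#' Zero-total (flagged) samples are excluded with a message; at least two
#' usable samples are required.
#'
#' @param x an [OtuTable-class].
#' @return a [DissimilarityMatrix-class] with metric `"morisita_horn"`.
#' @export
morisitaHornMatrix <- function(x) {
  cts <- otuCounts(x)
  tot <- colSums(cts)
  if (any(tot == 0)) {
    message("excluding zero-total sample(s): ",
            paste(colnames(cts)[tot == 0], collapse = ", "))
    cts <- cts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  n <- ncol(cts)
  if (n < 2) stop("fewer than 2 usable samples")
  # vectorised: cross-products and per-sample concentrations
  P <- sweep(cts, 2, tot, "/")
  cross <- crossprod(P)                     # sum_i p_xi p_yi
  d <- diag(cross)                          # sum p_i^2 per sample
  D <- 1 - 2 * cross / outer(d, d, "+")
  diag(D) <- 0
  D <- .clip01(D, "Morisita-Horn")
  D <- (D + t(D)) / 2
  dissimilarityMatrix(D, metric = "morisita_horn")
}

#' Jaccard distances between taxa presence patterns
#'
#' Each taxon is reduced to its presence/absence pattern across samples;
#' distance is `1 - |A intersect B| / |A union B|`. Two taxa absent everywhere
#' are at distance 0 (identical empty sets), reported as degenerate via a
#' message, so the matrix and single-linkage taxa ordering stay well-defined.
#'
#' @param x an [OtuTable-class] with at least 2 taxa.
#' @return a [DissimilarityMatrix-class] with metric `"jaccard_taxa"`.
#' @export
jaccardBetweenTaxa <- function(x) {
  pres <- otuCounts(x) > 0
  if (nrow(pres) < 2) stop("fewer than 2 taxa")
  inter <- tcrossprod(pres * 1)
  sz <- rowSums(pres)
  uni <- outer(sz, sz, "+") - inter
  D <- ifelse(uni == 0, 0, 1 - inter / uni)
  if (any(sz == 0))
    message("taxa absent from every sample (Jaccard degenerate): ",
            paste(rownames(pres)[sz == 0], collapse = ", "))
  diag(D) <- 0
  dissimilarityMatrix(.clip01(D, "Jaccard"), metric = "jaccard_taxa")
}

#' Construct a DissimilarityMatrix
#'
#' @param values symmetric numeric matrix with zero diagonal and dimnames.
#'   For the two bounded metrics (`morisita_horn`, `jaccard_taxa`) entries
#'   within `1e-12` outside `[0, 1]` are clipped and anything beyond errors;
#'   other metrics (e.g. `"euclidean"`) only need nonnegative entries.
#' @param metric metric name.
#' @return a [DissimilarityMatrix-class].
#' @export
dissimilarityMatrix <- function(values, metric) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("id", seq_len(nrow(values)))
  if (metric %in% c("morisita_horn", "jaccard_taxa"))
    values <- .clip01(values, metric)
  obj <- new("DissimilarityMatrix", values = values, metric = metric)
  validObject(obj)
  obj
}

#' @describeIn dissimilarityMatrix the matrix of values.
#' @export
setMethod("dissValues", "DissimilarityMatrix", function(x) x@values)

#' @describeIn dissimilarityMatrix the metric name.
#' @export
setMethod("dissMetric", "DissimilarityMatrix", function(x) x@metric)

setMethod("show", "DissimilarityMatrix", function(object) {
  cat(sprintf("DissimilarityMatrix (%s): %d x %d, range [%.3f, %.3f]\n",
              object@metric, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("dim", "DissimilarityMatrix", function(x) dim(x@values))

#' Read / write a dissimilarity matrix as square TSV
#'
#' @param path file path.
#' @param metric metric name to declare on read.
#' @return a [DissimilarityMatrix-class] (read) or `path` invisibly (write).
#' @export
readDissimilarity <- function(path, metric) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  dissimilarityMatrix(as.matrix(df), metric = metric)
}

#' @rdname readDissimilarity
#' @param x a [DissimilarityMatrix-class].
#' @export
writeDissimilarity <- function(x, path) {
  df <- data.frame(id = rownames(x@values), x@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
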