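## Dual hierarchical clustering: complete linkage on Morisita-Horn between
## samples, single linkage on Jaccard between taxa; heatmap-ready ordered
## matrices and Newick export. Agglomeration itself is stats::hclust, which
## breaks equal-height ties deterministically by pair order, so leaf orders
## are reproducible for a given input ordering.

#' Hierarchical clustering of a dissimilarity matrix
#'
#' @param D a [DissimilarityMatrix-class] with `n >= 2`.
#' @param linkage `"complete"` (sample dendrograms) or `"single"` (taxa
#'   ordering).
#' @return an `hclust` object; the dissimilarity metric is recorded in
#'   `$dist.method`.
#' @export
hierarchicalCluster <- function(D, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is(D, "DissimilarityMatrix"))
  if (nrow(dissValues(D)) < 2) stop("need at least 2 items")
  d <- stats::as.dist(dissValues(D))
  hc <- stats::hclust(d, method = linkage)
  hc$dist.method <- dissMetric(D)
  hc
}

#' Cut a dendrogram into flat clusters
#'
#' @param dend an `hclust` object.
#' @param k number of clusters, or
#' @param h merge height at which to cut (exactly one of `k`/`h`).
#' @return named integer vector of cluster labels.
#' @export
cutClusters <- function(dend, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) stop("supply exactly one of k or h")
  if (!is.null(k) && (k < 1 || k > length(dend$order)))
    stop("k must lie in [1, n]")
  stats::cutree(dend, k = k, h = h)
}

#' Heatmap-ready ordered relative-abundance matrix
#'
#' Normalizes each sample's counts to relative abundances and reorders
#' samples and taxa by the leaf orders of the two dendrograms (the natural
#' agglomeration order; no optimal-leaf-ordering rotation).
#'
#' @param x an [OtuTable-class].
#' @param sampleDend `hclust` over the samples (leaves must match sample ids).
#' @param taxaDend `hclust` over the taxa (leaves must match taxon labels).
#' @return list with `matrix` (samples x taxa relative abundances, reordered),
#'   `sampleOrder`, `taxaOrder`.
#' @export
orderedHeatmapMatrix <- function(x, sampleDend, taxaDend) {
  cts <- t(otuCounts(x))  # samples x taxa
  if (!setequal(sampleDend$labels, rownames(cts)))
    stop("sample dendrogram leaves do not match the table's sample ids")
  if (!setequal(taxaDend$labels, colnames(cts)))
    stop("taxa dendrogram leaves do not match the table's taxon labels")
  tot <- rowSums(cts)
  if (any(tot == 0)) stop("zero-total sample(s): cannot normalize")
  rel <- cts / tot
  so <- sampleDend$labels[sampleDend$order]
  to <- taxaDend$labels[taxaDend$order]
  list(matrix = rel[so, to, drop = FALSE], sampleOrder = so, taxaOrder = to)
}

#' Write an ordered matrix as TSV / read it back
#'
#' @param m numeric matrix with dimnames (e.g. `$matrix` from
#'   [orderedHeatmapMatrix()]).
#' @param path file path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
writeOrderedMatrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOrderedMatrix
#' @export
readOrderedMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths derive from the merge heights (via `ape::as.phylo`).
#'
#' @param dend an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
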