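#' Construct an OtuTable
#'
#' Validates and wraps a count matrix into an [OtuTable-class]. Counts must be
#' nonnegative and integer-valued with unique sample ids and taxon labels.
#' Samples with a zero total are an error at construction (they carry no
#' community information); zero totals arising later from taxa subsetting are
#' flagged instead, see [subsetTaxa()].
#'
#' @param counts numeric matrix of read counts. By default taxa are rows and
#'   samples are columns; set `taxaAreRows = FALSE` for the transpose.
#' @param rank taxonomic rank of the taxa: `"family"`, `"genus"` or `"otu"`.
#' @param taxaAreRows orientation flag.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata.
#'   Matched to samples by rownames, or by a `sample_id` column if present;
#'   its ids must cover every sample in `counts` (join failures are errors).
#' @param allowZeroSamples keep zero-total samples (flagged) instead of
#'   erroring; used internally by [subsetTaxa()].
#' @return an [OtuTable-class].
#' @examples
#' m <- matrix(rpois(12, 5) + 1, nrow = 3,
#'             dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
#' otuTable(m, rank = "family")
#' @export
otuTable <- function(counts, rank = c("family", "genus", "otu"),
                     taxaAreRows = TRUE, sampleData = NULL,
                     allowZeroSamples = FALSE) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty count table")
  if (!taxaAreRows) counts <- t(counts)
  if (is.null(rownames(counts))) stop("taxon labels are required")
  if (is.null(colnames(counts))) stop("sample ids are required")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated taxon labels: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integer-valued")
  storage.mode(counts) <- "double"
  counts <- round(counts)

  zero <- colSums(counts) == 0
  if (any(zero) && !allowZeroSamples)
    stop("zero-total sample(s) at ingest: ", paste(colnames(counts)[zero], collapse = ", "))

  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) cd <- .joinSampleData(sampleData, colnames(counts))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  obj <- new("OtuTable", se, rank = rank)
  S4Vectors::metadata(obj)$zero_total_samples <- colnames(counts)[zero]
  validObject(obj)
  obj
}

.joinSampleData <- function(sampleData, ids) {
  df <- as.data.frame(sampleData)
  if ("sample_id" %in% names(df)) {
    if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
  }
  missing <- setdiff(ids, rownames(df))
  if (length(missing))
    stop("metadata is missing sample(s): ", paste(missing, collapse = ", "))
  df <- df[ids, , drop = FALSE]
  .validateSampleMetadata(df)
  S4Vectors::DataFrame(df)
}

## Field-level checks on the clinical covariates; columns are optional but
## must be well-formed when present. BVAS outside the AAV group is allowed
## with a warning (the study design records it for AAV only).
.validateSampleMetadata <- function(df) {
  chk <- function(col, allowed) {
    if (col %in% names(df)) {
      bad <- !is.na(df[[col]]) & !df[[col]] %in% allowed
      if (any(bad))
        stop(sprintf("invalid %s value(s): %s", col,
                     paste(unique(df[[col]][bad]), collapse = ", ")))
    }
  }
  chk("disease", c("AAV", "sarcoidosis"))
  chk("sex", c("female", "male"))
  chk("smoking", c("never", "former", "current"))
  if ("bvas" %in% names(df)) {
    b <- df$bvas
    if (any(!is.na(b) & (b < 0 | abs(b - round(b)) > 1e-8)))
      stop("bvas must be a nonnegative integer or missing")
    if ("disease" %in% names(df)) {
      odd <- !is.na(b) & !is.na(df$disease) & df$disease != "AAV"
      if (any(odd))
        warning("BVAS present for non-AAV sample(s): ",
                paste(rownames(df)[odd], collapse = ", "))
    }
  }
  for (col in grep("^balf_.*_pct$", names(df), value = TRUE)) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop(col, " must lie in [0, 100] or be missing")
  }
  invisible(df)
}

#' @describeIn otuTable taxonomic rank of the table.
#' @export
setMethod("taxRank", "OtuTable", function(x) x@rank)

#' @describeIn otuTable count matrix, taxa x samples.
#' @export
setMethod("otuCounts", "OtuTable", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @describeIn otuTable sample ids.
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x))

#' @describeIn otuTable taxon labels.
#' @export
setMethod("taxonLabels", "OtuTable", function(x) rownames(x))

#' @describeIn otuTable per-sample metadata as a `DataFrame`.
#' @export
setMethod("sampleData", "OtuTable", function(x) SummarizedExperiment::colData(x))

#' @describeIn otuTable ids of samples flagged as zero-total after subsetting.
#' @export
setMethod("flaggedSamples", "OtuTable", function(x) {
  fl <- S4Vectors::metadata(x)$zero_total_samples
  if (is.null(fl)) character() else fl
})

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable: %d taxa (%s rank) x %d samples\n",
              nrow(object), object@rank, ncol(object)))
  cat(sprintf("  total reads: %s; per-sample median: %s\n",
              format(sum(otuCounts(object)), big.mark = ","),
              format(stats::median(colSums(otuCounts(object))), big.mark = ",")))
  fl <- flaggedSamples(object)
  if (length(fl)) cat("  flagged zero-total samples:", paste(fl, collapse = ", "), "\n")
  if (ncol(SummarizedExperiment::colData(object)))
    cat("  metadata:", paste(names(SummarizedExperiment::colData(object)), collapse = ", "), "\n")
})

#' Read a count table from TSV or BIOM
#'
#' TSV: tab-delimited, `#` comment lines permitted, first column holds sample
#' ids when `samplesAsRows = TRUE` (default) or taxon labels otherwise.
#' BIOM: v1 (JSON) always; v2.1 (HDF5) when the installed biomformat build
#' can read it.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param rank taxonomic rank to declare on the result.
#' @param samplesAsRows TSV orientation flag.
#' @return an [OtuTable-class].
#' @export
readOtuTable <- function(path, format = c("tsv", "biom"),
                         rank = c("family", "genus", "otu"),
                         samplesAsRows = TRUE) {
  format <- match.arg(format)
  rank <- match.arg(rank)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed table: ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicated ids in first column: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    otuTable(m, rank = rank, taxaAreRows = !samplesAsRows)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations (taxa) x samples
    otuTable(m, rank = rank, taxaAreRows = TRUE)
  }
}

#' Write a count table to TSV or BIOM (v1 JSON)
#'
#' @param x an [OtuTable-class].
#' @param path output path.
#' @param format `"tsv"` or `"biom"`.
#' @param samplesAsRows TSV orientation.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path, format = c("tsv", "biom"), samplesAsRows = TRUE) {
  format <- match.arg(format)
  cts <- otuCounts(x)
  if (format == "tsv") {
    m <- if (samplesAsRows) t(cts) else cts
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- if (samplesAsRows) "sample_id" else "taxon"
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    biomformat::write_biom(biomformat::make_biom(data = cts), path)
  }
  invisible(path)
}

#' Read per-sample metadata from a TSV file
#'
#' Expects a header with a `sample_id` column; remaining columns are clinical
#' covariates (`disease`, `sex`, `smoking`, `age`, `bvas`, `balf_*_pct`).
#'
#' @param path file path.
#' @return a validated `data.frame` with sample ids as rownames.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  .validateSampleMetadata(df)
  df
}

#' Aggregate an OTU-rank table to family or genus rank
#'
#' Counts are summed within the rank-level label. OTUs whose lineage lacks a
#' name at the target rank are pooled into the reserved `"__unassigned__"`
#' label (kept by default so per-sample totals are conserved; `dropUnassigned`
#' removes them).
#'
#' @param x an [OtuTable-class] at `"otu"` rank.
#' @param taxonomy `data.frame` mapping OTU labels (rownames or an `otu`
#'   column) to rank-level names in columns named after the ranks.
#' @param rank target rank, `"family"` or `"genus"`.
#' @param dropUnassigned drop the unassigned pool instead of keeping it.
#' @return an [OtuTable-class] at the target rank.
#' @export
aggregateToRank <- function(x, taxonomy, rank = c("family", "genus"),
                            dropUnassigned = FALSE) {
  rank <- match.arg(rank)
  tx <- as.data.frame(taxonomy)
  if ("otu" %in% names(tx)) rownames(tx) <- tx$otu
  if (!rank %in% names(tx))
    stop("taxonomy has no '", rank, "' column")
  lab <- as.character(tx[taxonLabels(x), rank])
  lab[is.na(lab) | lab == ""] <- .UNASSIGNED
  agg <- rowsum(otuCounts(x), group = lab)
  if (dropUnassigned) agg <- agg[rownames(agg) != .UNASSIGNED, , drop = FALSE]
  otuTable(agg, rank = rank, taxaAreRows = TRUE,
           allowZeroSamples = dropUnassigned) |>
    .carrySampleData(x)
}

.carrySampleData <- function(new, old) {
  SummarizedExperiment::colData(new) <-
    SummarizedExperiment::colData(old)[colnames(new), , drop = FALSE]
  new
}

#' Restrict or exclude a taxa set
#'
#' Set-intersection semantics: listed taxa absent from the table are not an
#' error, but their count is reported via a message. Samples whose subset
#' total becomes zero are retained and flagged (see [flaggedSamples()]);
#' downstream statistics decide how to handle them.
#'
#' @param x an [OtuTable-class].
#' @param taxa a [TaxaSet-class] at the same rank.
#' @param mode `"restrict"` keeps only the listed taxa; `"exclude"` removes them.
#' @return an [OtuTable-class].
#' @export
subsetTaxa <- function(x, taxa, mode = c("restrict", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(is(taxa, "TaxaSet"))
  if (taxa@rank != taxRank(x))
    stop(sprintf("rank mismatch: table is %s, taxa set is %s", taxRank(x), taxa@rank))
  hit <- intersect(taxa@labels, taxonLabels(x))
  unmatched <- length(taxa@labels) - length(hit)
  if (unmatched > 0)
    message(unmatched, " taxa-set label(s) not present in the table")
  keep <- if (mode == "restrict") hit else setdiff(taxonLabels(x), hit)
  if (length(keep) == 0L) stop("subset leaves 0 taxa")
  cts <- otuCounts(x)[keep, , drop = FALSE]
  out <- otuTable(cts, rank = taxRank(x), taxaAreRows = TRUE, allowZeroSamples = TRUE)
  out <- .carrySampleData(out, x)
  fl <- colnames(cts)[colSums(cts) == 0]
  S4Vectors::metadata(out)$zero_total_samples <- fl
  if (length(fl))
    message("zero-total after subsetting (flagged): ", paste(fl, collapse = ", "))
  out
}
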