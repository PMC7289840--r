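#' Construct a PrevalenceTable
#'
#' @param data `data.frame` with columns `subsite`, `taxon`, `detected`,
#'   `total`.
#' @param rank taxonomic rank of the taxa.
#' @return a [PrevalenceTable-class].
#' @export
prevalenceTable <- function(data, rank = c("family", "genus", "otu")) {
  rank <- match.arg(rank)
  data <- as.data.frame(data)
  data$subsite <- as.character(data$subsite)
  data$taxon <- as.character(data$taxon)
  obj <- new("PrevalenceTable", data = data, rank = rank)
  validObject(obj)
  obj
}

#' @describeIn prevalenceTable subsites present in the table.
#' @export
setMethod("subsites", "PrevalenceTable", function(x) unique(x@data$subsite))

#' @describeIn prevalenceTable named vector of detection fractions
#'   (`detected / total`) for one subsite.
#' @export
setMethod("prevalenceOf", "PrevalenceTable", function(x, subsite) {
  if (!subsite %in% x@data$subsite) stop("unknown subsite: ", subsite)
  d <- x@data[x@data$subsite == subsite, ]
  stats::setNames(d$detected / d$total, d$taxon)
})

setMethod("show", "PrevalenceTable", function(object) {
  cat(sprintf("PrevalenceTable (%s rank): %d subsites, %d taxa, %d rows\n",
              object@rank, length(unique(object@data$subsite)),
              length(unique(object@data$taxon)), nrow(object@data)))
})

#' Read / write prevalence tables as TSV
#'
#' Columns: `subsite`, `taxon`, `detected`, `total`; `#` comment lines allowed.
#'
#' @param path file path.
#' @param rank taxonomic rank to declare.
#' @return a [PrevalenceTable-class] (read) or `path` invisibly (write).
#' @export
readPrevalenceTable <- function(path, rank = c("family", "genus", "otu")) {
  rank <- match.arg(rank)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  prevalenceTable(df, rank = rank)
}

#' @rdname readPrevalenceTable
#' @param x a [PrevalenceTable-class].
#' @export
writePrevalenceTable <- function(x, path) {
  utils::write.table(x@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a TaxaSet
#'
#' @param labels character vector of taxon labels (deduplicated, order kept).
#' @param rank taxonomic rank of the labels.
#' @param provenance free-text origin tag, e.g. `"inhabitant:hard_palate@0.98"`.
#' @return a [TaxaSet-class].
#' @export
taxaSet <- function(labels, rank = c("family", "genus", "otu"),
                    provenance = "manual") {
  rank <- match.arg(rank)
  obj <- new("TaxaSet", labels = unique(as.character(labels)), rank = rank,
             provenance = provenance)
  validObject(obj)
  obj
}

#' @describeIn taxaSet the labels.
#' @export
setMethod("setLabels", "TaxaSet", function(x) x@labels)

#' @describeIn taxaSet the provenance tag.
#' @export
setMethod("provenance", "TaxaSet", function(x) x@provenance)

setMethod("show", "TaxaSet", function(object) {
  cat(sprintf("TaxaSet: %d taxa (%s rank), provenance %s\n",
              length(object@labels), object@rank, object@provenance))
  if (length(object@labels))
    cat(" ", paste(utils::head(object@labels, 8), collapse = ", "),
        if (length(object@labels) > 8) "..." else "", "\n")
})

setMethod("length", "TaxaSet", function(x) length(x@labels))

#' Read / write taxa sets as one-label-per-line text
#'
#' The provenance and rank are carried in `#`-prefixed header comments.
#'
#' @param path file path.
#' @return a [TaxaSet-class] (read) or `path` invisibly (write).
#' @export
readTaxaSet <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  rank <- sub("^# rank: ", "", grep("^# rank: ", hdr, value = TRUE))
  prov <- sub("^# provenance: ", "", grep("^# provenance: ", hdr, value = TRUE))
  labels <- ln[!grepl("^#", ln) & nzchar(ln)]
  taxaSet(labels,
          rank = if (length(rank)) rank else "otu",
          provenance = if (length(prov)) prov else "manual")
}

#' @rdname readTaxaSet
#' @param x a [TaxaSet-class].
#' @export
writeTaxaSet <- function(x, path) {
  writeLines(c(sprintf("# rank: %s", x@rank),
               sprintf("# provenance: %s", x@provenance),
               x@labels), path)
  invisible(path)
}
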