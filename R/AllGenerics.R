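#' @rdname OtuTable-class
#' @param x an object.
#' @export
setGeneric("taxRank", function(x) standardGeneric("taxRank"))

#' @rdname OtuTable-class
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OtuTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OtuTable-class
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' @rdname OtuTable-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname OtuTable-class
#' @export
setGeneric("flaggedSamples", function(x) standardGeneric("flaggedSamples"))

#' @rdname TaxaSet-class
#' @param x an object.
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @rdname TaxaSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname DissimilarityMatrix-class
#' @param x an object.
#' @export
setGeneric("dissValues", function(x) standardGeneric("dissValues"))

#' @rdname DissimilarityMatrix-class
#' @export
setGeneric("dissMetric", function(x) standardGeneric("dissMetric"))

#' @rdname PrevalenceTable-class
#' @param x an object.
#' @export
setGeneric("subsites", function(x) standardGeneric("subsites"))

#' @rdname PrevalenceTable-class
#' @param subsite subsite name.
#' @export
setGeneric("prevalenceOf", function(x, subsite) standardGeneric("prevalenceOf"))
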