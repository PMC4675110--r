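#' @rdname DereplicatedSet-class
#' @param object,x an object
#' @export
setGeneric("repIds", function(x) standardGeneric("repIds"))

#' @rdname DereplicatedSet-class
#' @export
setGeneric("uniqueSequences", function(x) standardGeneric("uniqueSequences"))

#' @rdname DereplicatedSet-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname DereplicatedSet-class
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname DereplicatedSet-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname SparseDistanceMatrix-class
#' @export
setGeneric("distIds", function(x) standardGeneric("distIds"))

#' @rdname SparseDistanceMatrix-class
#' @export
setGeneric("distCutoff", function(x) standardGeneric("distCutoff"))

#' @rdname SparseDistanceMatrix-class
#' @export
setGeneric("distPairs", function(x) standardGeneric("distPairs"))

#' @rdname OTUPartition-class
#' @export
setGeneric("otus", function(x) standardGeneric("otus"))

#' @rdname OTUPartition-class
#' @export
setGeneric("partitionLabel", function(x) standardGeneric("partitionLabel"))

#' @rdname OTUPartition-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname OTUPartition-class
#' @export
setGeneric("nOtus", function(x) standardGeneric("nOtus"))

#' @rdname OTUPartition-class
#' @export
setGeneric("otuSizes", function(x) standardGeneric("otuSizes"))

#' @rdname ReferenceDB-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname ReferenceDB-class
#' @export
setGeneric("refTaxonomy", function(x) standardGeneric("refTaxonomy"))

#' @rdname ReferenceDB-class
#' @export
setGeneric("refRegion", function(x) standardGeneric("refRegion"))

#' @rdname PairConfusion-class
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' Matthews correlation coefficient of a pair-counting confusion matrix
#'
#' @param x a [PairConfusion] (or an [MCCResult], returned unchanged).
#' @return an [MCCResult].
#' @export
setGeneric("mcc", function(x) standardGeneric("mcc"))

#' @rdname MCCResult-class
#' @export
setGeneric("mccValue", function(x) standardGeneric("mccValue"))

#' @rdname MCCResult-class
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname MCCResult-class
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
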