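## Accessors, show methods and small constructors for the S4 containers.

#' @rdname DereplicatedSet-class
#' @export
setMethod("repIds", "DereplicatedSet", function(x) names(x@sequences))

#' @rdname DereplicatedSet-class
#' @export
setMethod("uniqueSequences", "DereplicatedSet", function(x) x@sequences)

#' @rdname DereplicatedSet-class
#' @export
setMethod("abundances", "DereplicatedSet",
  function(x) stats::setNames(x@abundance, names(x@sequences)))

#' @rdname DereplicatedSet-class
#' @export
setMethod("memberIds", "DereplicatedSet",
  function(x) stats::setNames(x@members, names(x@sequences)))

#' @rdname DereplicatedSet-class
#' @export
setMethod("totalReads", "DereplicatedSet", function(x) sum(x@abundance))

#' @rdname DereplicatedSet-class
#' @export
setMethod("length", "DereplicatedSet", function(x) length(x@sequences))

#' @rdname DereplicatedSet-class
#' @param i index (numeric, logical or character) of units to keep
#' @export
setMethod("[", "DereplicatedSet", function(x, i) {
  new("DereplicatedSet", sequences = x@sequences[i],
      abundance = x@abundance[if (is.character(i)) match(i, names(x@sequences)) else i],
      members = x@members[if (is.character(i)) match(i, names(x@sequences)) else i])
})

setMethod("show", "DereplicatedSet", function(object) {
  cat("DereplicatedSet with", length(object), "unique sequences representing",
      totalReads(object), "reads\n")
  if (length(object) > 0L) {
    w <- seq_len(min(3L, length(object)))
    cat(sprintf("  %s (n=%d, %d nt)\n", names(object@sequences)[w],
                object@abundance[w], nchar(as.character(object@sequences))[w]),
        sep = "")
    if (length(object) > 3L) cat("  ...\n")
  }
})

#' @rdname SparseDistanceMatrix-class
#' @export
setMethod("distIds", "SparseDistanceMatrix", function(x) x@ids)

#' @rdname SparseDistanceMatrix-class
#' @export
setMethod("distCutoff", "SparseDistanceMatrix", function(x) x@cutoff)

#' @rdname SparseDistanceMatrix-class
#' @export
setMethod("distPairs", "SparseDistanceMatrix", function(x) {
  data.frame(id1 = x@ids[x@idx1], id2 = x@ids[x@idx2], dist = x@dist,
             stringsAsFactors = FALSE)
})

setMethod("show", "SparseDistanceMatrix", function(object) {
  n <- length(object@ids)
  cat("SparseDistanceMatrix:", n, "sequences,", length(object@dist),
      "of", choose(n, 2), "pairs stored (cutoff", object@cutoff, ")\n")
})

#' Convert a sparse distance matrix to a dense symmetric matrix
#'
#' Unstored (above-cutoff) pairs are filled with \code{fill}.
#'
#' @param x a [SparseDistanceMatrix]
#' @param fill value for unstored pairs (default \code{NA})
#' @param ... ignored
#' @return a symmetric numeric matrix with zero diagonal
#' @export
setMethod("as.matrix", "SparseDistanceMatrix", function(x, fill = NA_real_, ...) {
  n <- length(x@ids)
  m <- matrix(fill, n, n, dimnames = list(x@ids, x@ids))
  diag(m) <- 0
  if (length(x@dist) > 0L) {
    m[cbind(x@idx1, x@idx2)] <- x@dist
    m[cbind(x@idx2, x@idx1)] <- x@dist
  }
  m
})

#' Look up pairwise distances in a sparse distance matrix
#'
#' @param dm a [SparseDistanceMatrix]
#' @param id1,id2 character vectors of ids (recycled to a common length)
#' @return numeric vector of distances; \code{NA} for pairs stored above the
#'   cutoff; 0 for self-pairs
#' @export
lookupDistance <- function(dm, id1, id2) {
  stopifnot(is(dm, "SparseDistanceMatrix"))
  i <- match(id1, dm@ids)
  j <- match(id2, dm@ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(id1[is.na(i)], id2[is.na(j)]))
    stop("ids not present in the distance matrix: ",
         paste(bad, collapse = ", "))
  }
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  stored <- stats::setNames(dm@dist, paste(dm@idx1, dm@idx2))
  out <- unname(stored[key])
  out[lo == hi] <- 0
  out
}

#' Construct an OTU partition
#'
#' @param otus list of character vectors of member ids (one per OTU); names
#'   are used as OTU labels, defaulting to \code{OTU_1 ...}
#' @param label partition-level tag (threshold or method name)
#' @param universe the full id set; defaults to the union of the OTUs
#' @return an [OTUPartition]
#' @export
OTUPartition <- function(otus, label = "", universe = NULL) {
  otus <- lapply(otus, as.character)
  if (length(otus) > 0L && is.null(names(otus)))
    names(otus) <- paste0("OTU_", seq_along(otus))
  if (is.null(universe)) universe <- unlist(otus, use.names = FALSE)
  new("OTUPartition", label = as.character(label), otus = otus,
      universe = as.character(universe))
}

#' @rdname OTUPartition-class
#' @export
setMethod("otus", "OTUPartition", function(x) x@otus)

#' @rdname OTUPartition-class
#' @export
setMethod("partitionLabel", "OTUPartition", function(x) x@label)

#' @rdname OTUPartition-class
#' @export
setMethod("nOtus", "OTUPartition", function(x) length(x@otus))

#' @rdname OTUPartition-class
#' @export
setMethod("otuSizes", "OTUPartition",
  function(x) stats::setNames(lengths(x@otus), names(x@otus)))

#' @rdname OTUPartition-class
#' @export
setMethod("membership", "OTUPartition", function(x) {
  stats::setNames(rep(names(x@otus), lengths(x@otus)),
                  unlist(x@otus, use.names = FALSE))
})

setMethod("show", "OTUPartition", function(object) {
  cat("OTUPartition '", object@label, "': ", length(object@otus), " OTUs over ",
      length(object@universe), " sequences\n", sep = "")
})

#' Construct a reference database
#'
#' @param sequences a named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences, optionally gapped
#' @param taxonomy named character vector of semicolon-delimited taxonomy
#'   strings covering every reference id
#' @param region optional 1-based inclusive alignment-column interval
#' @param metadata optional list of annotations
#' @return a [ReferenceDB]
#' @export
referenceDB <- function(sequences, taxonomy, region = NULL, metadata = list()) {
  if (!is(sequences, "DNAStringSet")) {
    ids <- names(sequences)
    sequences <- DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- ids
  }
  new("ReferenceDB", sequences = sequences,
      taxonomy = taxonomy,
      region = if (is.null(region)) integer(0) else as.integer(region),
      metadata = metadata)
}

#' @rdname ReferenceDB-class
#' @export
setMethod("refSequences", "ReferenceDB", function(x) x@sequences)

#' @rdname ReferenceDB-class
#' @export
setMethod("refTaxonomy", "ReferenceDB", function(x) x@taxonomy)

#' @rdname ReferenceDB-class
#' @export
setMethod("refRegion", "ReferenceDB",
  function(x) if (length(x@region)) x@region else NULL)

#' @rdname ReferenceDB-class
#' @export
setMethod("length", "ReferenceDB", function(x) length(x@sequences))

#' @rdname ReferenceDB-class
#' @param i index (numeric, logical or character); reorders as well as
#'   subsets, which is how reference-order randomization is expressed
#' @export
setMethod("[", "ReferenceDB", function(x, i) {
  new("ReferenceDB", sequences = x@sequences[i], taxonomy = x@taxonomy,
      region = x@region, metadata = x@metadata)
})

setMethod("show", "ReferenceDB", function(object) {
  cat("ReferenceDB with", length(object), "references")
  if (length(object@region))
    cat("; region columns", object@region[1L], "-", object@region[2L])
  cat("\n")
})

#' Construct a pair-counting confusion matrix
#'
#' @param tp,tn,fp,fn non-negative pair counts
#' @param mode \code{"quality"} or \code{"stability"}
#' @return a [PairConfusion]
#' @export
pairConfusion <- function(tp, tn, fp, fn, mode = "quality") {
  new("PairConfusion", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn), mode = mode)
}

#' @rdname PairConfusion-class
#' @export
setMethod("pairCounts", "PairConfusion",
  function(x) c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

setMethod("show", "PairConfusion", function(object) {
  cat("PairConfusion (", object@mode, "): TP=", object@tp, " TN=", object@tn,
      " FP=", object@fp, " FN=", object@fn, "\n", sep = "")
})

#' @rdname MCCResult-class
#' @export
setMethod("mccValue", "MCCResult", function(x) x@mcc)

#' @rdname MCCResult-class
#' @export
setMethod("sensitivity", "MCCResult", function(x) x@sensitivity)

#' @rdname MCCResult-class
#' @export
setMethod("specificity", "MCCResult", function(x) x@specificity)

#' @rdname PairConfusion-class
#' @export
setMethod("pairCounts", "MCCResult", function(x) pairCounts(x@counts))

setMethod("show", "MCCResult", function(object) {
  cat(sprintf("MCC = %.4f (sensitivity %.4f, specificity %.4f)\n",
              object@mcc, object@sensitivity, object@specificity))
})
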