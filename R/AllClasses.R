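#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
NULL

#' Dereplicated sequence set
#'
#' Unique sequences together with their read abundances and the identifiers
#' of the reads each unique sequence represents. All clustering and
#' pair-counting statistics in the package operate on this container.
#' Units are stored in decreasing order of abundance, ties broken by
#' representative id, so that greedy clustering has a reproducible default
#' scan order.
#'
#' @slot sequences [Biostrings::DNAStringSet] of unique sequences, named by
#'   representative read id. Sequences may carry alignment gaps (\code{-} or
#'   \code{.}); uniqueness is judged on the gap-free string.
#' @slot abundance integer vector, parallel to \code{sequences}; the number
#'   of reads each unique sequence represents.
#' @slot members list of character vectors, parallel to \code{sequences};
#'   the ids of the member reads (representative id included).
#'
#' @seealso [dereplicate()], [expandReads()]
#' @export
setClass("DereplicatedSet",
  representation(sequences = "DNAStringSet",
                 abundance = "integer",
                 members   = "list"))

setValidity("DereplicatedSet", function(object) {
  n <- length(object@sequences)
  msgs <- character()
  if (length(object@abundance) != n || length(object@members) != n)
    msgs <- c(msgs, "slots 'sequences', 'abundance' and 'members' must have equal length")
  ids <- names(object@sequences)
  if (n > 0L && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    msgs <- c(msgs, "sequence names must be non-empty and unique")
  if (length(msgs) == 0L && n > 0L) {
    if (any(object@abundance < 1L))
      msgs <- c(msgs, "abundances must be positive")
    if (!all(lengths(object@members) == object@abundance))
      msgs <- c(msgs, "abundance must equal the number of member ids")
    key <- gsub("[-.]", "", as.character(object@sequences))
    if (anyDuplicated(key))
      msgs <- c(msgs, "sequences must be pairwise distinct after gap removal")
  }
  if (length(msgs)) msgs else TRUE
})

#' Sparse pairwise distance matrix
#'
#' Pairwise distances between unique sequences, stored sparsely: only pairs
#' at or below \code{cutoff} are kept, and a lookup of an unstored pair is
#' reported as above-cutoff (\code{NA}). Distances are symmetric by
#' construction (each unordered pair is stored once, with \code{idx1 < idx2})
#' and self-pairs are never stored.
#'
#' @slot ids character vector of sequence ids, fixing the index order.
#' @slot idx1,idx2 integer indices into \code{ids} with \code{idx1 < idx2}.
#' @slot dist numeric distances in \code{[0, 1]}, all \code{<= cutoff}.
#' @slot cutoff the storage cutoff; pairs above it are omitted.
#'
#' @seealso [distanceMatrix()], [lookupDistance()]
#' @export
setClass("SparseDistanceMatrix",
  representation(ids = "character", idx1 = "integer", idx2 = "integer",
                 dist = "numeric", cutoff = "numeric"))

setValidity("SparseDistanceMatrix", function(object) {
  msgs <- character()
  k <- length(object@dist)
  if (length(object@idx1) != k || length(object@idx2) != k)
    msgs <- c(msgs, "'idx1', 'idx2' and 'dist' must have equal length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "ids must be unique")
  if (length(object@cutoff) != 1L || object@cutoff < 0)
    msgs <- c(msgs, "'cutoff' must be a single non-negative number")
  if (length(msgs) == 0L && k > 0L) {
    n <- length(object@ids)
    if (any(object@idx1 < 1L) || any(object@idx2 > n) ||
        any(object@idx1 >= object@idx2))
      msgs <- c(msgs, "pair indices must satisfy 1 <= idx1 < idx2 <= length(ids)")
    if (any(object@dist < 0) || any(object@dist > 1))
      msgs <- c(msgs, "distances must lie in [0, 1]")
    if (any(object@dist > object@cutoff))
      msgs <- c(msgs, "stored distances must not exceed the cutoff")
  }
  if (length(msgs)) msgs else TRUE
})

#' OTU partition
#'
#' A disjoint assignment of sequence ids to labeled OTUs, as produced by any
#' clustering or reference-assignment method at a given threshold.
#'
#' @slot label a tag for the partition (conventionally the distance
#'   threshold, e.g. \code{"0.03"}, or a method name).
#' @slot otus named list of character vectors; each element is one OTU's
#'   member ids.
#' @slot universe character vector of all ids; the OTUs partition it.
#'
#' @seealso [membership()], [clusterHierarchical()], [clusterGreedy()]
#' @export
setClass("OTUPartition",
  representation(label = "character", otus = "list", universe = "character"))

setValidity("OTUPartition", function(object) {
  msgs <- character()
  all_ids <- unlist(object@otus, use.names = FALSE)
  if (any(lengths(object@otus) == 0L))
    msgs <- c(msgs, "OTUs must be non-empty")
  if (anyDuplicated(all_ids))
    msgs <- c(msgs, "OTUs must be pairwise disjoint")
  if (!setequal(all_ids, object@universe) ||
      length(all_ids) != length(object@universe))
    msgs <- c(msgs, "union of OTUs must equal the universe")
  if (length(object@otus) > 0L && is.null(names(object@otus)))
    msgs <- c(msgs, "OTUs must be named")
  if (length(msgs)) msgs else TRUE
})

#' Reference database
#'
#' Reference sequences with their taxonomy strings and, optionally, the
#' alignment-column interval of an extracted subregion. Record order is kept
#' because it is an experimental variable: closed-reference assignment with
#' \code{tie_rule = "first_in_db_order"} depends on it.
#'
#' @slot sequences [Biostrings::DNAStringSet], named by reference id; may be
#'   gapped when the database is aligned.
#' @slot taxonomy named character vector mapping reference id to a
#'   semicolon-delimited taxonomy string.
#' @slot region integer of length 0 or 2; when present, the 1-based
#'   inclusive alignment-column interval the records were extracted from.
#' @slot metadata list of free-form annotations (e.g. ids excluded by
#'   [extractRegion()] for incomplete coverage).
#'
#' @seealso [referenceDB()], [extractRegion()], [auditReferenceDb()]
#' @export
setClass("ReferenceDB",
  representation(sequences = "DNAStringSet", taxonomy = "character",
                 region = "integer", metadata = "list"))

setValidity("ReferenceDB", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (length(object@sequences) > 0L &&
      (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    msgs <- c(msgs, "reference ids must be non-empty and unique")
  if (!all(ids %in% names(object@taxonomy)))
    msgs <- c(msgs, "every reference id must have a taxonomy entry")
  if (!length(object@region) %in% c(0L, 2L))
    msgs <- c(msgs, "'region' must have length 0 or 2")
  if (length(object@region) == 2L &&
      (object@region[1L] < 1L || object@region[2L] < object@region[1L]))
    msgs <- c(msgs, "'region' must be a valid 1-based inclusive interval")
  if (length(msgs)) msgs else TRUE
})

#' Pair-counting confusion matrix
#'
#' TP/TN/FP/FN counted over unordered sequence pairs, under either the
#' quality construction (OTU co-membership against the pairwise distances at
#' a threshold) or the stability construction (co-membership in a subsampled
#' partition against a full-data partition).
#'
#' @slot tp,tn,fp,fn non-negative pair counts (numeric, as counts can exceed
#'   the integer range for large datasets).
#' @slot mode \code{"quality"} or \code{"stability"}.
#'
#' @seealso [qualityConfusion()], [stabilityConfusion()], [mcc()]
#' @export
setClass("PairConfusion",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", mode = "character"))

setValidity("PairConfusion", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  msgs <- character()
  if (length(counts) != 4L || any(counts < 0) || any(counts != round(counts)))
    msgs <- c(msgs, "tp, tn, fp and fn must be single non-negative counts")
  if (!object@mode %in% c("quality", "stability"))
    msgs <- c(msgs, "mode must be 'quality' or 'stability'")
  if (length(msgs)) msgs else TRUE
})

#' Matthews correlation coefficient result
#'
#' MCC, sensitivity and specificity derived from a [PairConfusion] object.
#' All three statistics use the convention that a zero denominator yields 0.
#'
#' @slot mcc MCC in \code{[-1, 1]}.
#' @slot sensitivity TP / (TP + FN).
#' @slot specificity TN / (TN + FP).
#' @slot counts the [PairConfusion] the statistics were computed from.
#'
#' @seealso [mcc()]
#' @export
setClass("MCCResult",
  representation(mcc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", counts = "PairConfusion"))
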