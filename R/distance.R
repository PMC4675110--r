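## Pairwise distances: global alignment of unaligned pairs, column-wise
## distances from a shared multiple alignment, and sparse storage.

#' Alignment and distance-calculator parameters
#'
#' Scoring defaults follow mothur's pairwise defaults (match +1, mismatch
#' -1, gap open -2, gap extend -1; a gap of length k costs
#' \code{gap_open + (k - 1) * gap_extend}). The distance calculator defaults
#' to the "onegap" convention (a maximal run of gap columns counts as a
#' single difference and a single unit of compared length) with terminal gap
#' columns counted.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores; \code{match}
#'   must exceed \code{mismatch} and gap penalties must be non-positive
#' @param gap_mode \code{"one_gap_per_run"} or \code{"each_gap_column"}
#' @param count_end_gaps logical; if \code{FALSE}, leading/trailing columns
#'   containing a gap are excluded from the distance
#' @return a list of validated parameters
#' @export
alignmentParams <- function(match = 1, mismatch = -1, gap_open = -2,
                            gap_extend = -1,
                            gap_mode = c("one_gap_per_run", "each_gap_column"),
                            count_end_gaps = TRUE) {
  gap_mode <- match.arg(gap_mode)
  if (match <= mismatch) stop("'match' must exceed 'mismatch'")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, gap_mode = gap_mode,
       count_end_gaps = isTRUE(count_end_gaps))
}

#' Needleman-Wunsch global alignment of two sequences
#'
#' Affine-gap global alignment with a deterministic traceback (ties prefer
#' the diagonal move, then the vertical, then the horizontal), so results
#' are order- and platform-stable.
#'
#' @param a,b gap-free nucleotide strings
#' @param params an [alignmentParams()] list
#' @return a list with elements \code{a}, \code{b} (equal-length aligned
#'   strings) and \code{score}
#' @export
nwAlign <- function(a, b, params = alignmentParams()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (grepl("[-.]", a) || grepl("[-.]", b))
    stop("input sequences must be gap-free")
  cpp_nw_align(chartr("U", "T", a), chartr("U", "T", b), params$match,
               params$mismatch, params$gap_open, params$gap_extend)
}

#' Distance between two aligned sequences
#'
#' The distance is differences divided by compared length. Columns where
#' both sequences are gapped are skipped; with
#' \code{gap_mode = "one_gap_per_run"} a maximal run of gap columns counts
#' as one difference over one unit of length; with
#' \code{count_end_gaps = FALSE} leading/trailing gap columns are excluded.
#'
#' @param a,b equal-length aligned strings
#' @param params an [alignmentParams()] list (only the calculator fields are
#'   used)
#' @return a distance in \code{[0, 1]}
#' @export
pairDistance <- function(a, b, params = alignmentParams()) {
  a <- chartr("U", "T", toupper(as.character(a)))
  b <- chartr("U", "T", toupper(as.character(b)))
  if (nchar(a) != nchar(b)) stop("aligned sequences have unequal lengths")
  cpp_pair_dist(a, b, params$gap_mode == "one_gap_per_run",
                params$count_end_gaps)
}

#' Sparse pairwise distance matrix over a dereplicated set
#'
#' Evaluates all unordered pairs of unique sequences, either by pairwise
#' Needleman-Wunsch global alignment (\code{mode = "pairwise_nw"}) or
#' column-wise from the shared multiple alignment the sequences carry
#' (\code{mode = "from_alignment"}), and stores only pairs at or below
#' \code{cutoff}. Looking up an unstored pair reports it as above-cutoff.
#'
#' @param x a [DereplicatedSet], named [Biostrings::DNAStringSet] or named
#'   character vector
#' @param mode \code{"pairwise_nw"} (default) or \code{"from_alignment"}
#' @param params an [alignmentParams()] list
#' @param cutoff storage cutoff (default 0.10, comfortably above the 0.03
#'   working threshold plus hierarchical-merge headroom)
#' @return a [SparseDistanceMatrix]
#' @export
distanceMatrix <- function(x, mode = c("pairwise_nw", "from_alignment"),
                           params = alignmentParams(), cutoff = 0.10) {
  mode <- match.arg(mode)
  seqs <- if (is(x, "DereplicatedSet")) as.character(x@sequences)
          else as.character(x)
  ids <- if (is(x, "DereplicatedSet")) repIds(x) else names(x)
  if (length(seqs) > 0L && is.null(ids)) stop("sequences must be named")
  seqs <- chartr("U", "T", toupper(seqs))
  if (mode == "pairwise_nw") {
    seqs <- gsub("[-.]", "", seqs)
    if (any(!nzchar(seqs))) stop("empty sequence after gap removal")
  } else if (length(seqs) > 1L && length(unique(nchar(seqs))) != 1L) {
    stop("'from_alignment' mode requires uniformly aligned sequences")
  }
  sp <- cpp_sparse_dist(seqs, mode == "from_alignment", cutoff,
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend,
                        params$gap_mode == "one_gap_per_run",
                        params$count_end_gaps)
  new("SparseDistanceMatrix", ids = as.character(ids),
      idx1 = as.integer(sp$i), idx2 = as.integer(sp$j),
      dist = as.numeric(sp$d), cutoff = cutoff)
}

#' Write and read mothur column-format distances
#'
#' One line per stored pair: \code{idA idB distance}, one direction only.
#' Reading requires the id universe and cutoff, which the format does not
#' record.
#'
#' @param dm a [SparseDistanceMatrix]
#' @param path file path
#' @param ids the id universe (for \code{readColumnDist})
#' @param cutoff the storage cutoff the file was written with
#' @return \code{writeColumnDist} returns \code{path} invisibly;
#'   \code{readColumnDist} a [SparseDistanceMatrix]
#' @export
writeColumnDist <- function(dm, path) {
  stopifnot(is(dm, "SparseDistanceMatrix"))
  p <- distPairs(dm)
  writeLines(sprintf("%s %s %.10g", p$id1, p$id2, p$dist), path)
  invisible(path)
}

#' @rdname writeColumnDist
#' @export
readColumnDist <- function(path, ids, cutoff = 0.10) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(new("SparseDistanceMatrix", ids = as.character(ids),
               idx1 = integer(0), idx2 = integer(0), dist = numeric(0),
               cutoff = cutoff))
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) != 3L))
    stop("malformed column distance file: expected 'idA idB dist' per line")
  id1 <- vapply(parts, `[[`, character(1), 1L)
  id2 <- vapply(parts, `[[`, character(1), 2L)
  d <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  i <- match(id1, ids); j <- match(id2, ids)
  if (anyNA(i) || anyNA(j))
    stop("column distance file names ids outside the given universe")
  lo <- pmin(i, j); hi <- pmax(i, j)
  ord <- order(lo, hi)
  new("SparseDistanceMatrix", ids = as.character(ids),
      idx1 = as.integer(lo[ord]), idx2 = as.integer(hi[ord]),
      dist = d[ord], cutoff = cutoff)
}

#' Write and read PHYLIP square distance matrices
#'
#' Unstored (above-cutoff) pairs are written as \code{fill}; on reading,
#' values above \code{cutoff} are dropped back out of sparse storage.
#'
#' @param dm a [SparseDistanceMatrix]
#' @param path file path
#' @param fill value written for unstored pairs (default 1)
#' @param cutoff storage cutoff applied on reading
#' @return \code{writePhylipDist} returns \code{path} invisibly;
#'   \code{readPhylipDist} a [SparseDistanceMatrix]
#' @export
writePhylipDist <- function(dm, path, fill = 1) {
  stopifnot(is(dm, "SparseDistanceMatrix"))
  m <- as.matrix(dm, fill = fill)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(format(nrow(m)), con)
  for (k in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[k], sprintf("%.10g", m[k, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(path, cutoff = 0.10) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP distance file")
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "[\t ]+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if (ncol(m) != n) stop("malformed PHYLIP distance file: wrong row length")
  keep <- which(upper.tri(m) & m <= cutoff, arr.ind = TRUE)
  ord <- order(keep[, 1L], keep[, 2L])
  keep <- keep[ord, , drop = FALSE]
  new("SparseDistanceMatrix", ids = ids,
      idx1 = as.integer(keep[, 1L]), idx2 = as.integer(keep[, 2L]),
      dist = m[keep], cutoff = cutoff)
}
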