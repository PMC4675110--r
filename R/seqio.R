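## Sequence and table input/output, plus dereplication.
##
## All on-disk formats follow the dialects common in amplicon work: FASTA
## (unaligned or gapped-aligned), mothur-style names and list files, a
## two-column count table and a two-column taxonomy file. Everything is
## plain UTF-8 text and newline-tolerant.

VALID_CHARS <- c("A", "C", "G", "T", "U", "N", "-", ".")

.normalizeSeqs <- function(seqs, ids) {
  seqs <- toupper(seqs)
  bad <- grepl("[^-ACGTUN.]", seqs)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,U,N,-,.}: ",
         paste(ids[bad], collapse = ", "))
  chartr("U", "T", seqs)
}

#' Read a FASTA file
#'
#' Records are returned in file order as a named
#' [Biostrings::DNAStringSet]. The header token before the first whitespace
#' is the id; the remaining description is dropped. Sequences are
#' uppercase-normalized and \code{U} is mapped to \code{T}; characters
#' outside \code{{A,C,G,T,U,N,-,.}} are an error, as are duplicate ids and
#' empty files.
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::DNAStringSet]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) stop("could not parse FASTA file '",
                                           path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file contains a record with an empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalizeSeqs(as.character(set), ids)
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    ids <- names(seqs)
    seqs <- DNAStringSet(toupper(chartr("U", "T", as.character(seqs))))
    names(seqs) <- ids
  }
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Dereplicate sequences into unique units with abundances
#'
#' Collapses identical sequences (identity judged after removing gap
#' characters, so aligned input dereplicates on the underlying sequence
#' while the aligned string of the first occurrence is retained for distance
#' calculation). The representative id of each unit is the id of its first
#' occurrence in input order. Units are sorted by decreasing abundance with
#' ties broken by representative id.
#'
#' @param x a named [Biostrings::DNAStringSet] or named character vector of
#'   reads; names are read ids
#' @return a [DereplicatedSet]; empty input gives an empty set
#' @export
dereplicate <- function(x) {
  seqs <- as.character(x)
  ids <- names(x)
  if (length(seqs) > 0L && (is.null(ids) || anyDuplicated(ids)))
    stop("reads must carry unique ids")
  key <- gsub("[-.]", "", seqs)
  first <- !duplicated(key)
  rep_key <- key[first]
  rep_id <- ids[first]
  rep_seq <- seqs[first]
  members <- split(ids, factor(key, levels = rep_key))
  names(members) <- rep_id
  ab <- lengths(members)
  ord <- order(-ab, rep_id)
  out_seqs <- DNAStringSet(rep_seq[ord])
  names(out_seqs) <- rep_id[ord]
  new("DereplicatedSet", sequences = out_seqs,
      abundance = as.integer(ab[ord]),
      members = lapply(members[ord], as.character))
}

#' Expand a dereplicated set back to per-read sequences
#'
#' The inverse of [dereplicate()] up to read order: every member read id is
#' emitted with its unit's (possibly aligned) sequence.
#'
#' @param x a [DereplicatedSet]
#' @return a named character vector, names are read ids
#' @export
expandReads <- function(x) {
  stopifnot(is(x, "DereplicatedSet"))
  seqs <- as.character(x@sequences)
  stats::setNames(rep(seqs, x@abundance), unlist(x@members, use.names = FALSE))
}

#' Write and read mothur-style list files
#'
#' One line per partition: the label, the OTU count, then the OTUs as
#' tab-separated fields of comma-joined member ids. Reading the file back
#' reproduces each partition up to OTU ordering (OTU names are not part of
#' the format and are regenerated).
#'
#' @param partitions a list of [OTUPartition] objects (or a single one)
#' @param path file path
#' @return \code{writeListFile} returns \code{path} invisibly;
#'   \code{readListFile} returns a list of [OTUPartition] objects
#' @export
writeListFile <- function(partitions, path) {
  if (is(partitions, "OTUPartition")) partitions <- list(partitions)
  lines <- vapply(partitions, function(p) {
    paste(c(p@label, length(p@otus),
            vapply(p@otus, paste, character(1), collapse = ",")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeListFile
#' @export
readListFile <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("malformed list file line ", k, ": fewer than 2 fields")
    n <- suppressWarnings(as.integer(fields[2L]))
    if (is.na(n) || length(fields) != n + 2L)
      stop("malformed list file line ", k,
           ": OTU count does not match the number of OTU fields")
    otus <- strsplit(fields[-(1:2)], ",", fixed = TRUE)
    OTUPartition(otus, label = fields[1L])
  })
}

.readTwoColumn <- function(path, what) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) < 2L))
    stop("malformed ", what, " file: line without two columns")
  keys <- vapply(parts, `[[`, character(1), 1L)
  vals <- vapply(parts, function(p) paste(p[-1L], collapse = " "), character(1))
  if (anyDuplicated(keys))
    stop("repeated key(s) in ", what, " file: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  stats::setNames(vals, keys)
}

#' Read a taxonomy file
#'
#' Two whitespace/tab-delimited columns: reference id and a
#' semicolon-delimited taxonomy string.
#'
#' @param path file path
#' @return named character vector mapping id to taxonomy string
#' @export
readTaxonomy <- function(path) .readTwoColumn(path, "taxonomy")

#' Read a count table
#'
#' Two columns: sequence id and a positive integer abundance.
#'
#' @param path file path
#' @return named integer vector of abundances
#' @export
readCountTable <- function(path) {
  vals <- .readTwoColumn(path, "count")
  counts <- suppressWarnings(as.numeric(vals))
  if (anyNA(counts) || any(counts != round(counts)) || any(counts < 1))
    stop("count table values must be positive integers")
  stats::setNames(as.integer(counts), names(vals))
}

#' Write and read mothur-style names files
#'
#' Two tab-separated columns: representative id and the comma-joined ids of
#' the reads it represents.
#'
#' @param x a [DereplicatedSet]
#' @param path file path
#' @return \code{writeNamesFile} returns \code{path} invisibly;
#'   \code{readNamesFile} returns a named list of member-id vectors
#' @export
writeNamesFile <- function(x, path) {
  stopifnot(is(x, "DereplicatedSet"))
  lines <- paste(repIds(x),
                 vapply(x@members, paste, character(1), collapse = ","),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNamesFile
#' @export
readNamesFile <- function(path) {
  vals <- .readTwoColumn(path, "names")
  lapply(vals, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
}
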