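## Reference-based assignment with an exhaustive (non-heuristic) best-match
## search, the reference-order randomization experiment, region extraction
## and the reference-database audit.

.seqChars <- function(x) {
  if (is(x, "DereplicatedSet")) {
    stats::setNames(as.character(x@sequences), repIds(x))
  } else if (is(x, "ReferenceDB")) {
    stats::setNames(as.character(x@sequences), names(x@sequences))
  } else {
    stats::setNames(as.character(x), names(x))
  }
}

#' Exhaustive query-by-reference distance matrix
#'
#' Computes the distance from every query to every reference, either by
#' pairwise global alignment of the gap-free sequences or column-wise when
#' queries and references share an alignment (or are equal-length,
#' gap-free region sequences).
#'
#' @param queries a [DereplicatedSet], named [Biostrings::DNAStringSet] or
#'   named character vector
#' @param refs a [ReferenceDB] (or named sequences)
#' @param mode \code{"pairwise_nw"} or \code{"from_alignment"}
#' @param params an [alignmentParams()] list
#' @return a numeric matrix, rows = query ids, columns = reference ids
#' @export
crossDistance <- function(queries, refs,
                          mode = c("pairwise_nw", "from_alignment"),
                          params = alignmentParams()) {
  mode <- match.arg(mode)
  q <- chartr("U", "T", toupper(.seqChars(queries)))
  r <- chartr("U", "T", toupper(.seqChars(refs)))
  if (length(r) == 0L) stop("reference set is empty")
  if (mode == "pairwise_nw") {
    q <- gsub("[-.]", "", q)
    r <- gsub("[-.]", "", r)
  } else if (length(unique(nchar(c(q, r)))) != 1L) {
    stop("'from_alignment' mode requires queries and references on the ",
         "same alignment columns")
  }
  out <- cpp_cross_dist(unname(q), unname(r), mode == "from_alignment",
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend,
                        params$gap_mode == "one_gap_per_run",
                        params$count_end_gaps)
  dimnames(out) <- list(names(q), names(r))
  out
}

#' Closed-reference OTU assignment (exhaustive best match)
#'
#' Every query's distance to every reference is computed (no heuristic
#' candidate selection); a query is assigned to the minimum-distance
#' reference when that distance is at most \code{threshold}, otherwise it is
#' left unassigned. Exact distance ties are resolved by \code{tie_rule}:
#' the reference earliest in database order (the default, which models the
#' order sensitivity of label assignment) or the lexicographically smallest
#' reference id.
#'
#' @param queries query sequences (see [crossDistance()])
#' @param refs a [ReferenceDB]
#' @param threshold maximum assignment distance (default 0.03, inclusive)
#' @param tie_rule \code{"first_in_db_order"} or \code{"lexicographic_id"}
#' @param mode,params distance options, see [crossDistance()]
#' @param xdist optional precomputed [crossDistance()] matrix
#' @return a list with \code{assigned} (data.frame with columns
#'   \code{query}, \code{reference}, \code{distance}) and \code{unassigned}
#'   (character vector of query ids); the two partition the query universe
#' @export
closedReferenceAssign <- function(queries, refs, threshold = 0.03,
                                  tie_rule = c("first_in_db_order",
                                               "lexicographic_id"),
                                  mode = c("pairwise_nw", "from_alignment"),
                                  params = alignmentParams(), xdist = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (is.null(xdist)) xdist <- crossDistance(queries, refs, mode, params)
  ref_order <- names(refSequences(refs))
  xdist <- xdist[, ref_order, drop = FALSE]
  dmin <- apply(xdist, 1L, min)
  hit <- dmin <= threshold
  pick <- vapply(which(hit), function(i) {
    ties <- colnames(xdist)[xdist[i, ] == dmin[i]]
    if (tie_rule == "first_in_db_order") ties[1L] else sort(ties)[1L]
  }, character(1))
  list(assigned = data.frame(query = rownames(xdist)[hit],
                             reference = unname(pick),
                             distance = unname(dmin[hit]),
                             stringsAsFactors = FALSE),
       unassigned = rownames(xdist)[!hit])
}

#' Partition induced by a closed-reference assignment
#'
#' Groups assigned queries by their assigned reference; OTUs are labeled
#' \code{ref:<reference id>}. Unassigned queries are omitted unless
#' \code{keep_unassigned = TRUE}, in which case each becomes a singleton
#' labeled \code{unassigned:<query id>}.
#'
#' @param assignment the result of [closedReferenceAssign()]
#' @param keep_unassigned keep unassigned queries as singletons
#' @param label partition label
#' @return an [OTUPartition]
#' @export
assignmentPartition <- function(assignment, keep_unassigned = FALSE,
                                label = "closed_ref") {
  a <- assignment$assigned
  otus <- split(a$query, factor(a$reference, levels = unique(a$reference)))
  if (length(otus) > 0L) names(otus) <- paste0("ref:", names(otus))
  if (keep_unassigned && length(assignment$unassigned) > 0L) {
    extra <- as.list(assignment$unassigned)
    names(extra) <- paste0("unassigned:", assignment$unassigned)
    otus <- c(otus, extra)
  }
  OTUPartition(otus, label = label)
}

#' Open-reference OTU assignment
#'
#' Closed-reference assignment followed by de novo clustering of the
#' queries that matched no reference. Reference OTUs are labeled
#' \code{ref:<reference id>} and de novo OTUs \code{denovo:<otu>}.
#'
#' @inheritParams closedReferenceAssign
#' @param queries a [DereplicatedSet] (abundances are needed for the greedy
#'   de novo stage)
#' @param denovo_mode greedy mode for the unassigned remainder
#'   (\code{"dgc"}, the UPARSE-style default, or \code{"agc"})
#' @param seed seed for the de novo stage
#' @param cutoff storage cutoff for the de novo distance matrix
#' @return an [OTUPartition] over the full query universe
#' @export
openReferenceAssign <- function(queries, refs, threshold = 0.03,
                                denovo_mode = c("dgc", "agc"), seed = NULL,
                                mode = c("pairwise_nw", "from_alignment"),
                                params = alignmentParams(), cutoff = 0.10,
                                xdist = NULL) {
  denovo_mode <- match.arg(denovo_mode)
  mode <- match.arg(mode)
  stopifnot(is(queries, "DereplicatedSet"))
  closed <- closedReferenceAssign(queries, refs, threshold = threshold,
                                  mode = mode, params = params,
                                  xdist = xdist)
  a <- closed$assigned
  otus <- split(a$query, factor(a$reference, levels = unique(a$reference)))
  if (length(otus) > 0L) names(otus) <- paste0("ref:", names(otus))
  if (length(closed$unassigned) > 0L) {
    rest <- queries[closed$unassigned]
    dmr <- distanceMatrix(rest, mode = mode, params = params,
                          cutoff = cutoff)
    sorted <- rest[order(-abundances(rest))]
    dn <- clusterGreedy(sorted, dmr, mode = denovo_mode,
                        threshold = threshold, order = "given")
    dn_otus <- otus(dn)
    names(dn_otus) <- paste0("denovo:", names(dn_otus))
    otus <- c(otus, dn_otus)
  }
  OTUPartition(otus, label = "open_ref", universe = repIds(queries))
}

#' Reference-order randomization experiment
#'
#' Runs exhaustive closed-reference assignment against \code{nPerm} seeded
#' permutations of the reference order and reports, per permutation, the
#' number of mapped queries and the OTU labels, plus the pairwise fraction
#' of shared labels across permutations. Because the search is exhaustive,
#' the mapped count and the induced partition of queries (grouping by the
#' permutation-invariant set of tied best references) are identical across
#' permutations; only the labels can differ, and they do exactly when tied
#' best references exist (e.g. references duplicated over the region).
#'
#' @inheritParams closedReferenceAssign
#' @param nPerm number of reference-order permutations (default 30)
#' @param seed master seed for the permutations
#' @return a list with \code{mapped_counts} (per permutation),
#'   \code{partition} (the invariant [OTUPartition] of assigned queries,
#'   grouped by tied-best reference set), \code{labels} (matrix: invariant
#'   OTU groups x permutations, the assigned reference label),
#'   \code{sharing} (matrix of pairwise shared-label fractions) and
#'   \code{mean_sharing} (mean over distinct permutation pairs)
#' @export
randomizeReferenceExperiment <- function(queries, refs, threshold = 0.03,
                                         nPerm = 30, seed = 1,
                                         mode = c("pairwise_nw",
                                                  "from_alignment"),
                                         params = alignmentParams(),
                                         xdist = NULL) {
  if (nPerm < 1L) stop("nPerm must be at least 1")
  mode <- match.arg(mode)
  if (is.null(xdist)) xdist <- crossDistance(queries, refs, mode, params)
  ref_ids <- names(refSequences(refs))
  xdist <- xdist[, ref_ids, drop = FALSE]
  dmin <- apply(xdist, 1L, min)
  hit <- which(dmin <= threshold)
  tie_sets <- lapply(hit, function(i)
    sort(colnames(xdist)[xdist[i, ] == dmin[i]]))
  group_key <- vapply(tie_sets, paste, character(1), collapse = "\r")
  groups <- split(rownames(xdist)[hit], group_key)
  group_ties <- lapply(split(tie_sets, group_key), `[[`, 1L)
  partition <- OTUPartition(stats::setNames(groups,
                                            paste0("grp_", seq_along(groups))),
                            label = "closed_ref_invariant")
  perm_seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, nPerm))
  labels <- matrix(NA_character_, nrow = length(groups), ncol = nPerm,
                   dimnames = list(names(otus(partition)), NULL))
  mapped <- integer(nPerm)
  for (p in seq_len(nPerm)) {
    ord <- .withSeed(perm_seeds[p], sample(ref_ids))
    rank <- stats::setNames(seq_along(ord), ord)
    labels[, p] <- vapply(group_ties, function(ts)
      ts[which.min(rank[ts])], character(1))
    mapped[p] <- length(hit)  # exhaustive search: invariant by construction
  }
  sharing <- matrix(1, nPerm, nPerm)
  if (length(groups) > 0L && nPerm > 1L) {
    for (p in seq_len(nPerm - 1L)) {
      for (q in seq(p + 1L, nPerm)) {
        s <- mean(labels[, p] == labels[, q])
        sharing[p, q] <- s; sharing[q, p] <- s
      }
    }
  }
  mean_sharing <- if (nPerm > 1L) mean(sharing[upper.tri(sharing)]) else 1
  list(mapped_counts = mapped, partition = partition, labels = labels,
       sharing = sharing, mean_sharing = mean_sharing)
}

#' Extract an alignment-column region from a reference database
#'
#' Truncates every record to the 1-based inclusive column interval
#' \code{[start, end]}, keeping gap characters. Records that do not fully
#' cover the interval (a non-gap character strictly before \code{start} and
#' strictly after \code{end} is required) are excluded from the returned
#' database; their ids are recorded in
#' \code{metadata$incomplete_coverage_ids}.
#'
#' @param refs an aligned [ReferenceDB]
#' @param start,end 1-based inclusive alignment columns
#' @return a [ReferenceDB] restricted to the covering records, with
#'   \code{region} set
#' @export
extractRegion <- function(refs, start, end) {
  stopifnot(is(refs, "ReferenceDB"))
  seqs <- as.character(refs@sequences)
  L <- unique(nchar(seqs))
  if (length(L) > 1L) stop("reference records are not uniformly aligned")
  if (start < 1L || end > L || end < start)
    stop("region [", start, ", ", end, "] outside alignment columns 1-", L)
  before <- substr(seqs, 1L, start - 1L)
  after <- substr(seqs, end + 1L, L)
  covers <- grepl("[ACGTN]", before) & grepl("[ACGTN]", after)
  inside <- substr(seqs, start, end)
  covers <- covers & grepl("[ACGTN]", inside)
  kept <- names(refs@sequences)[covers]
  out_seqs <- DNAStringSet(inside[covers])
  names(out_seqs) <- kept
  new("ReferenceDB", sequences = out_seqs, taxonomy = refs@taxonomy,
      region = as.integer(c(start, end)),
      metadata = c(refs@metadata,
                   list(incomplete_coverage_ids =
                          names(refs@sequences)[!covers])))
}

.normTax <- function(x) gsub("\\s+", " ", trimws(x))

#' Audit a reference database for duplicated and near-duplicate sequences
#'
#' Reports, over the (optionally region-extracted) references: the unique
#' sequence count after dereplication, the number of unordered pairs more
#' similar than \code{similarity_threshold} (distance strictly below
#' \code{1 - similarity_threshold}; identical pairs qualify), the groups of
#' records with identical gap-free sequences, and how many of those groups
#' carry discordant taxonomy strings (string inequality after whitespace
#' normalization).
#'
#' @param refs a [ReferenceDB]
#' @param similarity_threshold similarity above which a pair counts as a
#'   near-duplicate (default 0.97)
#' @param mode,params distance options, see [distanceMatrix()]
#' @return a list: \code{n_records}, \code{n_unique},
#'   \code{n_near_duplicate_pairs}, \code{duplicate_groups} (data.frame
#'   with columns \code{representative}, \code{size}, \code{n_taxonomies},
#'   \code{discordant}), \code{n_duplicate_groups},
#'   \code{n_discordant_groups}
#' @export
auditReferenceDb <- function(refs, similarity_threshold = 0.97,
                             mode = c("from_alignment", "pairwise_nw"),
                             params = alignmentParams()) {
  stopifnot(is(refs, "ReferenceDB"))
  mode <- match.arg(mode)
  seqs <- .seqChars(refs)
  key <- gsub("[-.]", "", seqs)
  dist_cut <- 1 - similarity_threshold
  n <- length(seqs)
  if (mode == "from_alignment" && length(unique(nchar(seqs))) > 1L)
    mode <- "pairwise_nw"
  sp <- if (n > 1L)
    cpp_sparse_dist(unname(if (mode == "pairwise_nw") key else seqs),
                    mode == "from_alignment", dist_cut,
                    params$match, params$mismatch, params$gap_open,
                    params$gap_extend,
                    params$gap_mode == "one_gap_per_run",
                    params$count_end_gaps)
  else list(d = numeric(0))
  n_pairs <- sum(sp$d < dist_cut)
  grp <- split(names(seqs), factor(key, levels = unique(key)))
  dup <- grp[lengths(grp) >= 2L]
  tax <- .normTax(refs@taxonomy)
  dup_df <- data.frame(
    representative = vapply(dup, `[[`, character(1), 1L),
    size = lengths(dup),
    n_taxonomies = vapply(dup, function(ids)
      length(unique(tax[ids])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  dup_df$discordant <- dup_df$n_taxonomies > 1L
  list(n_records = n,
       n_unique = length(grp),
       n_near_duplicate_pairs = n_pairs,
       duplicate_groups = dup_df,
       n_duplicate_groups = nrow(dup_df),
       n_discordant_groups = sum(dup_df$discordant))
}

#' Census of multi-hit queries under exhaustive closed-reference assignment
#'
#' For every query assigned within \code{threshold}, examines the set of
#' references tied at the minimum distance and counts queries with a unique
#' best reference, queries tied among references identical over the
#' compared region, queries tied among non-identical references, and
#' tied-best sets whose references carry conflicting taxonomies.
#'
#' @inheritParams closedReferenceAssign
#' @return a list of counts: \code{unique_best}, \code{tied_identical},
#'   \code{tied_nonidentical}, \code{tied_conflicting_taxonomy},
#'   \code{total_assigned}
#' @export
multiHitCensus <- function(queries, refs, threshold = 0.03,
                           mode = c("pairwise_nw", "from_alignment"),
                           params = alignmentParams(), xdist = NULL) {
  mode <- match.arg(mode)
  if (is.null(xdist)) xdist <- crossDistance(queries, refs, mode, params)
  ref_seq_key <- gsub("[-.]", "", .seqChars(refs))
  tax <- .normTax(refs@taxonomy)
  dmin <- apply(xdist, 1L, min)
  hit <- which(dmin <= threshold)
  uniq <- tied_id <- tied_non <- conflict <- 0L
  for (i in hit) {
    ties <- colnames(xdist)[xdist[i, ] == dmin[i]]
    if (length(ties) == 1L) {
      uniq <- uniq + 1L
    } else {
      if (length(unique(ref_seq_key[ties])) == 1L) tied_id <- tied_id + 1L
      else tied_non <- tied_non + 1L
      if (length(unique(tax[ties])) > 1L) conflict <- conflict + 1L
    }
  }
  list(unique_best = uniq, tied_identical = tied_id,
       tied_nonidentical = tied_non, tied_conflicting_taxonomy = conflict,
       total_assigned = length(hit))
}
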