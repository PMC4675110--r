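## De novo OTU clustering: hierarchical linkage with a distance cutoff and
## greedy centroid clustering (abundance- and distance-based).

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  code
}

.makePartition <- function(members_idx, ids, label) {
  if (length(members_idx) == 0L)
    return(OTUPartition(list(), label = label, universe = character(0)))
  ord <- order(-lengths(members_idx),
               vapply(members_idx, min, numeric(1)))
  members_idx <- members_idx[ord]
  otus <- lapply(members_idx, function(ix) ids[sort(ix)])
  names(otus) <- sprintf("OTU_%0*d", nchar(length(otus)), seq_along(otus))
  OTUPartition(otus, label = label, universe = ids)
}

#' Hierarchical agglomerative OTU clustering at a distance threshold
#'
#' Repeatedly merges the pair of clusters with the smallest linkage distance
#' while that minimum does not exceed \code{threshold}. Linkage is the
#' minimum pairwise distance for single linkage (\code{"sl"}, mothur's
#' nearest neighbor), the arithmetic mean over all inter-cluster pairs for
#' average linkage (\code{"al"}, average neighbor) and the maximum for
#' complete linkage (\code{"cl"}, furthest neighbor). Pairs absent from the
#' sparse matrix are above the storage cutoff: they make a merge impossible
#' under CL, contribute \code{distCutoff(dm)} to the AL mean by default
#' (\code{al_missing = "cutoff"}; set \code{"unmergeable"} for the stricter
#' behavior) and are irrelevant to SL. Exact ties between candidate merges
#' are broken by the seeded random number generator.
#'
#' @param dm a [SparseDistanceMatrix]
#' @param method \code{"sl"}, \code{"al"} or \code{"cl"}
#' @param threshold merge threshold (inclusive); must not exceed
#'   \code{distCutoff(dm)}
#' @param seed integer seed for tie-breaking (tie-free instances give the
#'   same partition under every seed)
#' @param al_missing how AL treats unstored pairs
#' @return an [OTUPartition] labeled with the threshold
#' @export
clusterHierarchical <- function(dm, method = c("sl", "al", "cl"), threshold,
                                seed = NULL,
                                al_missing = c("cutoff", "unmergeable")) {
  method <- match.arg(method)
  al_missing <- match.arg(al_missing)
  stopifnot(is(dm, "SparseDistanceMatrix"))
  if (threshold > dm@cutoff)
    stop("threshold (", threshold, ") exceeds the storage cutoff (",
         dm@cutoff, "); distances needed for linkage may be missing")
  ids <- dm@ids
  n <- length(ids)
  label <- format(threshold)
  if (n == 0L) return(OTUPartition(list(), label = label))
  fill <- if (method == "al" && al_missing == "cutoff") dm@cutoff else Inf
  D <- matrix(fill, n, n)
  if (length(dm@dist) > 0L) {
    D[cbind(dm@idx1, dm@idx2)] <- dm@dist
    D[cbind(dm@idx2, dm@idx1)] <- dm@dist
  }
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1, n)
  members <- as.list(seq_len(n))
  .withSeed(seed, {
    repeat {
      idx <- which(active)
      if (length(idx) < 2L) break
      sub <- D[idx, idx, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- Inf
      mn <- min(sub)
      if (!is.finite(mn) || mn > threshold) break
      cand <- which(sub == mn, arr.ind = TRUE)
      pick <- if (nrow(cand) > 1L) cand[sample.int(nrow(cand), 1L), ]
              else cand[1L, ]
      i <- idx[pick[1L]]; j <- idx[pick[2L]]
      others <- setdiff(idx, c(i, j))
      if (length(others) > 0L) {
        upd <- switch(method,
          sl = pmin(D[i, others], D[j, others]),
          cl = pmax(D[i, others], D[j, others]),
          al = (size[i] * D[i, others] + size[j] * D[j, others]) /
               (size[i] + size[j]))
        D[i, others] <- upd
        D[others, i] <- upd
      }
      size[i] <- size[i] + size[j]
      members[[i]] <- c(members[[i]], members[[j]])
      active[j] <- FALSE
    }
  })
  .makePartition(members[active], ids, label)
}

#' Greedy centroid OTU clustering (AGC/DGC)
#'
#' Scans the sequences in order (by default decreasing abundance, ties by
#' id). A sequence within \code{threshold} of no existing centroid founds a
#' new centroid; otherwise distance-based greedy clustering (\code{"dgc"})
#' joins the closest qualifying centroid (ties: larger abundance, then id
#' order) and abundance-based greedy clustering (\code{"agc"}) joins the
#' most abundant qualifying centroid (ties: smaller distance, then id
#' order). Centroid sequences and abundances are fixed at creation.
#'
#' @param units a [DereplicatedSet]
#' @param dm a [SparseDistanceMatrix] over the unit ids; pairs above its
#'   cutoff are treated as definitely more distant than \code{threshold}
#' @param mode \code{"agc"} or \code{"dgc"}
#' @param threshold joining threshold (inclusive); must not exceed
#'   \code{distCutoff(dm)}
#' @param order \code{"abundance"} (decreasing abundance, ties by id) or
#'   \code{"given"} (the stored unit order, for input-order-sensitivity
#'   experiments)
#' @return an [OTUPartition]; OTUs are named by their centroid id
#' @export
clusterGreedy <- function(units, dm, mode = c("agc", "dgc"), threshold,
                          order = c("abundance", "given")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(is(units, "DereplicatedSet"), is(dm, "SparseDistanceMatrix"))
  if (threshold > dm@cutoff)
    stop("threshold exceeds the storage cutoff of the distance matrix")
  ids <- repIds(units)
  if (!all(ids %in% dm@ids))
    stop("distance matrix does not cover all unit ids")
  n <- length(ids)
  label <- format(threshold)
  if (n == 0L) return(OTUPartition(list(), label = label))
  ab <- abundances(units)
  scan <- if (order == "abundance") ids[order(-ab, ids)] else ids
  # adjacency restricted to pairs at or below the joining threshold
  keep <- dm@dist <= threshold
  e1 <- dm@ids[dm@idx1[keep]]; e2 <- dm@ids[dm@idx2[keep]]
  ed <- dm@dist[keep]
  nbr <- split(c(e2, e1), factor(c(e1, e2), levels = ids))
  nbd <- split(c(ed, ed), factor(c(e1, e2), levels = ids))
  is_centroid <- stats::setNames(logical(n), ids)
  assigned_to <- stats::setNames(character(n), ids)
  for (u in scan) {
    cand <- nbr[[u]]
    keepc <- is_centroid[cand]
    cand <- cand[keepc]
    if (length(cand) == 0L) {
      is_centroid[u] <- TRUE
      assigned_to[u] <- u
      next
    }
    d <- nbd[[u]][keepc]
    pick <- if (mode == "dgc") order(d, -ab[cand], cand)[1L]
            else order(-ab[cand], d, cand)[1L]
    assigned_to[u] <- cand[pick]
  }
  otus <- split(ids, factor(assigned_to[ids], levels = unique(assigned_to[scan])))
  OTUPartition(otus, label = label, universe = ids)
}

#' Randomly permute the order of a dereplicated set
#'
#' Seeded Fisher-Yates shuffle of the unit order; the units themselves are
#' unchanged. Used with \code{order = "given"} in [clusterGreedy()] and for
#' the full-dataset order randomizations of the stability experiment.
#'
#' @param units a [DereplicatedSet]
#' @param seed integer seed
#' @return a [DereplicatedSet] with the same units in a new order
#' @export
permuteInput <- function(units, seed) {
  stopifnot(is(units, "DereplicatedSet"))
  perm <- .withSeed(seed, sample.int(length(units)))
  units[perm]
}
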