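# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: confusion matrices by a naive double loop over
# pairs, single-linkage by graph components, distances by direct column
# counting.

# Naive pair-by-pair quality confusion from a dense distance matrix
# (NA = above threshold).
brute_quality <- function(partition, D, threshold) {
  ids <- partition@universe
  memb <- membership(partition)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(ids)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- ids[i]; b <- ids[j]
      d <- D[a, b]
      close <- !is.na(d) && d <= threshold
      same <- memb[[a]] == memb[[b]]
      if (same && close) tp <- tp + 1
      else if (!same && !close) tn <- tn + 1
      else if (same && !close) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

brute_stability <- function(sub, full) {
  ids <- sub@universe
  ms <- membership(sub); mf <- membership(full)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(ids)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- ids[i]; b <- ids[j]
      ss <- ms[[a]] == ms[[b]]; sf <- mf[[a]] == mf[[b]]
      if (ss && sf) tp <- tp + 1
      else if (!ss && !sf) tn <- tn + 1
      else if (ss && !sf) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Random sparse distance matrix: n ids, a fraction of pairs get distances
# below the cutoff, the rest are unstored.
random_sparse_dm <- function(n, cutoff = 0.10, p_close = 0.25) {
  ids <- sprintf("s%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_close
  pairs <- pairs[keep, , drop = FALSE]
  d <- stats::runif(nrow(pairs), 0, cutoff)  # continuous: ties ~ never
  new("SparseDistanceMatrix", ids = ids,
      idx1 = as.integer(pairs[, 1]), idx2 = as.integer(pairs[, 2]),
      dist = d, cutoff = cutoff)
}

# Single linkage at a threshold == connected components of the graph whose
# edges are the pairs at or below the threshold.
sl_components_oracle <- function(dm, threshold) {
  ids <- distIds(dm)
  p <- distPairs(dm)
  p <- p[p$dist <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(p[, c("id1", "id2")], directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)$membership
  unname(split(ids, comp[ids]))
}

# Compare two partitions as sets of sets.
same_partition <- function(a, b) {
  if (is(a, "OTUPartition")) a <- otus(a)
  if (is(b, "OTUPartition")) b <- otus(b)
  key <- function(x) sort(unname(vapply(x, function(o)
    paste(sort(o), collapse = ","), character(1))))
  identical(key(a), key(b))
}

# Random partition of ids into at most k groups.
random_partition <- function(ids, k, label = "rand") {
  g <- sample.int(k, length(ids), replace = TRUE)
  OTUPartition(split(ids, g), label = label)
}

make_units <- function(seqs) dereplicate(seqs)

# DereplicatedSet with given ids and abundances (random sequences; member
# read ids synthesised to match the abundances).
fake_units <- function(ids, ab, L = 20) {
  seqs <- stats::setNames(vapply(seq_along(ids), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), ids)
  new("DereplicatedSet",
      sequences = Biostrings::DNAStringSet(seqs),
      abundance = as.integer(ab),
      members = stats::setNames(lapply(seq_along(ids), function(i)
        c(ids[i], sprintf("%s_dup%03d", ids[i],
                          seq_len(ab[i] - 1L)))[seq_len(ab[i])]), ids))
}
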