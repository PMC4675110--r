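## Pair-counting confusion matrices, MCC, threshold scanning, rarefaction
## and the subsampling experiment drivers.

.checkUniverse <- function(universe, ids, what) {
  missing <- setdiff(universe, ids)
  if (length(missing) > 0L)
    stop("id(s) in the partition missing from the ", what, ": ",
         paste(utils::head(missing, 5L), collapse = ", "))
}

#' Quality confusion matrix: OTU co-membership against pairwise distances
#'
#' Counts, over all unordered pairs of sequences in the partition universe:
#' pairs in the same OTU at distance \code{<= threshold} (TP), in different
#' OTUs at distance \code{> threshold} (TN), in the same OTU at distance
#' \code{> threshold} (FP) and in different OTUs at distance
#' \code{<= threshold} (FN). Pairs not stored in the sparse matrix are above
#' its cutoff and therefore count on the \code{> threshold} side. A distance
#' exactly equal to the threshold counts as "should co-cluster" (the TP
#' side); set \code{inclusive = FALSE} for the strict reading.
#'
#' @param partition an [OTUPartition]
#' @param dm a [SparseDistanceMatrix] covering the partition universe
#' @param threshold distance threshold; must not exceed \code{distCutoff(dm)}
#' @param inclusive whether a pair at exactly the threshold belongs on the
#'   TP side (default \code{TRUE})
#' @return a [PairConfusion] with \code{mode = "quality"}
#' @export
qualityConfusion <- function(partition, dm, threshold, inclusive = TRUE) {
  stopifnot(is(partition, "OTUPartition"), is(dm, "SparseDistanceMatrix"))
  if (threshold > dm@cutoff)
    stop("threshold exceeds the storage cutoff of the distance matrix")
  universe <- partition@universe
  .checkUniverse(universe, dm@ids, "distance matrix")
  m <- length(universe)
  total <- choose(m, 2)
  memb <- membership(partition)
  close <- if (inclusive) dm@dist <= threshold else dm@dist < threshold
  in_univ <- dm@ids[dm@idx1] %in% universe & dm@ids[dm@idx2] %in% universe
  keep <- close & in_univ
  id1 <- dm@ids[dm@idx1[keep]]
  id2 <- dm@ids[dm@idx2[keep]]
  n_close <- sum(keep)
  tp <- sum(memb[id1] == memb[id2])
  same_total <- sum(choose(lengths(partition@otus), 2))
  fp <- same_total - tp
  fn <- n_close - tp
  tn <- total - tp - fp - fn
  pairConfusion(tp, tn, fp, fn, mode = "quality")
}

#' Stability confusion matrix: subsampled against full-data OTUs
#'
#' Counts, over all unordered pairs of ids in the subsampled partition's
#' universe: pairs in the same OTU in both partitions (TP), in different
#' OTUs in both (TN), together in the subsample but apart in the full data
#' (FP) and apart in the subsample but together in the full data (FN).
#' Computed from the cluster contingency table, which is exactly the
#' pair-by-pair count.
#'
#' @param sub the partition of the subsampled data
#' @param full the partition of the full data; its universe must contain
#'   the subsample's
#' @return a [PairConfusion] with \code{mode = "stability"}
#' @export
stabilityConfusion <- function(sub, full) {
  stopifnot(is(sub, "OTUPartition"), is(full, "OTUPartition"))
  universe <- sub@universe
  missing <- setdiff(universe, full@universe)
  if (length(missing) > 0L)
    stop("subsample id(s) absent from the full partition: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  m <- length(universe)
  total <- choose(m, 2)
  msub <- membership(sub)[universe]
  mfull <- membership(full)[universe]
  nij <- table(msub, mfull)
  tp <- sum(choose(nij, 2))
  same_sub <- sum(choose(rowSums(nij), 2))
  same_full <- sum(choose(colSums(nij), 2))
  fp <- same_sub - tp
  fn <- same_full - tp
  tn <- total - tp - fp - fn
  pairConfusion(tp, tn, fp, fn, mode = "stability")
}

#' @rdname mcc
#' @export
setMethod("mcc", "PairConfusion", function(x) {
  tp <- x@tp; tn <- x@tn; fp <- x@fp; fn <- x@fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  m <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  new("MCCResult", mcc = m, sensitivity = sens, specificity = spec,
      counts = x)
})

#' @rdname mcc
#' @export
setMethod("mcc", "MCCResult", function(x) x)

#' Scan quality MCC over a threshold grid
#'
#' Evaluates the quality MCC of a fixed partition at each threshold and
#' returns the grid together with the MCC-maximising threshold (ties broken
#' toward the smallest threshold). The default grid covers 0 to 5% in 1%
#' increments.
#'
#' @param partition an [OTUPartition]
#' @param dm a [SparseDistanceMatrix]
#' @param thresholds numeric grid; all values must be within
#'   \code{distCutoff(dm)}
#' @return a list with \code{best_threshold} and a data.frame \code{scan}
#'   with columns \code{threshold} and \code{mcc}
#' @export
thresholdScan <- function(partition, dm, thresholds = seq(0, 0.05, by = 0.01)) {
  if (length(thresholds) == 0L) stop("threshold grid is empty")
  if (max(thresholds) > distCutoff(dm))
    stop("threshold grid exceeds the storage cutoff of the distance matrix")
  mccs <- vapply(thresholds, function(t)
    mccValue(mcc(qualityConfusion(partition, dm, t))), numeric(1))
  best <- thresholds[which.max(mccs)]  # which.max takes the first maximum
  list(best_threshold = best,
       scan = data.frame(threshold = thresholds, mcc = mccs))
}

#' Expected OTU count under rarefaction
#'
#' The expected number of OTUs observed in a random subsample of \code{n}
#' reads drawn without replacement. The analytic mode evaluates the
#' hypergeometric expectation
#' \eqn{E[S] = \sum_i 1 - \binom{N - N_i}{n} / \binom{N}{n}} over the OTU
#' read counts \eqn{N_i}; the Monte-Carlo mode averages observed OTU counts
#' over seeded draws.
#'
#' @param partition an [OTUPartition] over unique-sequence ids
#' @param abundances named read counts per unique sequence; summed per OTU
#' @param n subsample size, \code{1 <= n <= sum(abundances)}
#' @param mode \code{"analytic"} or \code{"montecarlo"}
#' @param reps Monte-Carlo replicates
#' @param seed Monte-Carlo seed
#' @return the expected OTU count (a single number)
#' @export
rarefyOtuCount <- function(partition, abundances, n,
                           mode = c("analytic", "montecarlo"), reps = 1000,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(partition, "OTUPartition"))
  .checkUniverse(partition@universe, names(abundances), "abundance map")
  sizes <- vapply(partition@otus, function(ix) sum(abundances[ix]), numeric(1))
  N <- sum(sizes)
  if (n > N) stop("subsample size n exceeds the total read count")
  if (n <= 0) stop("subsample size n must be positive")
  if (mode == "analytic") {
    sum(1 - exp(lchoose(N - sizes, n) - lchoose(N, n)))
  } else {
    labels <- rep(seq_along(sizes), sizes)
    .withSeed(seed, {
      mean(vapply(seq_len(reps), function(r) {
        length(unique(labels[sample.int(N, n)]))
      }, numeric(1)))
    })
  }
}

## Map subsample representative ids onto the full dataset's representative
## ids by matching the gap-free sequence strings, so that partitions of a
## subsample and of the full data talk about the same pair universe.
.relabelToFull <- function(subUnits, fullUnits) {
  full_key <- gsub("[-.]", "", as.character(fullUnits@sequences))
  sub_key <- gsub("[-.]", "", as.character(subUnits@sequences))
  hit <- match(sub_key, full_key)
  if (anyNA(hit))
    stop("subsample contains sequences absent from the full dataset")
  seqs <- subUnits@sequences
  names(seqs) <- repIds(fullUnits)[hit]
  new("DereplicatedSet", sequences = seqs, abundance = subUnits@abundance,
      members = stats::setNames(subUnits@members, names(seqs)))
}

## Draw a read-level subsample (without replacement) and re-dereplicate,
## relabelling the unique sequences with the full dataset's ids.
.subsampleUnits <- function(units, n, seed) {
  reads <- expandReads(units)
  take <- .withSeed(seed, sample.int(length(reads), n))
  .relabelToFull(dereplicate(reads[take]), units)
}

#' Build a clustering function for the experiment drivers
#'
#' Returns a function \code{f(units, seed = NULL, dm = NULL)} producing an
#' [OTUPartition] with the requested method at the working threshold,
#' computing a sparse distance matrix internally when one is not supplied.
#' Greedy methods scan in decreasing-abundance order with ties left in the
#' current unit order (a stable sort), so permuting the input with
#' [permuteInput()] exercises their order sensitivity; hierarchical methods
#' receive \code{seed} for linkage tie-breaking.
#'
#' @param method one of \code{"sl"}, \code{"al"}, \code{"cl"}, \code{"agc"},
#'   \code{"dgc"}
#' @param threshold clustering threshold (default 0.03)
#' @param cutoff storage cutoff for internally computed distance matrices
#' @param mode distance mode, see [distanceMatrix()]
#' @param params an [alignmentParams()] list
#' @return a clustering function
#' @export
makeClusterFun <- function(method = c("sl", "al", "cl", "agc", "dgc"),
                           threshold = 0.03, cutoff = 0.10,
                           mode = c("pairwise_nw", "from_alignment"),
                           params = alignmentParams()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  force(threshold); force(cutoff); force(params)
  function(units, seed = NULL, dm = NULL) {
    if (is.null(dm))
      dm <- distanceMatrix(units, mode = mode, params = params,
                           cutoff = cutoff)
    if (method %in% c("sl", "al", "cl")) {
      clusterHierarchical(dm, method = method, threshold = threshold,
                          seed = seed)
    } else {
      sorted <- units[order(-abundances(units))]  # stable: ties keep order
      clusterGreedy(sorted, dm, mode = method, threshold = threshold,
                    order = "given")
    }
  }
}

#' Stability experiment: subsampled against permuted full-data clusterings
#'
#' For each fraction, draws \code{nSubsampleReps} read-level subsamples
#' without replacement, re-dereplicates and clusters each, and scores it
#' (stability confusion + MCC) against each of \code{nFullPerms} clusterings
#' of order-permuted full data. The defaults (30 subsample replicates
#' against 30 full-data order permutations) give 900 comparisons per
#' fraction.
#'
#' @param units the full [DereplicatedSet]
#' @param clusterFun a function \code{f(units, seed, dm = NULL)} returning an
#'   [OTUPartition]; see [makeClusterFun()]
#' @param fractions subsample fractions in \code{(0, 1]}
#' @param nSubsampleReps subsample replicates per fraction
#' @param nFullPerms full-data order permutations
#' @param seed master seed; every random draw is derived from it
#' @return a data.frame with one row per (fraction, subsample, permutation)
#'   comparison: columns \code{fraction}, \code{subsample}, \code{full_perm},
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn}, \code{mcc}
#' @export
runStabilityExperiment <- function(units, clusterFun,
                                   fractions = c(0.2, 0.4, 0.6, 0.8),
                                   nSubsampleReps = 30, nFullPerms = 30,
                                   seed = 1) {
  stopifnot(is(units, "DereplicatedSet"))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  N <- totalReads(units)
  seeds <- .withSeed(seed,
    sample.int(.Machine$integer.max - 1L,
               2L * nFullPerms + length(fractions) * nSubsampleReps))
  perm_seeds <- seeds[seq_len(nFullPerms)]
  tie_seeds <- seeds[nFullPerms + seq_len(nFullPerms)]
  sub_seeds <- matrix(seeds[2L * nFullPerms +
                            seq_len(length(fractions) * nSubsampleReps)],
                      nrow = length(fractions))
  fulls <- lapply(seq_len(nFullPerms), function(p)
    clusterFun(permuteInput(units, perm_seeds[p]), seed = tie_seeds[p]))
  rows <- vector("list", length(fractions) * nSubsampleReps)
  k <- 0L
  for (fi in seq_along(fractions)) {
    n <- max(1L, round(fractions[fi] * N))
    for (r in seq_len(nSubsampleReps)) {
      s <- sub_seeds[fi, r]
      subUnits <- .subsampleUnits(units, n, s)
      subPart <- clusterFun(subUnits, seed = s)
      res <- lapply(seq_len(nFullPerms), function(p) {
        cc <- stabilityConfusion(subPart, fulls[[p]])
        c(pairCounts(cc), mcc = mccValue(mcc(cc)))
      })
      res <- do.call(rbind, res)
      k <- k + 1L
      rows[[k]] <- data.frame(fraction = fractions[fi], subsample = r,
                              full_perm = seq_len(nFullPerms),
                              tp = res[, "tp"], tn = res[, "tn"],
                              fp = res[, "fp"], fn = res[, "fn"],
                              mcc = res[, "mcc"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quality experiment: subsampled clusterings against their own distances
#'
#' For each fraction and replicate, draws a read-level subsample without
#' replacement, re-dereplicates and clusters it, and evaluates the quality
#' MCC against the subsample's own distance matrix at the working threshold.
#'
#' @inheritParams runStabilityExperiment
#' @param reps replicates per fraction
#' @param threshold evaluation threshold (default 0.03)
#' @param cutoff storage cutoff for the subsample distance matrices
#' @param mode distance mode, see [distanceMatrix()]
#' @param params an [alignmentParams()] list
#' @return a list with \code{values} (one row per fraction x replicate:
#'   \code{fraction}, \code{rep}, \code{mcc}, \code{n_otus}) and
#'   \code{summary} (per fraction: mean MCC and empirical 2.5/97.5
#'   percentiles)
#' @export
runQualityExperiment <- function(units, clusterFun,
                                 fractions = c(0.2, 0.4, 0.6, 0.8),
                                 reps = 30, threshold = 0.03, cutoff = 0.10,
                                 mode = c("pairwise_nw", "from_alignment"),
                                 params = alignmentParams(), seed = 1) {
  stopifnot(is(units, "DereplicatedSet"))
  mode <- match.arg(mode)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  N <- totalReads(units)
  seeds <- .withSeed(seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(fractions) * reps),
           nrow = length(fractions)))
  rows <- vector("list", length(fractions) * reps)
  k <- 0L
  for (fi in seq_along(fractions)) {
    n <- max(1L, round(fractions[fi] * N))
    for (r in seq_len(reps)) {
      s <- seeds[fi, r]
      subUnits <- if (fractions[fi] == 1) units
                  else .subsampleUnits(units, n, s)
      dm <- distanceMatrix(subUnits, mode = mode, params = params,
                           cutoff = cutoff)
      part <- clusterFun(subUnits, seed = s, dm = dm)
      q <- mccValue(mcc(qualityConfusion(part, dm, threshold)))
      k <- k + 1L
      rows[[k]] <- data.frame(fraction = fractions[fi], rep = r, mcc = q,
                              n_otus = nOtus(part))
    }
  }
  values <- do.call(rbind, rows)
  rownames(values) <- NULL
  agg <- split(values$mcc, values$fraction)
  summary <- data.frame(
    fraction = as.numeric(names(agg)),
    mean_mcc = vapply(agg, mean, numeric(1)),
    lower = vapply(agg, function(v) unname(stats::quantile(v, 0.025)),
                   numeric(1)),
    upper = vapply(agg, function(v) unname(stats::quantile(v, 0.975)),
                   numeric(1)))
  rownames(summary) <- NULL
  list(values = values, summary = summary)
}
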