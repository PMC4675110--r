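dense3e <- function(ab, ac, bc) {
  D <- matrix(NA_real_, 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
  diag(D) <- 0
  D["A","B"] <- D["B","A"] <- ab
  D["A","C"] <- D["C","A"] <- ac
  D["B","C"] <- D["C","B"] <- bc
  D
}

sparse_from_dense <- function(D, cutoff = 0.10) {
  keep <- which(upper.tri(D) & !is.na(D) & D <= cutoff, arr.ind = TRUE)
  new("SparseDistanceMatrix", ids = rownames(D),
      idx1 = as.integer(keep[, 1]), idx2 = as.integer(keep[, 2]),
      dist = D[keep], cutoff = cutoff)
}

test_that("MCC follows the pair-counting formula with the zero-denominator convention", {
  expect_equal(mccValue(mcc(pairConfusion(10, 10, 0, 0))), 1)
  expect_equal(mccValue(mcc(pairConfusion(0, 0, 5, 5))), -1)
  expect_equal(mccValue(mcc(pairConfusion(6, 2, 1, 1))), 11 / 21)
  # all four single-margin-zero cases return 0
  expect_equal(mccValue(mcc(pairConfusion(0, 2, 0, 1))), 0)
  expect_equal(mccValue(mcc(pairConfusion(1, 0, 2, 0))), 0)
  expect_equal(mccValue(mcc(pairConfusion(0, 0, 0, 0))), 0)
  expect_equal(mccValue(mcc(pairConfusion(0, 5, 0, 0))), 0)
  r <- mcc(pairConfusion(6, 2, 1, 1))
  expect_equal(sensitivity(r), 6 / 7)
  expect_equal(specificity(r), 2 / 3)
  expect_equal(sensitivity(mcc(pairConfusion(0, 1, 1, 0))), 0)
  expect_equal(specificity(mcc(pairConfusion(1, 0, 0, 1))), 0)
})

test_that("quality confusion reproduces the hand-enumerated 3-sequence cases", {
  D <- dense3e(0.02, 0.05, 0.05)
  dm <- sparse_from_dense(D)
  p1 <- OTUPartition(list(c("A", "B"), "C"))
  c1 <- qualityConfusion(p1, dm, 0.03)
  expect_equal(pairCounts(c1), c(tp = 1, tn = 2, fp = 0, fn = 0))
  expect_equal(mccValue(mcc(c1)), 1)

  p2 <- OTUPartition(list("A", "B", "C"))
  c2 <- qualityConfusion(p2, dm, 0.03)
  expect_equal(pairCounts(c2), c(tp = 0, tn = 2, fp = 0, fn = 1))
  expect_equal(mccValue(mcc(c2)), 0)

  p3 <- OTUPartition(list(c("A", "B", "C")))
  c3 <- qualityConfusion(p3, dm, 0.03)
  expect_equal(pairCounts(c3), c(tp = 1, tn = 0, fp = 2, fn = 0))
  expect_equal(mccValue(mcc(c3)), 0)

  expect_error(qualityConfusion(OTUPartition(list(c("A", "Z"))), dm, 0.03),
               "Z")
})

test_that("stability confusion reproduces the hand-enumerated sub-vs-full cases", {
  full1 <- OTUPartition(list(c("A", "B", "C", "D")))
  sub1 <- OTUPartition(list(c("A", "B"), "C"))
  s1 <- stabilityConfusion(sub1, full1)
  expect_equal(pairCounts(s1), c(tp = 1, tn = 0, fp = 0, fn = 2))

  sub2 <- OTUPartition(list("A", "B"))
  full2 <- OTUPartition(list(c("A", "B")))
  s2 <- stabilityConfusion(sub2, full2)
  expect_equal(pairCounts(s2), c(tp = 0, tn = 0, fp = 0, fn = 1))
  expect_equal(mccValue(mcc(s2)), 0)

  # self-agreement
  s3 <- stabilityConfusion(sub1, OTUPartition(list(c("A", "B"), "C",
                                                   "D", "E")))
  expect_equal(pairCounts(s3)[["fp"]], 0)
  expect_equal(pairCounts(s3)[["fn"]], 0)
  expect_equal(mccValue(mcc(s3)), 1)

  expect_error(stabilityConfusion(OTUPartition(list("Q")), full1), "Q")
})

test_that("pair counts conserve C(m,2) and match the brute-force oracle", {
  set.seed(2024)
  for (k in 1:40) {
    n <- sample(5:40, 1)
    dm <- random_sparse_dm(n, p_close = stats::runif(1, 0.1, 0.6))
    ids <- distIds(dm)
    t <- stats::runif(1, 0.01, 0.09)
    part <- random_partition(ids, sample(2:8, 1))
    cc <- qualityConfusion(part, dm, t)
    counts <- pairCounts(cc)
    expect_equal(sum(counts), choose(n, 2))
    D <- as.matrix(dm)  # NA fill = above cutoff
    expect_equal(counts, brute_quality(part, D, t))

    sub_ids <- sample(ids, max(3, floor(n / 2)))
    sub <- random_partition(sub_ids, sample(2:6, 1))
    full <- random_partition(ids, sample(2:6, 1))
    sc <- stabilityConfusion(sub, full)
    expect_equal(sum(pairCounts(sc)), choose(length(sub_ids), 2))
    expect_equal(pairCounts(sc), brute_stability(sub, full))
  }
})

test_that("quality MCC is invariant under OTU relabeling and member reordering", {
  set.seed(10)
  dm <- random_sparse_dm(20, p_close = 0.4)
  ids <- distIds(dm)
  part <- random_partition(ids, 5)
  shuffled <- OTUPartition(
    stats::setNames(lapply(rev(otus(part)), sample),
                    paste0("renamed_", seq_len(nOtus(part)))))
  q1 <- mccValue(mcc(qualityConfusion(part, dm, 0.05)))
  q2 <- mccValue(mcc(qualityConfusion(shuffled, dm, 0.05)))
  expect_equal(q1, q2)
})

test_that("stability MCC is symmetric when the universes coincide", {
  set.seed(12)
  ids <- sprintf("u%02d", 1:25)
  a <- random_partition(ids, 4)
  b <- random_partition(ids, 6)
  m1 <- mcc(stabilityConfusion(a, b))
  m2 <- mcc(stabilityConfusion(b, a))
  expect_equal(mccValue(m1), mccValue(m2))
  ca <- pairCounts(m1); cb <- pairCounts(m2)
  expect_equal(ca[["tp"]], cb[["tp"]])
  expect_equal(ca[["fp"]], cb[["fn"]])
})

test_that("quality MCC is 1 exactly when the partition matches a transitive threshold graph", {
  skip_if_not_installed("igraph")
  set.seed(33)
  checked_pos <- 0; checked_neg <- 0
  for (k in 1:60) {
    n <- sample(5:14, 1)
    dm <- random_sparse_dm(n, p_close = stats::runif(1, 0.1, 0.7))
    t <- stats::runif(1, 0.01, 0.09)
    comps <- sl_components_oracle(dm, t)
    # transitivity of the threshold graph: every intra-component pair close
    p <- distPairs(dm); close <- p[p$dist <= t, ]
    memb <- stats::setNames(rep(seq_along(comps), lengths(comps)),
                            unlist(comps))
    n_close_needed <- sum(choose(lengths(comps), 2))
    transitive <- nrow(close) == n_close_needed
    part <- OTUPartition(comps)
    val <- mccValue(mcc(qualityConfusion(part, dm, t)))
    # MCC = 1 is only achievable when both close and distant pairs exist;
    # otherwise a zero margin forces the 0 convention
    if (nrow(close) == 0 || n_close_needed == choose(n, 2)) next
    if (transitive) {
      expect_equal(val, 1)
      checked_pos <- checked_pos + 1
    } else {
      expect_lt(val, 1)
      checked_neg <- checked_neg + 1
    }
  }
  expect_gt(checked_pos, 0)
  expect_gt(checked_neg, 0)
})

test_that("threshold scan picks the MCC-maximising threshold, smallest on ties", {
  D <- dense3e(0.02, 0.05, 0.05)
  dm <- sparse_from_dense(D)
  p <- OTUPartition(list(c("A", "B"), "C"))
  res <- thresholdScan(p, dm)
  expect_equal(res$scan$threshold, seq(0, 0.05, 0.01))
  expect_equal(res$best_threshold, 0.02)  # 0.02..0.03 tie at MCC 1
  expect_equal(res$scan$mcc[res$scan$threshold == 0.03], 1)

  # single-element grid
  expect_equal(thresholdScan(p, dm, 0.04)$best_threshold, 0.04)
  # all-singleton partition on all-distant data: constant curve, smallest
  far <- sparse_from_dense(dense3e(NA, NA, NA))
  singletons <- OTUPartition(list("A", "B", "C"))
  res2 <- thresholdScan(singletons, far)
  expect_equal(length(unique(res2$scan$mcc)), 1L)
  expect_equal(res2$best_threshold, 0)
  expect_error(thresholdScan(p, dm, numeric(0)), "empty")
})

test_that("analytic rarefaction matches the hypergeometric hand calculation and Monte Carlo", {
  p <- OTUPartition(list(c("u1"), c("u2")))
  ab <- c(u1 = 2, u2 = 1)
  expect_equal(rarefyOtuCount(p, ab, 2), 5 / 3)
  expect_equal(rarefyOtuCount(p, ab, 3), 2)     # n = N: observed count
  expect_equal(rarefyOtuCount(p, ab, 1), 1)
  expect_error(rarefyOtuCount(p, ab, 4), "exceeds")
  expect_error(rarefyOtuCount(p, ab, 0), "positive")

  set.seed(60)
  for (k in 1:5) {
    n_otu <- sample(3:8, 1)
    ids <- sprintf("v%02d", seq_len(n_otu))
    part <- OTUPartition(as.list(ids))
    ab <- stats::setNames(sample.int(30, n_otu, replace = TRUE), ids)
    n <- sample.int(sum(ab), 1)
    ana <- rarefyOtuCount(part, ab, n)
    reps <- 3000
    mcarlo <- rarefyOtuCount(part, ab, n, mode = "montecarlo", reps = reps,
                             seed = k)
    # binomial-type bound on the SE of a mean of counts in [1, n_otu]
    se <- n_otu / (2 * sqrt(reps))
    expect_lt(abs(ana - mcarlo), 3 * se + 1e-9)
  }
})

test_that("planted partitions maximise quality MCC over random degradations", {
  set.seed(90)
  sim <- generateCommunity(communitySpec(n_clusters = 6, n_reads = 300,
                                         error_rate = 0, seed = 17))
  dm <- distanceMatrix(sim$units, mode = "from_alignment")
  truth <- sim$truth$partition
  base <- mccValue(mcc(qualityConfusion(truth, dm, 0.03)))
  expect_equal(base, 1)
  ids <- truth@universe
  for (k in 1:100) {
    memb <- membership(truth)[ids]
    if (k %% 2 == 0) {
      # random merge of two OTUs
      pick <- sample(unique(memb), 2)
      memb[memb == pick[2]] <- pick[1]
    } else {
      # random split of one OTU
      pick <- sample(unique(memb), 1)
      inside <- names(memb)[memb == pick]
      if (length(inside) < 2) next
      moved <- sample(inside, ceiling(length(inside) / 2))
      memb[moved] <- "split_off"
    }
    degraded <- OTUPartition(split(names(memb), memb))
    expect_lte(mccValue(mcc(qualityConfusion(degraded, dm, 0.03))), base)
  }
  # and the scan recovers the generating threshold on the planted partition
  expect_equal(thresholdScan(truth, dm)$best_threshold, 0.03)
})

test_that("experiment drivers have the prescribed shape and are deterministic", {
  sim <- generateCommunity(communitySpec(n_clusters = 5, n_reads = 250,
                                         seed = 23))
  cf <- makeClusterFun("dgc", mode = "from_alignment")
  st <- runStabilityExperiment(sim$units, cf, fractions = c(0.4, 0.8),
                               nSubsampleReps = 4, nFullPerms = 5, seed = 2)
  expect_equal(nrow(st), 2 * 4 * 5)
  expect_equal(unname(table(st$fraction)), c(20L, 20L), ignore_attr = TRUE)
  st2 <- runStabilityExperiment(sim$units, cf, fractions = c(0.4, 0.8),
                                nSubsampleReps = 4, nFullPerms = 5, seed = 2)
  expect_identical(st, st2)
  expect_error(runStabilityExperiment(sim$units, cf, fractions = 1.2),
               "fractions")

  qu <- runQualityExperiment(sim$units, cf, fractions = c(0.5, 1),
                             reps = 3, seed = 7)
  expect_equal(nrow(qu$values), 6L)
  expect_equal(nrow(qu$summary), 2L)
  qu2 <- runQualityExperiment(sim$units, cf, fractions = c(0.5, 1),
                              reps = 3, seed = 7)
  expect_identical(qu, qu2)
  # reps = 1: interval collapses to the point value
  q1 <- runQualityExperiment(sim$units, cf, fractions = 0.5, reps = 1,
                             seed = 3)
  expect_equal(q1$summary$lower, q1$summary$mean_mcc)
  expect_equal(q1$summary$upper, q1$summary$mean_mcc)
})

test_that("planted well-separated communities are perfectly stable at every fraction", {
  sim <- generateCommunity(communitySpec(n_clusters = 5, n_reads = 300,
                                         error_rate = 0, seed = 31))
  for (m in c("al", "dgc")) {
    cf <- makeClusterFun(m, mode = "from_alignment")
    st <- runStabilityExperiment(sim$units, cf, fractions = c(0.3, 0.7),
                                 nSubsampleReps = 3, nFullPerms = 3, seed = 5)
    expect_true(all(st$mcc == 1), info = m)
  }
})
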