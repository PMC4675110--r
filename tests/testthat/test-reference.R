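make_ref <- function(seqs, tax = NULL, region = NULL) {
  if (is.null(tax))
    tax <- stats::setNames(paste0("k__B;g__G", seq_along(seqs)), names(seqs))
  referenceDB(seqs, tax, region = region)
}

test_that("closed-reference assignment picks the exhaustive best match", {
  refs <- make_ref(c(R1 = "AAAAAAAAAAAAAAAAAAAA", R2 = "CCCCCCCCCCCCCCCCCCCC"))
  q <- c(q1 = "AAAAAAAAAAAAAAAAAAAA",   # identical to R1
         q2 = "GGGGGGGGGGGGGGGGGGGG")   # far from both
  res <- closedReferenceAssign(q, refs, threshold = 0.03,
                               mode = "from_alignment")
  expect_equal(res$assigned$query, "q1")
  expect_equal(res$assigned$reference, "R1")
  expect_equal(res$assigned$distance, 0)
  expect_equal(res$unassigned, "q2")
  expect_error(closedReferenceAssign(q, make_ref(stats::setNames(
    character(0), character(0)))), "empty")
})

test_that("assigned distances are the true minimum over all references", {
  set.seed(31)
  L <- 60
  rs <- vapply(1:12, function(i) paste(sample(c("A","C","G","T"), L,
                                              replace = TRUE), collapse = ""),
               character(1))
  names(rs) <- sprintf("R%02d", 1:12)
  refs <- make_ref(rs)
  # queries: perturbed copies of some references
  qs <- vapply(rs[1:6], function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(L, 1)
    ch[pos] <- sample(setdiff(c("A","C","G","T"), ch[pos]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(qs) <- sprintf("q%02d", 1:6)
  res <- closedReferenceAssign(qs, refs, threshold = 0.05,
                               mode = "from_alignment")
  xd <- crossDistance(qs, refs, mode = "from_alignment")
  for (k in seq_len(nrow(res$assigned))) {
    row <- res$assigned[k, ]
    expect_equal(row$distance, min(xd[row$query, ]))
    expect_lte(row$distance, 0.05)
  }
  expect_setequal(c(res$assigned$query, res$unassigned), names(qs))
})

test_that("duplicate references shift labels with db order but never the induced partition", {
  refs_fwd <- make_ref(c(A1 = "AAAATTTTCCCCGGGGAAAA", A2 = "AAAATTTTCCCCGGGGAAAA",
                         B1 = "CCCCGGGGTTTTAAAACCCC"))
  refs_rev <- refs_fwd[c("A2", "A1", "B1")]
  q <- c(q1 = "AAAATTTTCCCCGGGGAAAA", q2 = "CCCCGGGGTTTTAAAACCCC")
  r_fwd <- closedReferenceAssign(q, refs_fwd, mode = "from_alignment")
  r_rev <- closedReferenceAssign(q, refs_rev, mode = "from_alignment")
  expect_equal(r_fwd$assigned[r_fwd$assigned$query == "q1", "reference"], "A1")
  expect_equal(r_rev$assigned[r_rev$assigned$query == "q1", "reference"], "A2")
  # induced partitions identical
  expect_true(same_partition(assignmentPartition(r_fwd),
                             assignmentPartition(r_rev)))
  # lexicographic tie rule is order-invariant
  r_lex <- closedReferenceAssign(q, refs_rev, tie_rule = "lexicographic_id",
                                 mode = "from_alignment")
  expect_equal(r_lex$assigned[r_lex$assigned$query == "q1", "reference"], "A1")
})

test_that("open-reference assignment unions reference and de novo OTUs", {
  set.seed(55)
  sim <- generateCommunity(communitySpec(n_clusters = 4, n_reads = 120,
                                         n_variants = 2, error_rate = 0,
                                         seed = 9))
  units <- sim$units
  # references cover two planted clusters exactly
  tmpl <- sim$truth$variant_seqs[!duplicated(sim$truth$variant_cluster)]
  refs <- make_ref(stats::setNames(tmpl[1:2], c("refA", "refB")))
  p <- openReferenceAssign(units, refs, threshold = 0.03,
                           mode = "from_alignment")
  expect_setequal(p@universe, repIds(units))
  labs <- names(otus(p))
  expect_true(any(grepl("^ref:", labs)))
  expect_equal(sum(grepl("^denovo:", labs)), 2L)  # two unmatched clusters

  # all queries match: identical to closed reference
  refs_all <- make_ref(stats::setNames(tmpl, paste0("ref", 1:4)))
  p_all <- openReferenceAssign(units, refs_all, threshold = 0.03,
                               mode = "from_alignment")
  closed <- assignmentPartition(closedReferenceAssign(
    units, refs_all, threshold = 0.03, mode = "from_alignment"))
  expect_true(same_partition(p_all, closed))

  # none match: identical to pure de novo
  far <- make_ref(c(Z = paste(rep("A", nchar(tmpl[1])), collapse = "")))
  p_none <- openReferenceAssign(units, far, threshold = 0.03,
                                mode = "from_alignment", seed = 1)
  dmu <- distanceMatrix(units, mode = "from_alignment")
  sorted <- units[order(-abundances(units))]
  denovo <- clusterGreedy(sorted, dmu, mode = "dgc", threshold = 0.03,
                          order = "given")
  expect_true(same_partition(p_none, denovo))
})

test_that("reference-order randomization: invariant mapped counts, label sharing below 1 only with duplicates", {
  gen <- generateReferenceDb(18, duplicate_groups = list(c(3, 2), c(2, 1)),
                             seed = 71)
  reg <- extractRegion(gen$db, refRegion(gen$db)[1], refRegion(gen$db)[2])
  q <- gen$truth$region_seqs
  res <- randomizeReferenceExperiment(q, reg, threshold = 0.03, nPerm = 12,
                                      seed = 4, mode = "from_alignment")
  expect_length(unique(res$mapped_counts), 1L)
  expect_lt(res$mean_sharing, 1)
  expect_gt(res$mean_sharing, 0)

  gen0 <- generateReferenceDb(15, seed = 72)
  reg0 <- extractRegion(gen0$db, refRegion(gen0$db)[1], refRegion(gen0$db)[2])
  res0 <- randomizeReferenceExperiment(gen0$truth$region_seqs, reg0,
                                       threshold = 0.03, nPerm = 12,
                                       seed = 4, mode = "from_alignment")
  expect_equal(res0$mean_sharing, 1)
  # single permutation trivially agrees with itself
  res1 <- randomizeReferenceExperiment(gen0$truth$region_seqs, reg0,
                                       nPerm = 1, seed = 4,
                                       mode = "from_alignment")
  expect_equal(res1$mean_sharing, 1)
})

test_that("region extraction keeps covering records and counts the rest", {
  aln <- c(r1 = "AAAACCCCGGGG",
           r2 = "AAAACCCCGGGG",
           r3 = "----CCCC----",   # no flanking bases: incomplete
           r4 = "AAAA----GGGG",   # all-gap inside the region: incomplete
           r5 = "AA--CCCCGG--")
  refs <- make_ref(aln)
  out <- extractRegion(refs, 5, 8)
  expect_setequal(names(refSequences(out)), c("r1", "r2", "r5"))
  expect_equal(unname(as.character(refSequences(out))["r1" == names(refSequences(out))]), "CCCC")
  expect_setequal(out@metadata$incomplete_coverage_ids, c("r3", "r4"))
  expect_equal(refRegion(out), c(5L, 8L))
  expect_error(extractRegion(refs, 0, 8), "outside")
  expect_error(extractRegion(refs, 5, 99), "outside")
})

test_that("database audit counts duplicate groups, taxonomies and near-duplicate pairs", {
  # all mutually distant: nothing to report
  set.seed(81)
  far <- vapply(1:6, function(i) paste(sample(c("A","C","G","T"), 100,
                                              replace = TRUE), collapse = ""),
                character(1))
  names(far) <- sprintf("F%d", 1:6)
  a0 <- auditReferenceDb(make_ref(far))
  expect_equal(a0$n_near_duplicate_pairs, 0L)
  expect_equal(a0$n_duplicate_groups, 0L)

  # two identical sequences with different taxonomies
  dup <- c(D1 = far[[1]], D2 = far[[1]])
  a1 <- auditReferenceDb(make_ref(dup,
    tax = c(D1 = "k__B;g__X", D2 = "k__B;g__Y")))
  expect_equal(a1$n_duplicate_groups, 1L)
  expect_equal(a1$n_discordant_groups, 1L)
  expect_equal(a1$duplicate_groups$size, 2L)
  expect_equal(a1$n_unique, 1L)

  # one 4-member duplicate group (2 taxonomies) + three near-duplicate
  # non-identical pairs: qualifying pairs = 3 + choose(4, 2)
  base <- far[[1]]
  mutate1 <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- setdiff(c("A","C","G","T"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  near <- c(N1 = far[[2]], N2 = mutate1(far[[2]], 1), N3 = mutate1(far[[2]], 2))
  seqs <- c(G1 = base, G2 = base, G3 = base, G4 = base, near)
  tax <- stats::setNames(c("t1", "t1", "t2", "t1", "t3", "t4", "t5"),
                         names(seqs))
  a2 <- auditReferenceDb(make_ref(seqs, tax = tax))
  expect_equal(a2$n_duplicate_groups, 1L)
  expect_equal(a2$duplicate_groups$size, 4L)
  expect_equal(a2$duplicate_groups$n_taxonomies, 2L)
  expect_true(a2$duplicate_groups$discordant)
  expect_equal(a2$n_near_duplicate_pairs, 3L + choose(4, 2))
  expect_equal(a2$n_unique, 4L)  # base + N1 + N2 + N3
})

test_that("multi-hit census classifies tie sets by identity and taxonomy", {
  seqs <- c(U1 = "AAAACCCCGGGGTTTTAAAA",            # unique best for q1
            I1 = "CCCCGGGGAAAATTTTCCCC",            # identical pair
            I2 = "CCCCGGGGAAAATTTTCCCC")
  tax <- c(U1 = "t1", I1 = "tA", I2 = "tA")
  refs <- make_ref(seqs, tax = tax)
  q <- c(q1 = "AAAACCCCGGGGTTTTAAAA", q2 = "CCCCGGGGAAAATTTTCCCC")
  cen <- multiHitCensus(q, refs, threshold = 0.03, mode = "from_alignment")
  expect_equal(cen$unique_best, 1L)
  expect_equal(cen$tied_identical, 1L)
  expect_equal(cen$tied_nonidentical, 0L)
  expect_equal(cen$tied_conflicting_taxonomy, 0L)
  expect_equal(cen$total_assigned, 2L)

  # conflicting taxonomy inside the tie set is flagged
  tax2 <- c(U1 = "t1", I1 = "tA", I2 = "tB")
  cen2 <- multiHitCensus(q, make_ref(seqs, tax = tax2), threshold = 0.03,
                         mode = "from_alignment")
  expect_equal(cen2$tied_conflicting_taxonomy, 1L)

  # equidistant non-identical references
  seqs3 <- c(X1 = "AAAAAAAAAACCCCCCCCCC", X2 = "TAAAAAAAAACCCCCCCCCC",
             X3 = "AAAAAAAAAACCCCCCCCCG")
  q3 <- c(q = "AAAAAAAAAACCCCCCCCCC")
  cen3 <- multiHitCensus(q3, make_ref(seqs3[2:3]), threshold = 0.10,
                         mode = "from_alignment")
  expect_equal(cen3$tied_nonidentical, 1L)
})
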