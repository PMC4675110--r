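---
title: "Evaluating OTU clustering methods with pair-counting MCC"
author: "otubench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating OTU clustering methods with pair-counting MCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otubench)
```

## The problem

Amplicon surveys of microbial communities cluster 16S rRNA gene sequences
into operational taxonomic units (OTUs), almost always at a 3% distance
(97% similarity) threshold, and every downstream ecological statement is a
statement about those bins. The methods in common use disagree with each
other, and two properties are routinely conflated when they are compared:

* **stability** — whether clustering a subsample reproduces the OTUs of the
  full dataset (and whether re-running the method with the input in a
  different order does);
* **quality** — whether the OTUs faithfully represent the pairwise
  distances between the sequences at the chosen threshold.

A method can be perfectly stable and still bin sequences badly:
closed-reference assignment is stable by construction, yet inherits every
duplicate and mislabel in its database. `otubench` implements both families
of methods and both statistics so the trade-off can be measured on data
with known ground truth.

## The statistics

All evaluation happens on **dereplicated** data: identical reads are
collapsed into unique sequences with abundances, and pairs are counted over
unique sequences, unweighted by abundance. Abundances matter only for
subsampling, for greedy scan order and for rarefaction.

For a partition $P$ and a distance matrix $D$ at threshold $t$, every
unordered pair of unique sequences falls into one cell of a 2x2 table:
co-clustered and $d \le t$ (TP), separated and $d > t$ (TN), co-clustered
and $d > t$ (FP), separated and $d \le t$ (FN). The stability construction
replaces the distance relation with co-membership in a second (full-data)
partition, restricted to the subsample's sequences. Either table is
summarised by the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} \in [-1, 1],$$

with the convention $\mathrm{MCC} = 0$ whenever a marginal is zero (the
formula is undefined there, and 0 keeps experiment tables total);
sensitivity and specificity use the same convention. `stabilityConfusion()`
computes the table from the cluster contingency matrix — $TP = \sum_{ij}
\binom{n_{ij}}{2}$ and so on — which is exactly the pair-by-pair count at a
fraction of the cost; the test suite verifies both constructions against a
naive double loop over pairs.

Two boundary conventions are deliberate and exposed as arguments:

* a pair at *exactly* the threshold counts on the "should co-cluster" (TP)
  side (`inclusive = TRUE`), matching the inclusive reading of "97%
  similarity";
* clustering merges while linkage $\le t$, and greedy assignment joins at
  distance $\le t$, for the same reason.

## Distances

`distanceMatrix()` supports the two routes used in practice. For unaligned
sequences it computes affine-gap Needleman–Wunsch global alignments with
match +1, mismatch −1, gap open −2, gap extend −1 (a gap of length $k$
costs $\mathrm{open} + (k-1)\,\mathrm{extend}$); these are mothur's
documented pairwise defaults, and all four scores are adjustable through
`alignmentParams()`. The traceback breaks ties deterministically
(diagonal, then vertical, then horizontal) so results are order- and
platform-stable; the aligned strings, though not the optimal score, can
therefore depend on argument order, and the matrix always aligns the
lower-index sequence first. For pre-aligned input the distance is computed
column-wise on the shared columns.

The distance between two aligned strings is differences over compared
length. Columns where both sequences are gapped are skipped; by default a
maximal run of gap columns counts as one difference over one unit of
length ("onegap") and terminal gap columns are counted. Both options are
arguments, because published pipelines differ and the exact calculator
used in older studies is not always recoverable.

Distances are stored sparsely: only pairs at or below a **storage cutoff**
(default 0.10) are kept, and a lookup of an unstored pair answers
"above cutoff". The default leaves comfortable headroom above the 0.03
working threshold for hierarchical merging. Average linkage must average
over pairs it cannot see; by default an unstored pair contributes the
cutoff value to the mean, which biases *against* merging and is therefore
conservative. The stricter alternative (`al_missing = "unmergeable"`) is
also available, since either behaviour is defensible for sparse-matrix
clustering. Complete linkage treats any unstored pair as unmergeable, and
single linkage never needs them.

## Clustering methods

`clusterHierarchical()` is plain agglomerative clustering cut at the
threshold: repeatedly merge the pair of clusters with minimum linkage
(min, size-weighted mean, or max pairwise distance for SL/AL/CL) while
that minimum is at most $t$. Exact linkage ties are broken by a seeded
random number generator — the seed is a required, logged part of any
experiment — and on tie-free matrices every seed yields the same
partition, which the suite asserts.

`clusterGreedy()` scans sequences (by default in decreasing-abundance
order, ties by id) against the centroids created so far. A sequence within
$t$ of no centroid founds a new one; otherwise DGC joins the closest
qualifying centroid (ties: larger abundance, then id) and AGC the most
abundant qualifying centroid (ties: smaller distance, then id). Centroids
never change after creation. For order-sensitivity experiments
`makeClusterFun()` sorts by abundance with a *stable* sort, so permuting
the input with `permuteInput()` changes only the order of equal-abundance
sequences — the mechanism by which these methods are order-sensitive in
practice.

Closed-reference assignment is implemented as the *exhaustive* oracle:
every query's distance to every reference is computed and the minimum
taken. Heuristic k-mer candidate search (USEARCH/VSEARCH style) is
deliberately not emulated — its internal tie-breaking is undocumented and
unverifiable; the pluggable `xdist` argument leaves room for heuristic
backends. Exact ties are resolved by database order by default
(`tie_rule = "first_in_db_order"`), which is precisely what makes OTU
*labels* sensitive to reference order while the induced *partition* of
queries (grouping by the tied-best reference set) is provably invariant —
`randomizeReferenceExperiment()` measures exactly this, reporting the
pairwise fraction of OTU groups whose label agrees between reference
permutations. Open-reference assignment unions the closed-reference OTUs
with a DGC de novo clustering of the unassigned remainder.

The database audit counts near-duplicate pairs (distance strictly below
$1 - 0.97$, so that "more than 97% similar" includes identical pairs),
groups of records identical over the compared region, and groups whose
members carry unequal taxonomy strings after whitespace normalization; no
rank-aware comparison is attempted. Region extraction uses 1-based
inclusive alignment columns — the R/Bioconductor convention (`IRanges`,
`subseq`) — and requires flanking non-gap characters on both sides for a
record to count as covering the region.

## Rarefaction

`rarefyOtuCount()` computes the expected number of OTUs in a subsample of
$n$ reads drawn without replacement, analytically as
$E[S] = \sum_i \left[1 - \binom{N-N_i}{n}\middle/\binom{N}{n}\right]$
(evaluated via `lchoose` for numerical range) or by Monte Carlo. The suite
checks the two against each other at 10,000 replicates within three
standard errors.

## Experiment drivers

`runStabilityExperiment()` follows the canonical subsampling design:
for each fraction (defaults 20/40/60/80%) draw 30 read-level subsamples
without replacement, re-dereplicate and cluster each, and score it against
each of 30 clusterings of order-permuted full data — 900 MCC values per
fraction. Subsampling operates on reads (abundances expanded), not unique
sequences, because depth is a read-level property. Pairs are counted over
the subsample's unique sequences only; sequences absent from the subsample
cannot be classified by it, so restricting to the subsample universe is
the only self-consistent comparison, and it makes the stability MCC
symmetric in its arguments when universes coincide. Subsample unique
sequences are matched to full-data representative ids by their gap-free
strings so both partitions speak about the same universe.

`runQualityExperiment()` scores each subsample's clustering against the
subsample's own distance matrix at the working threshold and reports means
with empirical 2.5/97.5 percentile intervals (no normality assumption).
`thresholdScan()` evaluates the quality MCC on a grid (default 0 to 5% in
1% steps) and returns the maximising threshold, smallest first on ties.
`runFullComparison()` wires all of this into one report per method and
fraction, embedding the resolved configuration and seed so any report is
reproducible from its own metadata.

## The synthetic-data generator

`generateCommunity()` is first-class, tested code, not a fixture. It
emulates the structure of a dereplicated amplicon dataset: planted
clusters at controllable divergence, skewed abundances, and substitution
errors.

* **Templates.** One random ancestor is mutated heavily and independently
  per cluster; candidate template sets are rejection-sampled until all
  between-cluster *member-level* distances meet `inter_divergence`
  (template separation of at least the requested divergence plus twice
  the cluster diameter). Failure after bounded attempts errors with the
  advice to use longer sequences.
* **Satellites.** Within a cluster, variants form a mutation chain:
  each variant differs from its predecessor by
  $\lfloor \mathrm{intra} \cdot L \rfloor$ substitutions at previously
  untouched positions. Serial divergence is the natural within-population
  model, and fresh positions make every planted distance exact:
  $d(v_i, v_j) = |i-j| \cdot \mathrm{step}/L$, so `intra_divergence` is a
  *nearest-neighbour* divergence and the cluster diameter is
  $(v-1)\cdot\mathrm{step}/L$. At the defaults ($L = 250$, 4 variants,
  intra 0.01) the diameter is 0.024: within-cluster pairs up to 2.4%
  apart, between-cluster pairs at 10% or more. This places the planted
  structure where the 0-5% threshold scan has a unique optimum at 3% —
  grid points below 3% split real within-cluster pairs, and the
  smallest-on-ties rule returns 3% rather than a looser tie — while
  remaining recoverable by all five de novo methods (a complete-linkage
  merge needs the full diameter under the threshold).
* **Reads.** Per-variant weights come from the abundance model (uniform,
  log-normal with `meanlog` 0/`sdlog` 1 — the usual shape of microbial
  abundance distributions — or power-law); each variant is guaranteed one
  read so the planted partition covers every variant, and the remaining
  reads are multinomial. Substitution errors are i.i.d. per base at
  `error_rate`, default 0.02% — the error rate reported for well-curated
  MiSeq amplicon data. Indels, chimeras, homopolymer artefacts and
  quality scores are *not* modelled: planted distances stay analytic only
  under substitution, so a clean pass on synthetic data bounds
  method-induced error, not platform-induced error.

`generateReferenceDb()` plants the database pathology that makes
closed-reference labels unstable: groups of references identical over an
extracted region (with a controlled number of distinct taxonomy strings
per group) but divergent over their full length, because each record
carries independent random flanks. Distinct region sequences are kept at
least 0.10 apart so audits count exactly the planted structure.

All randomness flows from a single integer seed per generator or driver;
drivers derive per-component sub-seeds by sampling seed values, so
experiments are reproducible piecewise as well as end-to-end.

## Numerical and design choices

* MCC products are computed in double precision; counts up to
  $\binom{m}{2}$ for $m \sim 10^5$ remain exact.
* Ties: hierarchical merges by seeded RNG; greedy and reference ties by
  the documented deterministic rules above; `which.max` in the threshold
  scan takes the first (smallest) maximiser.
* Degenerate inputs: empty read sets dereplicate to empty sets, cluster to
  empty partitions and error nowhere; zero compared length between two
  aligned sequences is an error rather than a silent 0.
* Thresholds above the storage cutoff are refused rather than silently
  computed on incomplete information.
* `extractRegion()` uses 1-based inclusive columns; tools with 0-based
  half-open conventions must convert at the boundary.

## Problem sizes

The shipped tests and the acceptance script run synthetic communities of
500–1,000 reads over 5–10 clusters (20–90 unique sequences) and reference
databases of 10–24 records, with the full 30 x 30 stability design at
those sizes; property checks sweep 100–200 random instances of up to 40
sequences against brute-force oracles. These sizes exercise every code
path, including sparse-matrix behaviour, while keeping a full run in the
order of a minute; the algorithms themselves are the $O(n^2)$–$O(n^3)$
textbook versions and have been run comfortably on a few thousand unique
sequences.

## Known limitations

* The exhaustive reference matcher is quadratic; it is an oracle for
  evaluating heuristics, not a replacement for them at database scale.
* Average linkage on a sparse matrix is defined only up to the policy for
  unstored pairs; both supported policies are approximations to the dense
  computation whenever true distances exceed the cutoff but differ from
  it.
* Abundance-weighted pair counting, mutual-information comparison metrics,
  chimera simulation and platform-specific error profiles are out of
  scope.
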