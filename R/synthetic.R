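## Synthetic communities and reference databases with planted ground truth.
##
## The generator plants clusters as template sequences separated by at
## least `inter_divergence` (member-to-member, not just
## template-to-template) and, within each cluster, a chain of satellite
## variants in which consecutive variants differ by
## `floor(intra_divergence * seq_length)` substitutions at previously
## untouched positions. Serial divergence along a chain is the natural
## within-population model, and because every mutation hits a fresh
## position all planted pairwise distances are exact:
## d(variant_i, variant_j) = |i - j| * step / L.

BASES <- c("A", "C", "G", "T")

.mutateAt <- function(seq_chars, positions) {
  for (p in positions)
    seq_chars[p] <- sample(setdiff(BASES, seq_chars[p]), 1L)
  seq_chars
}

.hamming <- function(a, b) sum(a != b) / length(a)

## Templates mutually separated by at least min_sep (proportion of sites),
## built by heavy independent mutation from a shared ancestor.
.makeTemplates <- function(n, L, min_sep, max_attempts = 200L) {
  m <- max(ceiling(1.6 * min_sep * L), ceiling(0.3 * L))
  m <- min(m, L)
  for (attempt in seq_len(max_attempts)) {
    ancestor <- sample(BASES, L, replace = TRUE)
    templates <- lapply(seq_len(n), function(k)
      .mutateAt(ancestor, sample.int(L, m)))
    ok <- TRUE
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          if (.hamming(templates[[i]], templates[[j]]) < min_sep) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
    }
    if (ok) return(templates)
  }
  stop("could not place ", n, " templates at divergence >= ", min_sep,
       " within ", max_attempts, " attempts; use longer sequences")
}

#' Specification of a synthetic community
#'
#' Collects and validates the parameters of [generateCommunity()]. The
#' defaults emulate a small MiSeq-style amplicon survey: 250-nt region
#' sequences, well-separated clusters (minimum between-cluster distance
#' 0.10) each holding a short chain of satellite variants diverging by
#' \code{intra_divergence} per step, log-normal variant abundances and a
#' per-base substitution error rate of 0.02%.
#'
#' @param n_clusters number of planted OTUs
#' @param intra_divergence divergence between consecutive satellite
#'   variants within a cluster (nearest-neighbour divergence, as a
#'   proportion of sites)
#' @param inter_divergence minimum distance between members of different
#'   clusters; must exceed \code{intra_divergence}
#' @param seq_length template length in nt
#' @param n_variants variants per cluster (the template counts as one)
#' @param abundance_model \code{"uniform"}, \code{"lognormal"} or
#'   \code{"powerlaw"}
#' @param meanlog,sdlog log-normal abundance parameters
#' @param alpha power-law exponent
#' @param n_reads total reads; each variant is guaranteed at least one read
#'   so the planted partition covers every variant
#' @param error_rate per-base substitution probability in \code{[0, 0.05]}
#' @param seed integer seed; all randomness derives from it
#' @return a validated list of class \code{CommunitySpec}
#' @export
communitySpec <- function(n_clusters = 10, intra_divergence = 0.01,
                          inter_divergence = 0.10, seq_length = 250,
                          n_variants = 4,
                          abundance_model = c("lognormal", "uniform",
                                              "powerlaw"),
                          meanlog = 0, sdlog = 1, alpha = 1.5,
                          n_reads = 1000, error_rate = 2e-4, seed = 1) {
  abundance_model <- match.arg(abundance_model)
  if (inter_divergence <= intra_divergence)
    stop("inter_divergence must exceed intra_divergence")
  if (intra_divergence < 0) stop("intra_divergence must be >= 0")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  if (n_reads < n_clusters * n_variants)
    stop("n_reads must cover at least one read per variant")
  spec <- list(n_clusters = as.integer(n_clusters),
               intra_divergence = intra_divergence,
               inter_divergence = inter_divergence,
               seq_length = as.integer(seq_length),
               n_variants = as.integer(n_variants),
               abundance_model = abundance_model, meanlog = meanlog,
               sdlog = sdlog, alpha = alpha, n_reads = as.integer(n_reads),
               error_rate = error_rate, seed = as.integer(seed))
  class(spec) <- "CommunitySpec"
  spec
}

#' Generate a synthetic community with planted OTU structure
#'
#' Builds \code{n_clusters} template sequences whose members are separated
#' by at least \code{inter_divergence}, grows a chain of satellite variants
#' per cluster (consecutive variants differ by
#' \code{floor(intra_divergence * seq_length)} substitutions at fresh
#' positions, so planted distances are exact), draws reads across the
#' variant pool under the abundance model (every variant receives at least
#' one read) and applies independent per-base substitution errors. Output
#' is deterministic given the spec's seed.
#'
#' @param spec a [communitySpec()]
#' @return a list with \code{units} (the [DereplicatedSet] of the emitted
#'   reads) and \code{truth}: \code{partition} (the planted [OTUPartition]
#'   over the unique sequences), \code{template_of} (read id to cluster),
#'   \code{variant_cluster} (variant index to cluster),
#'   \code{variant_seqs} (character), and \code{max_intra}/\code{min_inter}
#'   (the planted distance bounds actually realised by the error-free
#'   variants)
#' @export
generateCommunity <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  L <- spec$seq_length
  nv <- spec$n_variants
  step <- if (nv > 1L && spec$intra_divergence > 0)
    max(1L, floor(spec$intra_divergence * L)) else 0L
  diam <- if (nv > 1L) (nv - 1L) * step / L else 0
  .withSeed(spec$seed, {
    templates <- .makeTemplates(spec$n_clusters, L,
                                spec$inter_divergence + 2 * diam)
    variants <- list()
    variant_cluster <- character(0)
    for (k in seq_len(spec$n_clusters)) {
      pool <- sample.int(L)  # fresh mutation positions for this cluster
      v <- templates[[k]]
      used <- 0L
      for (j in seq_len(nv)) {
        if (j > 1L) {
          pos <- pool[used + seq_len(step)]
          used <- used + step
          v <- .mutateAt(v, pos)
        }
        variants[[length(variants) + 1L]] <- v
        variant_cluster <- c(variant_cluster, sprintf("cluster_%03d", k))
      }
    }
    nvar <- length(variants)
    w <- switch(spec$abundance_model,
      uniform = rep(1, nvar),
      lognormal = stats::rlnorm(nvar, spec$meanlog, spec$sdlog),
      powerlaw = sample(seq_len(nvar))^(-spec$alpha))
    draw <- c(seq_len(nvar),
              sample.int(nvar, spec$n_reads - nvar, replace = TRUE,
                         prob = w))
    draw <- sample(draw)  # shuffle read order
    read_seqs <- vapply(draw, function(i) paste(variants[[i]], collapse = ""),
                        character(1))
    if (spec$error_rate > 0) {
      nerr <- stats::rbinom(spec$n_reads, L, spec$error_rate)
      for (i in which(nerr > 0L)) {
        chars <- strsplit(read_seqs[i], "")[[1]]
        read_seqs[i] <- paste(.mutateAt(chars, sample.int(L, nerr[i])),
                              collapse = "")
      }
    }
    names(read_seqs) <- sprintf("read_%06d", seq_len(spec$n_reads))
    units <- dereplicate(read_seqs)
    template_of <- stats::setNames(variant_cluster[draw], names(read_seqs))
    unit_cluster <- vapply(memberIds(units), function(mem)
      template_of[[mem[1L]]], character(1))
    planted <- OTUPartition(split(repIds(units), unit_cluster),
                            label = "planted")
    list(units = units,
         truth = list(partition = planted,
                      template_of = template_of,
                      variant_cluster = variant_cluster,
                      variant_seqs = vapply(variants, paste, character(1),
                                            collapse = ""),
                      max_intra = diam,
                      min_inter = spec$inter_divergence))
  })
}

.taxString <- function(i) {
  sprintf("k__Bacteria;p__P%03d;c__C%03d;o__O%03d;f__F%03d;g__G%03d;s__S%04d",
          i %% 7L + 1L, i %% 11L + 1L, i %% 13L + 1L, i %% 17L + 1L, i, i)
}

#' Generate a synthetic reference database with planted duplicates
#'
#' Builds full-length references (random flanks around a variable region)
#' whose region sequences are mutually distant except for planted duplicate
#' groups: sets of references identical over the region but differing in
#' their flanks, each carrying a specified number of distinct taxonomy
#' strings. Full-length sequences are pairwise far below 97% similarity
#' because the flanks are independent random sequence.
#'
#' @param n_refs total number of references
#' @param duplicate_groups list of \code{c(size, n_taxonomies)} pairs; group
#'   sizes must sum to at most \code{n_refs}
#' @param region_length length of the variable region (nt)
#' @param flank_length length of each flank (nt)
#' @param min_region_divergence minimum distance between distinct region
#'   sequences (default 0.10, so no near-duplicate pairs arise by accident)
#' @param seed integer seed
#' @return a list with \code{db} (a full-length [ReferenceDB] whose
#'   \code{region} marks the variable-region columns) and \code{truth}:
#'   \code{duplicate_members} (list of member-id vectors per planted
#'   group), \code{region_seqs} (named character, one per distinct region
#'   sequence)
#' @export
generateReferenceDb <- function(n_refs, duplicate_groups = list(),
                                region_length = 250, flank_length = 100,
                                min_region_divergence = 0.10, seed = 1) {
  sizes <- vapply(duplicate_groups, `[`, numeric(1), 1L)
  ntaxs <- vapply(duplicate_groups, `[`, numeric(1), 2L)
  if (any(sizes < 2L)) stop("duplicate groups must have size >= 2")
  if (any(ntaxs < 1L | ntaxs > sizes))
    stop("group taxonomy counts must lie in [1, size]")
  if (sum(sizes) > n_refs)
    stop("duplicate group sizes exceed n_refs")
  n_distinct <- n_refs - sum(pmax(sizes - 1L, 0L))
  .withSeed(seed, {
    region <- .makeTemplates(n_distinct, region_length,
                             min_region_divergence)
    region <- vapply(region, paste, character(1), collapse = "")
    ng <- length(duplicate_groups)
    # region sequence index per reference: groups first, then singletons
    region_of <- c(rep(seq_len(ng), times = sizes),
                   seq(ng + 1L, length.out = n_distinct - ng))
    n <- length(region_of)
    ids <- sprintf("ref_%04d", seq_len(n))
    flanks_l <- vapply(seq_len(n), function(i)
      paste(sample(BASES, flank_length, replace = TRUE), collapse = ""),
      character(1))
    flanks_r <- vapply(seq_len(n), function(i)
      paste(sample(BASES, flank_length, replace = TRUE), collapse = ""),
      character(1))
    full <- paste0(flanks_l, region[region_of], flanks_r)
    names(full) <- ids
    # taxonomy: planted groups cycle through their allotted distinct
    # strings; all other references get unique strings
    tax <- stats::setNames(.taxString(seq_len(n) + 1000L), ids)
    offset <- 0L
    for (g in seq_len(ng)) {
      mem <- ids[offset + seq_len(sizes[g])]
      pool <- .taxString(g * 100L + seq_len(ntaxs[g]))
      tax[mem] <- rep_len(pool, length(mem))
      offset <- offset + sizes[g]
    }
    db <- referenceDB(full, tax,
                      region = c(flank_length + 1L,
                                 flank_length + region_length))
    dup_members <- lapply(seq_len(ng), function(g)
      ids[sum(sizes[seq_len(g - 1L)]) + seq_len(sizes[g])])
    reg_names <- ids[!duplicated(region_of)]
    list(db = db,
         truth = list(duplicate_members = dup_members,
                      region_seqs = stats::setNames(region,
                                                    reg_names[seq_len(n_distinct)])))
  })
}
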