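## Top-level experiment driver: stability and quality by method x fraction,
## with OTU counts from subset clustering and rarefaction, reproducing the
## figure-level comparison tables from a single config.

#' Default configuration for [runFullComparison()]
#'
#' The defaults mirror the canonical benchmark design: 0.03 working
#' threshold, subsample fractions 20/40/60/80%, 30 subsample replicates
#' against 30 full-data order permutations, and a 0-5% threshold grid in 1%
#' steps.
#'
#' @param ... named overrides of any default field
#' @return a configuration list
#' @export
comparisonConfig <- function(...) {
  config <- list(methods = c("sl", "al", "cl", "agc", "dgc"),
                 threshold = 0.03,
                 cutoff = 0.10,
                 fractions = c(0.2, 0.4, 0.6, 0.8),
                 n_subsample_reps = 30,
                 n_full_perms = 30,
                 quality_reps = 30,
                 threshold_grid = seq(0, 0.05, by = 0.01),
                 distance_mode = "from_alignment",
                 seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), c(names(config), "community", "units"))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config[names(override)] <- override
  config
}

#' Run the full method comparison
#'
#' For every method in the config, runs the stability experiment
#' (subsampled clusterings scored against order-permuted full-data
#' clusterings), the quality experiment (subsampled clusterings scored
#' against their own distances at the working threshold), and tabulates OTU
#' counts: the mean OTU count of the subset clusterings and the analytic
#' rarefaction of the full-data clustering to the same depth. The report
#' embeds the resolved config so any run is reproducible from its output.
#'
#' @param config a [comparisonConfig()] holding either \code{units} (a
#'   [DereplicatedSet]) or \code{community} (a [communitySpec()] to
#'   generate)
#' @return a list with \code{config}, \code{summary} (one row per method x
#'   fraction), \code{stability_values}, \code{quality_values} and
#'   \code{full_n_otus} (per method)
#' @export
runFullComparison <- function(config = comparisonConfig()) {
  valid <- c("sl", "al", "cl", "agc", "dgc")
  bad <- setdiff(config$methods, valid)
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid methods are: ", paste(valid, collapse = ", "))
  units <- if (!is.null(config$units)) config$units
           else if (!is.null(config$community))
             generateCommunity(config$community)$units
           else stop("config must provide 'units' or 'community'")
  N <- totalReads(units)
  reads_ab <- abundances(units)
  summary_rows <- list()
  stab_all <- list()
  qual_all <- list()
  full_n_otus <- stats::setNames(numeric(length(config$methods)),
                                 config$methods)
  for (m in config$methods) {
    cf <- makeClusterFun(m, threshold = config$threshold,
                         cutoff = config$cutoff,
                         mode = config$distance_mode)
    stab <- runStabilityExperiment(units, cf,
                                   fractions = config$fractions,
                                   nSubsampleReps = config$n_subsample_reps,
                                   nFullPerms = config$n_full_perms,
                                   seed = config$seed)
    qual <- runQualityExperiment(units, cf,
                                 fractions = config$fractions,
                                 reps = config$quality_reps,
                                 threshold = config$threshold,
                                 cutoff = config$cutoff,
                                 mode = config$distance_mode,
                                 seed = config$seed + 1L)
    full_part <- cf(units, seed = config$seed)
    full_n_otus[m] <- nOtus(full_part)
    stab$method <- m
    qual$values$method <- m
    stab_all[[m]] <- stab
    qual_all[[m]] <- qual$values
    for (f in config$fractions) {
      sv <- stab$mcc[stab$fraction == f]
      qv <- qual$values$mcc[qual$values$fraction == f]
      no <- qual$values$n_otus[qual$values$fraction == f]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        method = m, fraction = f,
        stability_mean = mean(sv),
        stability_lower = unname(stats::quantile(sv, 0.025)),
        stability_upper = unname(stats::quantile(sv, 0.975)),
        quality_mean = mean(qv),
        quality_lower = unname(stats::quantile(qv, 0.025)),
        quality_upper = unname(stats::quantile(qv, 0.975)),
        n_otus_subset = mean(no),
        n_otus_rarefied = rarefyOtuCount(full_part, reads_ab,
                                         n = max(1L, round(f * N)),
                                         mode = "analytic"))
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(config = config, summary = summary,
       stability_values = do.call(rbind, stab_all),
       quality_values = do.call(rbind, qual_all),
       full_n_otus = full_n_otus)
}
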