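#' @include AllClasses.R core_data.R fit.R
NULL

#' Create an EffortSpec
#'
#' @param nLines trap-lines retained per location (1-4).
#' @param nights `"both"` or `"first_only"`.
#' @param nReplicates without-replacement subsampling replicates
#'   (default 100, as in the headline effort analysis).
#' @param seed integer seed for the replicate stream.
#' @return an [EffortSpec-class].
#' @export
effortSpec <- function(nLines, nights = c("both", "first_only"),
                       nReplicates = 100L, seed = 1L) {
  new("EffortSpec", nLines = as.integer(nLines),
      nights = match.arg(nights), nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

#' Subsample trap-lines without replacement
#'
#' For each replicate, independently at every sampling location, draws
#' `nLines` of that location's surveyed trap-lines uniformly without
#' replacement and keeps only their records (both nights; the night
#' restriction is applied later by [summarizeDetections()]). Pellet
#' transects are never subsampled. Locations with fewer surveyed lines than
#' requested keep all their lines, with a warning. Replicate streams derive
#' from the [EffortSpec-class] seed, so results are reproducible.
#'
#' @param dataset a [SurveyDataset-class].
#' @param spec an [EffortSpec-class].
#' @return list of `nReplicates` [SurveyDataset-class] objects.
#' @export
subsampleLines <- function(dataset, spec) {
  stopifnot(is(dataset, "SurveyDataset"), is(spec, "EffortSpec"))
  validObject(spec)
  tr <- trapRecords(dataset)
  byLoc <- split(tr$line_id, tr$location_id)
  byLoc <- lapply(byLoc, unique)
  short <- names(byLoc)[lengths(byLoc) < spec@nLines]
  if (length(short))
    warning(sprintf(
      "%d location(s) have fewer than %d surveyed lines (all kept): %s",
      length(short), spec@nLines, paste(short, collapse = ", ")))
  repSeeds <- deriveSeeds(spec@seed, spec@nReplicates)
  lapply(seq_len(spec@nReplicates), function(r) {
    set.seed(repSeeds[r])
    keep <- unlist(lapply(names(byLoc), function(id) {
      lines <- byLoc[[id]]
      chosen <- if (length(lines) <= spec@nLines) lines
                else sample(lines, spec@nLines)
      paste(id, chosen)
    }))
    sub <- tr[paste(tr$location_id, tr$line_id) %in% keep, , drop = FALSE]
    SurveyDataset(locations = dataset@locations, traps = sub,
                  pellets = pelletRecords(dataset))
  })
}

## posterior means of psi and zlambda (the quantities tracked in the
## effort analysis), in long form
effortEstimates <- function(fit) {
  s <- posteriorSummary(fit)
  s <- s[s$parameter %in% c("psi", "zlambda"), c("parameter", "stratum",
                                                 "mean")]
  rownames(s) <- NULL
  s
}

#' Evaluate reduced survey effort over a lines x nights grid
#'
#' For every combination of retained trap-lines and trap nights, fits the
#' occupancy-abundance model to each without-replacement subsampling
#' replicate and reports estimates and relative bias against the
#' full-effort baseline (all four lines, both nights) fitted with the same
#' configuration and seed — so the 4-line/2-night cell reproduces the
#' baseline exactly, replicate by replicate.
#'
#' @param dataset a [SurveyDataset-class].
#' @param config a [ModelConfig-class] used for the baseline and every
#'   replicate fit. For desk-scale grids, shorten `burnIn`/`keptIter`; the
#'   defaults remain the headline 10,000/50,000 settings.
#' @param nLines integer vector of line counts to evaluate (default 1:4).
#' @param nights character vector of night regimes (default both regimes).
#' @param nReplicates subsampling replicates per cell (default 100).
#' @param seed seed for the subsampling streams.
#' @return list of [EffortResult-class], one per grid cell, named
#'   `"<nLines>lines_<nights>"`.
#' @export
runEffortGrid <- function(dataset, config = modelConfig(),
                          nLines = 1:4,
                          nights = c("both", "first_only"),
                          nReplicates = 100L, seed = 1L) {
  stopifnot(is(dataset, "SurveyDataset"))
  nights <- match.arg(nights, several.ok = TRUE)
  baseFit <- fitOccAbund(summarizeDetections(dataset, "both"), config)
  baseline <- effortEstimates(baseFit)

  cells <- expand.grid(nLines = nLines, nights = nights,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  names(out) <- paste0(cells$nLines, "lines_", cells$nights)
  for (ci in seq_len(nrow(cells))) {
    k <- cells$nLines[ci]; ngt <- cells$nights[ci]
    reps <- subsampleLines(dataset,
                           effortSpec(k, ngt, nReplicates, seed))
    est <- do.call(rbind, lapply(seq_along(reps), function(r) {
      f <- fitOccAbund(summarizeDetections(reps[[r]], ngt), config)
      cbind(replicate = r, effortEstimates(f),
            converged = isConverged(f))
    }))
    merged <- merge(est, baseline, by = c("parameter", "stratum"),
                    suffixes = c("", "_baseline"))
    merged$rel_bias <- (merged$mean - merged$mean_baseline) /
      merged$mean_baseline
    merged <- merged[order(merged$replicate, merged$parameter,
                           merged$stratum), , drop = FALSE]
    rownames(merged) <- NULL
    agg <- do.call(rbind, lapply(
      split(merged, merged[c("parameter", "stratum")], drop = TRUE),
      function(d) data.frame(
        parameter = d$parameter[1], stratum = d$stratum[1],
        mean_rel_bias = mean(d$rel_bias),
        min_rel_bias = min(d$rel_bias), max_rel_bias = max(d$rel_bias),
        cv_of_estimates = stats::sd(d$mean) / mean(d$mean),
        prop_converged = mean(d$converged),
        stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    out[[ci]] <- new("EffortResult", nLines = as.integer(k), nights = ngt,
                     replicateEstimates =
                       merged[c("replicate", "parameter", "stratum", "mean",
                                "converged")],
                     baseline = baseline,
                     relativeBias =
                       merged[c("replicate", "parameter", "stratum",
                                "rel_bias")],
                     summaries = agg)
  }
  out
}

setMethod("show", "EffortResult", function(object) {
  cat(sprintf("EffortResult: %d trap-line(s), nights = %s, %d replicates\n",
              object@nLines, object@nights,
              max(object@replicateEstimates$replicate)))
  s <- object@summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %-9s rel bias mean %+6.1f%% range [%+6.1f%%, %+6.1f%%]\n",
                s$parameter[i], s$stratum[i], 100 * s$mean_rel_bias[i],
                100 * s$min_rel_bias[i], 100 * s$max_rel_bias[i]))
})

#' Compare two-night and first-night-only analyses side by side
#'
#' Fits the model to the same dataset using both trap nights and the first
#' night only, pooled and stratified by habitat, and returns the posterior
#' summaries in one table. Pellet data are identical under both regimes,
#' so differences reflect the trapping information alone.
#'
#' @param dataset a [SurveyDataset-class] (two-night data present).
#' @param config a [ModelConfig-class]; its `strata` slot is overridden.
#' @return data.frame of posterior summaries with `nights` and `strata`
#'   columns prepended.
#' @export
compareNights <- function(dataset, config = modelConfig()) {
  stopifnot(is(dataset, "SurveyDataset"))
  out <- list()
  for (ngt in c("both", "first_only")) {
    for (str in c("pooled", "by_habitat")) {
      cfg <- config
      cfg@strata <- str
      f <- fitOccAbund(summarizeDetections(dataset, ngt), cfg)
      out[[length(out) + 1L]] <- cbind(nights = ngt, strata = str,
                                       posteriorSummary(f))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
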