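#' @include AllClasses.R core_data.R
NULL

#' Create a synthetic survey design
#'
#' Defaults emulate the phased implementation of the national monitoring
#' programme: 164 locations (85 forest, 79 non-forest), 4 trap-lines of 10
#' traps run for 2 nights and 4 pellet transects of 30 plots per location,
#' with 16% of locations missing part of their line set. Occupancy and
#' conditional mean TCI default to forest 0.8 / 4.5 and non-forest 0.4 /
#' 2.0, which pool to the magnitudes the programme reports (occupancy near
#' 0.6, mean TCI in the low single digits); per-plot pellet detection 0.05
#' gives a per-transect detection near 0.79. Non-target and sprung-trap
#' rates (2% per trap-night each) are free parameters of the generator.
#'
#' @param nForest,nNonforest locations per habitat.
#' @param psi named occupancy probabilities `c(forest=, nonforest=)`.
#' @param lambda named conditional mean TCI `c(forest=, nonforest=)`.
#' @param pelletPlotP per-plot pellet detection probability given occupancy.
#' @param nontargetRate,sprungRate per-trap-night event probabilities.
#' @param missingLineFraction proportion of locations with missing units.
#' @param linesPerLocation,trapsPerLine,nights,plotsPerTransect geometry.
#' @param seed integer RNG seed.
#' @return a [SimDesign-class].
#' @export
simDesign <- function(nForest = 85L, nNonforest = 79L,
                      psi = c(forest = 0.8, nonforest = 0.4),
                      lambda = c(forest = 4.5, nonforest = 2.0),
                      pelletPlotP = 0.05,
                      nontargetRate = 0.02, sprungRate = 0.02,
                      missingLineFraction = 0.16,
                      linesPerLocation = 4L, trapsPerLine = 10L,
                      nights = 2L, plotsPerTransect = 30L, seed = 1L) {
  new("SimDesign", nForest = as.integer(nForest),
      nNonforest = as.integer(nNonforest),
      psi = psi[HABITATS], lambda = lambda[HABITATS],
      pelletPlotP = pelletPlotP, nontargetRate = nontargetRate,
      sprungRate = sprungRate, missingLineFraction = missingLineFraction,
      linesPerLocation = as.integer(linesPerLocation),
      trapsPerLine = as.integer(trapsPerLine), nights = as.integer(nights),
      plotsPerTransect = as.integer(plotsPerTransect),
      seed = as.integer(seed))
}

setMethod("show", "SimDesign", function(object) {
  cat("SimDesign:", object@nForest, "forest +", object@nNonforest,
      "non-forest locations\n")
  cat(sprintf("  psi = (%.2f, %.2f), lambda = (%.2f, %.2f), seed = %d\n",
              object@psi["forest"], object@psi["nonforest"],
              object@lambda["forest"], object@lambda["nonforest"],
              object@seed))
})

#' Simulate a survey dataset from the occupancy-abundance process
#'
#' Generates data exactly under the model the package fits: latent occupancy
#' `z_i ~ Bernoulli(psi_habitat)`; per trap-line and night, non-target and
#' sprung-trap events are Binomial draws that reduce the corrected
#' trap-nights `e`, then possum captures are `Poisson(z_i * e *
#' lambda_habitat / 100)` truncated at the traps still available (a line
#' cannot hold more possums than it has free traps); pellet-transect
#' presence is the union of 30 per-plot Bernoulli(`pelletPlotP`) draws,
#' forced to 0 at unoccupied locations (no false positives). A seeded random
#' subset of locations loses 1-2 of its 8 units, emulating incomplete
#' surveys. Trap-line detection is emergent from captures, so `X = 1(C > 0)`
#' holds by construction.
#'
#' @param design a [SimDesign-class].
#' @return list with elements `dataset` (a [SurveyDataset-class]) and
#'   `truth` (latent z, the design parameters, and the implied per-method
#'   detection probabilities from [impliedDetection()]).
#' @export
simulateSurvey <- function(design) {
  stopifnot(is(design, "SimDesign"))
  validObject(design)
  set.seed(design@seed)
  n <- design@nForest + design@nNonforest
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("L%0", width, "d"), seq_len(n))
  habitat <- c(rep("forest", design@nForest),
               rep("nonforest", design@nNonforest))
  z <- stats::rbinom(n, 1L, design@psi[habitat])

  lines <- TRAP_LINES[seq_len(design@linesPerLocation)]
  tr <- expand.grid(night = seq_len(design@nights), line_id = lines,
                    loc = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  m <- nrow(tr)
  traps <- design@trapsPerLine
  nontarget <- stats::rbinom(m, traps, design@nontargetRate)
  sprung <- stats::rbinom(m, pmax(traps - nontarget, 0L), design@sprungRate)
  e <- traps - 0.5 * (nontarget + sprung)
  mu <- z[tr$loc] * e * design@lambda[habitat[tr$loc]] / 100
  captures <- pmin(stats::rpois(m, mu), traps - nontarget - sprung)
  trapdf <- data.frame(location_id = ids[tr$loc], line_id = tr$line_id,
                       night = as.integer(tr$night),
                       traps_set = traps, possum_captures = captures,
                       nontarget_captures = nontarget, sprung_empty = sprung,
                       stringsAsFactors = FALSE)

  pe <- expand.grid(transect_id = PELLET_TRANSECTS, loc = seq_len(n),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hits <- stats::rbinom(nrow(pe), design@plotsPerTransect, design@pelletPlotP)
  presence <- as.integer(z[pe$loc] == 1L & hits > 0L)
  pelletdf <- data.frame(location_id = ids[pe$loc],
                         transect_id = pe$transect_id,
                         presence = presence, stringsAsFactors = FALSE)

  ## missing-at-random incomplete surveys: drop 1-2 of the 8 units
  n_miss <- round(design@missingLineFraction * n)
  if (n_miss > 0) {
    miss_loc <- sample.int(n, n_miss)
    for (i in miss_loc) {
      k <- sample(1:2, 1L)
      drop_units <- sample(UNIT_COLUMNS, k)
      drop_lines <- intersect(drop_units, lines)
      drop_tran <- intersect(drop_units, PELLET_TRANSECTS)
      if (length(drop_lines))
        trapdf <- trapdf[!(trapdf$location_id == ids[i] &
                             trapdf$line_id %in% drop_lines), , drop = FALSE]
      if (length(drop_tran))
        pelletdf <- pelletdf[!(pelletdf$location_id == ids[i] &
                                 pelletdf$transect_id %in% drop_tran), ,
                             drop = FALSE]
    }
  }

  dataset <- SurveyDataset(
    locations = data.frame(location_id = ids, habitat = habitat,
                           stringsAsFactors = FALSE),
    traps = trapdf, pellets = pelletdf)
  list(dataset = dataset,
       truth = list(z = stats::setNames(z, ids),
                    psi = design@psi, lambda = design@lambda,
                    pellet_plot_p = design@pelletPlotP,
                    implied = impliedDetection(design),
                    design = design))
}

#' Detection probabilities implied by a synthetic design
#'
#' Links the generator's rates to the model's per-line detection
#' probabilities: for trap-lines, captures are Poisson with mean
#' `e_bar * lambda / 100`, so detection at an occupied location is
#' `1 - exp(-e_bar * lambda / 100)` with `e_bar` the expected corrected
#' trap-nights of the line under the night regime (truncation at the trap
#' count is ignored; negligible at realistic lambda). For pellet transects,
#' `1 - (1 - pelletPlotP)^plots`.
#'
#' @param design a [SimDesign-class].
#' @param nights `"both"` or `"first_only"` (trap detection only).
#' @return list with `p_trap` (named per habitat) and `p_pellet` (scalar).
#' @export
impliedDetection <- function(design, nights = c("both", "first_only")) {
  stopifnot(is(design, "SimDesign"))
  nights <- match.arg(nights)
  n_nights <- if (nights == "both") design@nights else 1L
  e_night <- design@trapsPerLine *
    (1 - 0.5 * (design@nontargetRate +
                  (1 - design@nontargetRate) * design@sprungRate))
  e_bar <- n_nights * e_night
  p_trap <- 1 - exp(-e_bar * design@lambda / 100)
  p_pellet <- 1 - (1 - design@pelletPlotP)^design@plotsPerTransect
  list(p_trap = p_trap, p_pellet = p_pellet, expected_trap_nights = e_bar)
}
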