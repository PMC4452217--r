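## Central S4 classes. Survey geometry follows the national 8-km-grid design:
## each sampling location carries four 10-trap leg-hold trap-lines (AA, DD,
## MM, PP) run for up to two nights, and four 30-plot faecal-pellet transects
## (A, D, M, P).

#' Trap-line identifiers used at every sampling location
#' @keywords internal
TRAP_LINES <- c("AA", "DD", "MM", "PP")

#' Pellet-transect identifiers used at every sampling location
#' @keywords internal
PELLET_TRANSECTS <- c("A", "D", "M", "P")

#' Column order of the 8 detection units (4 trap-lines then 4 transects)
#' @keywords internal
UNIT_COLUMNS <- c(TRAP_LINES, PELLET_TRANSECTS)

HABITATS <- c("forest", "nonforest")

#' SurveyDataset: per-location trap-line and pellet-transect records
#'
#' Container for one season of possum survey data. `locations` holds one row
#' per sampling location (`location_id`, `habitat`); `traps` one row per
#' (location, trap-line, night) with trap counts; `pellets` one row per
#' (location, transect) with the transect-level pellet presence bit. Lines or
#' transects that were not surveyed (e.g. dangerous terrain) simply have no
#' row: absence of a record means missing, never a zero observation.
#'
#' @slot locations data.frame with columns `location_id`, `habitat`
#'   (`"forest"`/`"nonforest"`).
#' @slot traps data.frame with columns `location_id`, `line_id`, `night`,
#'   `traps_set`, `possum_captures`, `nontarget_captures`, `sprung_empty`.
#' @slot pellets data.frame with columns `location_id`, `transect_id`,
#'   `presence` (0/1).
#' @seealso [SurveyDataset()], [readSurveyCsv()], [summarizeDetections()]
#' @export
setClass("SurveyDataset",
  slots = c(locations = "data.frame",
            traps     = "data.frame",
            pellets   = "data.frame"))

setValidity("SurveyDataset", function(object) {
  msgs <- character()
  loc <- object@locations
  tr  <- object@traps
  pe  <- object@pellets
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      msgs <<- c(msgs, sprintf("%s missing column(s): %s", what,
                               paste(miss, collapse = ", ")))
    length(miss) == 0L
  }
  ok_loc <- need(loc, c("location_id", "habitat"), "locations")
  ok_tr  <- need(tr, c("location_id", "line_id", "night", "traps_set",
                       "possum_captures", "nontarget_captures",
                       "sprung_empty"), "traps")
  ok_pe  <- need(pe, c("location_id", "transect_id", "presence"), "pellets")
  if (!ok_loc || !ok_tr || !ok_pe) return(msgs)

  if (anyDuplicated(loc$location_id))
    msgs <- c(msgs, "duplicate location_id in locations")
  bad_hab <- !loc$habitat %in% HABITATS
  if (any(bad_hab))
    msgs <- c(msgs, sprintf("invalid habitat value(s): %s",
                            paste(unique(loc$habitat[bad_hab]), collapse = ", ")))

  if (nrow(tr)) {
    if (!all(tr$location_id %in% loc$location_id))
      msgs <- c(msgs, "trap record location_id not listed in locations")
    if (!all(tr$line_id %in% TRAP_LINES))
      msgs <- c(msgs, "trap line_id outside {AA, DD, MM, PP}")
    if (!all(tr$night %in% c(1L, 2L)))
      msgs <- c(msgs, "trap night outside {1, 2}")
    cnt <- tr[c("traps_set", "possum_captures", "nontarget_captures",
                "sprung_empty")]
    if (any(unlist(cnt) < 0, na.rm = TRUE))
      msgs <- c(msgs, "negative count in trap records")
    over <- with(tr, possum_captures + nontarget_captures + sprung_empty >
                   traps_set)
    if (any(over, na.rm = TRUE))
      msgs <- c(msgs, sprintf(
        "trap record row(s) %s: captures + non-target + sprung exceed traps_set",
        paste(which(over), collapse = ", ")))
    if (anyDuplicated(tr[c("location_id", "line_id", "night")]))
      msgs <- c(msgs, "duplicate (location, line, night) trap record")
  }
  if (nrow(pe)) {
    if (!all(pe$location_id %in% loc$location_id))
      msgs <- c(msgs, "pellet record location_id not listed in locations")
    if (!all(pe$transect_id %in% PELLET_TRANSECTS))
      msgs <- c(msgs, "pellet transect_id outside {A, D, M, P}")
    if (!all(pe$presence %in% c(0L, 1L)))
      msgs <- c(msgs, "pellet presence must be 0/1")
    if (anyDuplicated(pe[c("location_id", "transect_id")]))
      msgs <- c(msgs, "duplicate (location, transect) pellet record")
  }
  if (length(msgs)) msgs else TRUE
})

#' DetectionSummary: model-ready detection and abundance matrices
#'
#' Per-location matrices indexed j = 1-4 over trap-lines (AA, DD, MM, PP) and
#' j = 5-8 over pellet transects (A, D, M, P), assembled by
#' [summarizeDetections()]. `NA` marks units that were not surveyed.
#'
#' @slot X n x 8 binary detection matrix (trap-lines then transects).
#' @slot Y n x 4 Trap Catch Index values (possums per 100 corrected
#'   trap-nights).
#' @slot E n x 4 corrected trap-nights underlying each TCI value.
#' @slot C n x 4 raw possum capture counts.
#' @slot habitat character vector of per-location habitat labels.
#' @slot nights `"both"` or `"first_only"` — which trap nights were used.
#' @export
setClass("DetectionSummary",
  slots = c(X = "matrix", Y = "matrix", E = "matrix", C = "matrix",
            habitat = "character", nights = "character"))

setValidity("DetectionSummary", function(object) {
  msgs <- character()
  n <- nrow(object@X)
  if (ncol(object@X) != 8L) msgs <- c(msgs, "X must have 8 columns")
  for (nm in c("Y", "E", "C")) {
    m <- slot(object, nm)
    if (nrow(m) != n || ncol(m) != 4L)
      msgs <- c(msgs, sprintf("%s must be n x 4", nm))
  }
  if (length(object@habitat) != n)
    msgs <- c(msgs, "habitat length must match rows of X")
  if (!object@nights %in% c("both", "first_only"))
    msgs <- c(msgs, "nights must be 'both' or 'first_only'")
  X <- object@X; Y <- object@Y; E <- object@E; C <- object@C
  if (any(X[!is.na(X)] != 0 & X[!is.na(X)] != 1))
    msgs <- c(msgs, "X entries must be 0/1 or NA")
  if (any(Y[!is.na(Y)] < 0)) msgs <- c(msgs, "negative TCI value")
  if (any(!is.na(Y) & is.na(E)) || any(E[!is.na(Y) & !is.na(E)] <= 0))
    msgs <- c(msgs, "E must be positive wherever Y is observed")
  both <- !is.na(C) & !is.na(X[, 1:4, drop = FALSE])
  if (any((C > 0)[both] != (X[, 1:4, drop = FALSE] == 1)[both]))
    msgs <- c(msgs, "trap-line X must equal 1(C > 0)")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: sampler and prior settings for the occupancy-abundance model
#'
#' Defaults follow the headline analysis: two chains, 10,000 burn-in and
#' 50,000 kept iterations per chain (100,000 posterior draws), Beta(1,1)
#' priors on occupancy and the per-method detection probabilities, and a
#' diffuse Normal(0, variance 100) prior on log(lambda).
#'
#' @slot nChains number of MCMC chains (>= 2 for convergence diagnostics).
#' @slot burnIn discarded iterations per chain.
#' @slot keptIter kept iterations per chain.
#' @slot seed integer RNG seed; all chain streams derive from it.
#' @slot priorPsi,priorP Beta shape pairs for psi and p.
#' @slot priorLogLambdaMean,priorLogLambdaSd Normal prior on log(lambda);
#'   the default sd 10 encodes variance 100 (diffuse). A BUGS-style
#'   precision-100 reading (sd 0.1) can be requested explicitly.
#' @slot likelihoodMode `"count_offset"` (captures ~ Poisson with corrected
#'   trap-nights as effort offset; default) or `"tci_rounded"` (TCI rounded
#'   to the nearest integer and modelled Poisson(z * lambda) directly).
#' @slot strata `"pooled"` or `"by_habitat"` (psi and lambda per habitat;
#'   detection probabilities always shared).
#' @slot methods subset of `c("traps", "pellets")` used for detection.
#' @slot rhatThreshold convergence flag threshold (default 1.1).
#' @export
setClass("ModelConfig",
  slots = c(nChains = "integer", burnIn = "integer", keptIter = "integer",
            seed = "integer",
            priorPsi = "numeric", priorP = "numeric",
            priorLogLambdaMean = "numeric", priorLogLambdaSd = "numeric",
            likelihoodMode = "character", strata = "character",
            methods = "character", rhatThreshold = "numeric"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be >= 1")
  if (object@burnIn < 1L || object@keptIter < 1L)
    msgs <- c(msgs, "burnIn and keptIter must be >= 1")
  if (length(object@priorPsi) != 2L || any(object@priorPsi <= 0))
    msgs <- c(msgs, "priorPsi must be two positive Beta shapes")
  if (length(object@priorP) != 2L || any(object@priorP <= 0))
    msgs <- c(msgs, "priorP must be two positive Beta shapes")
  if (object@priorLogLambdaSd <= 0)
    msgs <- c(msgs, "priorLogLambdaSd must be positive")
  if (!object@likelihoodMode %in% c("count_offset", "tci_rounded"))
    msgs <- c(msgs, "likelihoodMode must be 'count_offset' or 'tci_rounded'")
  if (!object@strata %in% c("pooled", "by_habitat"))
    msgs <- c(msgs, "strata must be 'pooled' or 'by_habitat'")
  if (!length(object@methods) || !all(object@methods %in% c("traps", "pellets")))
    msgs <- c(msgs, "methods must be a non-empty subset of {traps, pellets}")
  if (length(msgs)) msgs else TRUE
})

#' PosteriorResult: combined posterior draws and summaries
#'
#' @slot draws matrix of combined post-burn-in draws (rows = iterations from
#'   all chains stacked; columns = parameters, including the derived
#'   `zlambda` = lambda x psi computed draw-by-draw).
#' @slot chain integer chain index for every row of `draws`.
#' @slot summaries data.frame: parameter, stratum, mean, sd, ci_lower,
#'   ci_upper (central 95% credible interval), cv (sd/mean), rhat.
#' @slot rhat named per-parameter Gelman-Rubin statistics.
#' @slot converged TRUE when all finite R-hat values fall below the
#'   configured threshold.
#' @slot zTotals matrix of per-draw occupied-location counts per stratum.
#' @slot z optional matrix of per-draw latent occupancy indicators
#'   (kept only when `fitOccAbund(keepZ = TRUE)`; 0 rows otherwise).
#' @slot config the [ModelConfig-class] used for the fit.
#' @export
setClass("PosteriorResult",
  slots = c(draws = "matrix", chain = "integer", summaries = "data.frame",
            rhat = "numeric", converged = "logical", zTotals = "matrix",
            z = "matrix", config = "ModelConfig"))

setValidity("PosteriorResult", function(object) {
  msgs <- character()
  if (nrow(object@draws) != length(object@chain))
    msgs <- c(msgs, "chain index length must match draws rows")
  s <- object@summaries
  need <- c("parameter", "stratum", "mean", "sd", "ci_lower", "ci_upper",
            "cv", "rhat")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, "summaries missing required columns")
  else if (any(s$ci_lower > s$ci_upper, na.rm = TRUE))
    msgs <- c(msgs, "credible interval bounds out of order")
  if (length(msgs)) msgs else TRUE
})

#' EffortSpec: a reduced-effort sampling design to evaluate
#'
#' @slot nLines trap-lines retained per location (1-4).
#' @slot nights `"both"` or `"first_only"`.
#' @slot nReplicates without-replacement subsampling replicates (default 100).
#' @slot seed integer seed for the replicate stream.
#' @export
setClass("EffortSpec",
  slots = c(nLines = "integer", nights = "character",
            nReplicates = "integer", seed = "integer"))

setValidity("EffortSpec", function(object) {
  msgs <- character()
  if (!object@nLines %in% 1:4) msgs <- c(msgs, "nLines must be in 1..4")
  if (!object@nights %in% c("both", "first_only"))
    msgs <- c(msgs, "nights must be 'both' or 'first_only'")
  if (object@nReplicates < 1L) msgs <- c(msgs, "nReplicates must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' EffortResult: replicate estimates and relative bias for one design cell
#'
#' @slot nLines,nights the design cell evaluated.
#' @slot replicateEstimates data.frame of per-replicate posterior means
#'   (one row per replicate x stratum x parameter).
#' @slot baseline data.frame of full-effort (4 lines, both nights) posterior
#'   means in the same layout.
#' @slot relativeBias data.frame of per-replicate (estimate - baseline) /
#'   baseline.
#' @slot summaries data.frame with mean/min/max relative bias and the CV of
#'   replicate estimates per parameter and stratum.
#' @export
setClass("EffortResult",
  slots = c(nLines = "integer", nights = "character",
            replicateEstimates = "data.frame", baseline = "data.frame",
            relativeBias = "data.frame", summaries = "data.frame"))

#' CostSchedule: unit costs and logistics of the annual monitoring programme
#'
#' Defaults are the programme's 2013 NZD rates: transport NZ$2,943.00 per
#' location (vehicle 498.00 + helicopter 2,445.00), equipment NZ$335.00,
#' labour NZ$22.50/h, field allowance NZ$21.00 and food NZ$22.61 per
#' person-day, two-person teams working 8 h x 3 d (two-night trapping) or
#' 10 h x 2 d (one-night), 271 locations per year, a 172-day field season
#' with 30% of days lost to weather.
#'
#' @slot vehiclePerLocation,helicopterPerLocation,equipmentPerLocation fixed
#'   per-location costs (NZD).
#' @slot labourRate NZD per person-hour.
#' @slot allowancePerPersonDay,foodPerPersonDay NZD per person-day.
#' @slot crewSize persons per field team.
#' @slot hoursPerDay named numeric `c(two_night=, one_night=)`.
#' @slot daysOnSite named numeric `c(two_night=, one_night=)`.
#' @slot locationsPerYear sampling locations measured annually.
#' @slot seasonDays potential field days in a season.
#' @slot weatherLossFraction proportion of season days lost to weather.
#' @export
setClass("CostSchedule",
  slots = c(vehiclePerLocation = "numeric", helicopterPerLocation = "numeric",
            equipmentPerLocation = "numeric", labourRate = "numeric",
            allowancePerPersonDay = "numeric", foodPerPersonDay = "numeric",
            crewSize = "integer", hoursPerDay = "numeric",
            daysOnSite = "numeric", locationsPerYear = "integer",
            seasonDays = "integer", weatherLossFraction = "numeric"))

setValidity("CostSchedule", function(object) {
  msgs <- character()
  rates <- c(object@vehiclePerLocation, object@helicopterPerLocation,
             object@equipmentPerLocation, object@labourRate,
             object@allowancePerPersonDay, object@foodPerPersonDay)
  if (any(rates < 0)) msgs <- c(msgs, "cost rates must be >= 0")
  for (nm in c("hoursPerDay", "daysOnSite")) {
    v <- slot(object, nm)
    if (!all(c("two_night", "one_night") %in% names(v)) || any(v <= 0))
      msgs <- c(msgs, sprintf("%s must be positive and name both regimes", nm))
  }
  if (object@crewSize < 1L) msgs <- c(msgs, "crewSize must be >= 1")
  if (object@weatherLossFraction < 0 || object@weatherLossFraction >= 1)
    msgs <- c(msgs, "weatherLossFraction must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' SimDesign: synthetic survey design emulating the national grid study
#'
#' Defaults emulate the phased-implementation seasons: 85 forest and 79
#' non-forest locations, 4 trap-lines x 10 traps x 2 nights and 4 pellet
#' transects x 30 plots per location, and 16% of locations with an
#' incomplete set of lines.
#'
#' @slot nForest,nNonforest locations per habitat.
#' @slot psi named per-habitat occupancy probabilities.
#' @slot lambda named per-habitat conditional mean TCI (given occupancy).
#' @slot pelletPlotP per-plot pellet detection probability given occupancy.
#' @slot nontargetRate,sprungRate per-trap-night probabilities of a
#'   non-target capture / sprung-but-empty trap.
#' @slot missingLineFraction proportion of locations missing some units.
#' @slot linesPerLocation,trapsPerLine,nights,plotsPerTransect geometry.
#' @slot seed integer RNG seed.
#' @export
setClass("SimDesign",
  slots = c(nForest = "integer", nNonforest = "integer",
            psi = "numeric", lambda = "numeric", pelletPlotP = "numeric",
            nontargetRate = "numeric", sprungRate = "numeric",
            missingLineFraction = "numeric",
            linesPerLocation = "integer", trapsPerLine = "integer",
            nights = "integer", plotsPerTransect = "integer",
            seed = "integer"))

setValidity("SimDesign", function(object) {
  msgs <- character()
  probs <- c(object@psi, object@pelletPlotP, object@nontargetRate,
             object@sprungRate, object@missingLineFraction)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (!all(HABITATS %in% names(object@psi)) ||
      !all(HABITATS %in% names(object@lambda)))
    msgs <- c(msgs, "psi and lambda must name forest and nonforest")
  if (any(object@lambda < 0)) msgs <- c(msgs, "lambda must be >= 0")
  geom <- c(object@nForest, object@nNonforest)
  if (any(geom < 0)) msgs <- c(msgs, "location counts must be >= 0")
  if (any(c(object@linesPerLocation, object@trapsPerLine, object@nights,
            object@plotsPerTransect) < 1))
    msgs <- c(msgs, "design geometry must be positive")
  if (object@nights > 2L) msgs <- c(msgs, "at most 2 trap nights supported")
  if (object@linesPerLocation > 4L)
    msgs <- c(msgs, "at most 4 trap-lines supported")
  if (length(msgs)) msgs else TRUE
})
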