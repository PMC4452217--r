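#' @include AllClasses.R core_data.R
NULL

#' Create a ModelConfig
#'
#' @param nChains,burnIn,keptIter chain geometry; defaults 2 chains,
#'   10,000 burn-in and 50,000 kept iterations each (100,000 draws).
#' @param seed integer seed; per-chain streams are derived from it.
#' @param priorPsi,priorP Beta shape pairs (default Beta(1,1), uniform).
#' @param priorLogLambdaMean,priorLogLambdaSd Normal prior on log(lambda);
#'   default mean 0, sd 10 (variance 100, diffuse).
#' @param likelihoodMode `"count_offset"` (default) or `"tci_rounded"`; see
#'   [ModelConfig-class].
#' @param strata `"pooled"` or `"by_habitat"`.
#' @param methods detection methods to use, subset of `c("traps","pellets")`.
#' @param rhatThreshold R-hat convergence threshold (default 1.1).
#' @return a [ModelConfig-class]
#' @export
modelConfig <- function(nChains = 2L, burnIn = 10000L, keptIter = 50000L,
                        seed = 1L, priorPsi = c(1, 1), priorP = c(1, 1),
                        priorLogLambdaMean = 0, priorLogLambdaSd = 10,
                        likelihoodMode = c("count_offset", "tci_rounded"),
                        strata = c("pooled", "by_habitat"),
                        methods = c("traps", "pellets"),
                        rhatThreshold = 1.1) {
  new("ModelConfig", nChains = as.integer(nChains),
      burnIn = as.integer(burnIn), keptIter = as.integer(keptIter),
      seed = as.integer(seed), priorPsi = as.numeric(priorPsi),
      priorP = as.numeric(priorP),
      priorLogLambdaMean = priorLogLambdaMean,
      priorLogLambdaSd = priorLogLambdaSd,
      likelihoodMode = match.arg(likelihoodMode),
      strata = match.arg(strata),
      methods = match.arg(methods, several.ok = TRUE),
      rhatThreshold = rhatThreshold)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %d chain(s) x (%d burn-in + %d kept), seed %d\n",
    object@nChains, object@burnIn, object@keptIter, object@seed))
  cat(sprintf("  likelihood %s, strata %s, methods {%s}\n",
              object@likelihoodMode, object@strata,
              paste(object@methods, collapse = ", ")))
})

## Internal: precomputed per-location sufficient statistics, so each MCMC
## sweep is O(n) in vectorised arithmetic.
##  - xTrap/xPel:     detections among observed units, per method
##  - nTrapObs/nPelObs: observed units per method
##  - cSum/eSum:      total captures / corrected trap-nights over observed
##                    lines (count_offset mode)
##  - yrSum/nYObs:    total rounded TCI / observed lines (tci_rounded mode)
buildModelStats <- function(data, config) {
  stopifnot(is(data, "DetectionSummary"))
  n <- nLocations(data)
  if (n < 1L) stop("no locations with observations")
  use_traps <- "traps" %in% config@methods
  use_pellets <- "pellets" %in% config@methods
  Xt <- data@X[, 1:4, drop = FALSE]
  Xp <- data@X[, 5:8, drop = FALSE]
  zero <- numeric(n)
  stats <- list(
    n = n,
    use_traps = use_traps, use_pellets = use_pellets,
    xTrap = if (use_traps) rowSums(Xt == 1, na.rm = TRUE) else zero,
    nTrapObs = if (use_traps) rowSums(!is.na(Xt)) else zero,
    xPel = if (use_pellets) rowSums(Xp == 1, na.rm = TRUE) else zero,
    nPelObs = if (use_pellets) rowSums(!is.na(Xp)) else zero,
    cSum = if (use_traps) rowSums(data@C, na.rm = TRUE) else zero,
    eSum = if (use_traps) rowSums(data@E * !is.na(data@Y), na.rm = TRUE)
           else zero,
    yrSum = if (use_traps) rowSums(round(data@Y), na.rm = TRUE) else zero,
    nYObs = if (use_traps) rowSums(!is.na(data@Y)) else zero)
  stats$detAny <- (stats$xTrap + stats$xPel) > 0
  if (config@strata == "by_habitat") {
    stats$strata <- HABITATS
    stats$sIdx <- match(data@habitat, HABITATS)
    if (anyNA(stats$sIdx)) stop("habitat labels must be forest/nonforest")
  } else {
    stats$strata <- "pooled"
    stats$sIdx <- rep(1L, n)
  }
  stats$sList <- lapply(seq_along(stats$strata),
                        function(s) which(stats$sIdx == s))
  ## mean positive TCI per stratum for initialisation
  stats$lambdaInit <- vapply(stats$sList, function(ix) {
    y <- data@Y[ix, , drop = FALSE]
    pos <- y[!is.na(y) & y > 0]
    if (length(pos)) mean(pos) else 1
  }, numeric(1))
  stats
}

#' Joint data log-likelihood of the occupancy-abundance model
#'
#' Evaluates the log-likelihood of the observed detection histories and TCI
#' values given a full latent state: Bernoulli terms `X_ij ~ Bern(z_i p_j)`
#' over observed units (trap columns use `p_trap`, pellet columns
#' `p_pellet`) plus the zero-inflated Poisson abundance terms for the trap
#' lines (`C_ij ~ Poisson(z_i E_ij lambda/100)` under `count_offset`,
#' `round(Y_ij) ~ Poisson(z_i lambda)` under `tci_rounded`). Missing
#' entries contribute nothing; a positive observation at a location with
#' `z_i = 0` yields `-Inf`.
#'
#' @param state list with elements `z` (0/1 per location), `p_trap`,
#'   `p_pellet`, and `lambda` (scalar, or one value per stratum when the
#'   config is stratified).
#' @param data a [DetectionSummary-class].
#' @param config a [ModelConfig-class] (controls likelihood mode, strata
#'   and which methods contribute).
#' @return scalar log-likelihood (may be `-Inf`).
#' @export
logLikelihood <- function(state, data, config = modelConfig()) {
  stopifnot(is(data, "DetectionSummary"))
  n <- nLocations(data)
  z <- as.numeric(state$z)
  stopifnot(length(z) == n, all(z %in% c(0, 1)))
  sIdx <- if (config@strata == "by_habitat")
    match(data@habitat, HABITATS) else rep(1L, n)
  nS <- if (config@strata == "by_habitat") 2L else 1L
  lambda <- rep_len(as.numeric(state$lambda), nS)[sIdx]

  ll <- 0
  if ("traps" %in% config@methods) {
    Xt <- data@X[, 1:4, drop = FALSE]
    pz <- z * state$p_trap
    obs <- !is.na(Xt)
    ll <- ll + sum(stats::dbinom(Xt[obs], 1L, (pz %o% rep(1, 4))[obs],
                                 log = TRUE))
    if (config@likelihoodMode == "count_offset") {
      obsY <- !is.na(data@Y)
      mu <- (z * lambda / 100) %o% rep(1, 4) * data@E
      ll <- ll + sum(stats::dpois(data@C[obsY], mu[obsY], log = TRUE))
    } else {
      obsY <- !is.na(data@Y)
      mu <- (z * lambda) %o% rep(1, 4)
      ll <- ll + sum(stats::dpois(round(data@Y)[obsY], mu[obsY], log = TRUE))
    }
  }
  if ("pellets" %in% config@methods) {
    Xp <- data@X[, 5:8, drop = FALSE]
    pz <- z * state$p_pellet
    obs <- !is.na(Xp)
    ll <- ll + sum(stats::dbinom(Xp[obs], 1L, (pz %o% rep(1, 4))[obs],
                                 log = TRUE))
  }
  ll
}
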