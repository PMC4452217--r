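#' @include AllClasses.R AllGenerics.R likelihood.R diagnostics.R
NULL

#' Fit the joint occupancy-abundance model by MCMC
#'
#' Gibbs-within-Metropolis sampler for the hierarchical model
#' `z_i ~ Bern(psi)`, `X_ij ~ Bern(z_i p_j)` (detection probability constant
#' within each method), and a zero-inflated Poisson abundance component for
#' the trap-line TCI (see [ModelConfig-class] for the two likelihood
#' readings). Occupancy `psi`, the method detection probabilities and the
#' latent `z_i` have conjugate Beta/Bernoulli full conditionals; `log
#' lambda` is updated by a Gaussian random-walk Metropolis step whose scale
#' is adapted towards 0.44 acceptance during burn-in only and frozen
#' afterwards. Chains start from deterministic, chain-indexed perturbations
#' of a common initial state, and all randomness derives from the config
#' seed, so results are exactly reproducible. The derived mean TCI across
#' all locations, `zlambda = lambda * psi`, is computed draw-by-draw.
#'
#' Non-convergence (any R-hat at or above the configured threshold) is
#' reported through the `converged` flag, never as an error.
#'
#' @param data a [DetectionSummary-class] from [summarizeDetections()].
#' @param config a [ModelConfig-class].
#' @param fixP optional named vector `c(p_trap=, p_pellet=)` holding
#'   detection probabilities fixed (used when cross-validating the sampler
#'   against the enumeration oracle).
#' @param fixLambda optional fixed lambda (scalar or per stratum).
#' @param keepZ keep the full latent-occupancy draws (memory-heavy; meant
#'   for small fixtures).
#' @return a [PosteriorResult-class].
#' @seealso [bruteForcePosterior()], [gelmanRhat()]
#' @export
fitOccAbund <- function(data, config = modelConfig(), fixP = NULL,
                        fixLambda = NULL, keepZ = FALSE) {
  stopifnot(is(data, "DetectionSummary"), is(config, "ModelConfig"))
  validObject(config)
  st <- buildModelStats(data, config)
  chainSeeds <- deriveSeeds(config@seed, config@nChains)
  chains <- lapply(seq_len(config@nChains), function(k) {
    runOccAbundChain(st, config, k, chainSeeds[k], fixP, fixLambda, keepZ)
  })

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config@nChains),
                  each = config@keptIter)
  zTotals <- do.call(rbind, lapply(chains, `[[`, "zTotals"))
  zmat <- if (keepZ) do.call(rbind, lapply(chains, `[[`, "z"))
          else matrix(numeric(), 0L, 0L)

  pars <- colnames(draws)
  rhat <- vapply(pars, function(p) {
    gelmanRhat(vapply(chains, function(ch) ch$draws[, p],
                      numeric(config@keptIter)))
  }, numeric(1))
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, stats::sd)
  meta <- attr(chains[[1]]$draws, "meta")
  summaries <- data.frame(parameter = meta$parameter, stratum = meta$stratum,
                          mean = unname(mu), sd = unname(sdv),
                          ci_lower = qs[1, ], ci_upper = qs[2, ],
                          cv = unname(sdv / mu), rhat = unname(rhat),
                          stringsAsFactors = FALSE)
  rownames(summaries) <- NULL
  converged <- config@nChains >= 2L &&
    all(rhat[is.finite(rhat)] < config@rhatThreshold)
  new("PosteriorResult", draws = draws, chain = as.integer(chain_id),
      summaries = summaries, rhat = rhat, converged = converged,
      zTotals = zTotals, z = zmat, config = config)
}

## Split one user seed into independent sub-seeds (kept below 2^31).
deriveSeeds <- function(seed, k) {
  old <- globalRNGState()
  on.exit(restoreRNGState(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

globalRNGState <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

restoreRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

runOccAbundChain <- function(st, config, chainIndex, chainSeed,
                             fixP = NULL, fixLambda = NULL, keepZ = FALSE) {
  set.seed(chainSeed)
  nS <- length(st$strata)
  count_mode <- config@likelihoodMode == "count_offset"
  aPsi <- config@priorPsi; aP <- config@priorP
  m0 <- config@priorLogLambdaMean; s0 <- config@priorLogLambdaSd

  est_ptrap <- st$use_traps && (is.null(fixP) || is.na(fixP["p_trap"]))
  est_ppel <- st$use_pellets && (is.null(fixP) || is.na(fixP["p_pellet"]))
  est_lambda <- st$use_traps && is.null(fixLambda)

  ## initial state: a common centre, perturbed deterministically per chain
  off <- (chainIndex - 1) * 1.2 * (-1)^chainIndex
  psi <- rep(stats::plogis(0 + off), nS)
  p_trap <- if (st$use_traps && !is.null(fixP) && !is.na(fixP["p_trap"]))
    unname(fixP["p_trap"]) else stats::plogis(0 - off)
  p_pellet <- if (st$use_pellets && !is.null(fixP) && !is.na(fixP["p_pellet"]))
    unname(fixP["p_pellet"]) else stats::plogis(0 - off)
  lambda <- if (!is.null(fixLambda)) rep_len(as.numeric(fixLambda), nS)
            else st$lambdaInit * exp(off / 2)
  z <- as.numeric(st$detAny)
  if (chainIndex > 1)
    z <- pmax(z, stats::rbinom(st$n, 1L, 0.5))

  loglam <- log(lambda)
  step <- rep(0.5, nS)
  acc <- integer(nS); batch <- 0L
  total <- config@burnIn + config@keptIter
  kept <- config@keptIter

  parnames <- c(paste0("psi", strataSuffix(st$strata)),
                if (st$use_traps) "p_trap",
                if (st$use_pellets) "p_pellet",
                if (st$use_traps) paste0("lambda", strataSuffix(st$strata)),
                if (st$use_traps) paste0("zlambda", strataSuffix(st$strata)))
  draws <- matrix(NA_real_, kept, length(parnames),
                  dimnames = list(NULL, parnames))
  zTotals <- matrix(NA_real_, kept, nS,
                    dimnames = list(NULL, st$strata))
  zmat <- if (keepZ) matrix(NA_real_, kept, st$n) else NULL

  for (it in seq_len(total)) {
    ## -- lambda | z (Metropolis on log scale, per stratum)
    if (st$use_traps && est_lambda) {
      for (s in seq_len(nS)) {
        occ <- st$sList[[s]][z[st$sList[[s]]] == 1]
        if (count_mode) {
          Sc <- sum(st$cSum[occ]); Se <- sum(st$eSum[occ])
        } else {
          Sc <- sum(st$yrSum[occ]); Se <- sum(st$nYObs[occ])
        }
        prop <- loglam[s] + stats::rnorm(1, 0, step[s])
        d_rate <- if (count_mode) (exp(prop) - exp(loglam[s])) / 100
                  else exp(prop) - exp(loglam[s])
        logr <- Sc * (prop - loglam[s]) - Se * d_rate +
          stats::dnorm(prop, m0, s0, log = TRUE) -
          stats::dnorm(loglam[s], m0, s0, log = TRUE)
        if (log(stats::runif(1)) < logr) {
          loglam[s] <- prop
          acc[s] <- acc[s] + 1L
        }
      }
      lambda <- exp(loglam)
      ## adapt proposal scale during burn-in only
      if (it <= config@burnIn && it %% 50L == 0L) {
        batch <- batch + 1L
        rate <- acc / 50
        step <- step * exp((rate - 0.44) / sqrt(batch))
        acc[] <- 0L
      }
    }

    ## -- z | psi, p, lambda  (forced 1 on any detection)
    logA <- st$nTrapObs * log1p(-p_trap) + st$nPelObs * log1p(-p_pellet)
    lam_i <- lambda[st$sIdx]
    logA <- logA + if (count_mode) -st$eSum * lam_i / 100
                   else -st$nYObs * lam_i
    A <- exp(logA)
    psi_i <- psi[st$sIdx]
    pr1 <- psi_i * A / (psi_i * A + (1 - psi_i))
    z <- ifelse(st$detAny, 1, stats::rbinom(st$n, 1L, pr1))

    ## -- psi | z (conjugate Beta, per stratum)
    zTot <- vapply(st$sList, function(ix) sum(z[ix]), numeric(1))
    nStr <- lengths(st$sList)
    psi <- stats::rbeta(nS, aPsi[1] + zTot, aPsi[2] + nStr - zTot)

    ## -- p | z (conjugate Beta, occupied locations only)
    if (est_ptrap) {
      det <- sum(st$xTrap[z == 1]); tries <- sum(st$nTrapObs[z == 1])
      p_trap <- stats::rbeta(1, aP[1] + det, aP[2] + tries - det)
    }
    if (est_ppel) {
      det <- sum(st$xPel[z == 1]); tries <- sum(st$nPelObs[z == 1])
      p_pellet <- stats::rbeta(1, aP[1] + det, aP[2] + tries - det)
    }

    if (it > config@burnIn) {
      j <- it - config@burnIn
      row <- psi
      if (st$use_traps) row <- c(row, p_trap)
      if (st$use_pellets) row <- c(row, p_pellet)
      if (st$use_traps) row <- c(row, lambda, lambda * psi)
      draws[j, ] <- row
      zTotals[j, ] <- zTot
      if (keepZ) zmat[j, ] <- z
    }
  }

  param <- c(rep("psi", nS),
             if (st$use_traps) "p_trap", if (st$use_pellets) "p_pellet",
             if (st$use_traps) rep(c("lambda", "zlambda"), each = nS))
  stratum <- c(st$strata,
               if (st$use_traps) "all", if (st$use_pellets) "all",
               if (st$use_traps) rep(st$strata, 2))
  attr(draws, "meta") <- data.frame(parameter = param, stratum = stratum,
                                    stringsAsFactors = FALSE)
  list(draws = draws, zTotals = zTotals, z = zmat)
}

strataSuffix <- function(strata) {
  if (identical(strata, "pooled")) "" else paste0("_", strata)
}

#' @describeIn fitOccAbund combined posterior draws
#' @param x a PosteriorResult
#' @export
setMethod("posteriorDraws", "PosteriorResult", function(x) x@draws)

#' @describeIn fitOccAbund posterior summary table
#' @export
setMethod("posteriorSummary", "PosteriorResult", function(x) x@summaries)

#' @describeIn fitOccAbund convergence flag
#' @export
setMethod("isConverged", "PosteriorResult", function(x) x@converged)

setMethod("show", "PosteriorResult", function(object) {
  cat(sprintf("PosteriorResult: %d draws (%d chain(s)), %s\n",
              nrow(object@draws), max(object@chain),
              if (object@converged) "converged"
              else "NOT converged (check R-hat)"))
  s <- object@summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %-9s mean %8.4f  sd %7.4f  95%% CI [%.4f, %.4f]  CV %5.1f%%  Rhat %.3f\n",
                s$parameter[i], s$stratum[i], s$mean[i], s$sd[i],
                s$ci_lower[i], s$ci_upper[i], 100 * s$cv[i], s$rhat[i]))
})

#' Write posterior summaries to CSV
#'
#' Columns: parameter, stratum, mean, sd, ci_lower, ci_upper, cv, rhat.
#'
#' @param result a [PosteriorResult-class].
#' @param path output path.
#' @param comment optional `#` comment line (e.g. seed / config hash).
#' @return invisibly, the path.
#' @export
writePosteriorCsv <- function(result, path, comment = NULL) {
  stopifnot(is(result, "PosteriorResult"))
  writeCsvWithComment(posteriorSummary(result), path, comment)
  invisible(path)
}
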