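## Shared fixture builders and independent oracles. Everything here is
## deliberately written naively (entry-by-entry loops, closed forms) so it
## cannot share a code path with the package internals it checks.

TRAPLINES <- c("AA", "DD", "MM", "PP")
TRANSECTS <- c("A", "D", "M", "P")

## A full factorial trap table: every line, both nights, zero everything.
fullTrapGrid <- function(ids, nights = 1:2, lines = TRAPLINES) {
  g <- expand.grid(location_id = ids, line_id = lines, night = nights,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$traps_set <- 10L
  g$possum_captures <- 0L
  g$nontarget_captures <- 0L
  g$sprung_empty <- 0L
  g
}

fullPelletGrid <- function(ids, transects = TRANSECTS) {
  g <- expand.grid(location_id = ids, transect_id = transects,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$presence <- 0L
  g
}

makeLocations <- function(ids, habitat = "forest") {
  data.frame(location_id = ids,
             habitat = rep(habitat, length.out = length(ids)),
             stringsAsFactors = FALSE)
}

## Two-location dataset with one capture and one pellet presence.
makeTinyDataset <- function() {
  ids <- c("L1", "L2")
  tr <- fullTrapGrid(ids)
  tr$possum_captures[tr$location_id == "L1" & tr$line_id == "AA" &
                       tr$night == 1] <- 1L
  pe <- fullPelletGrid(ids)
  pe$presence[pe$location_id == "L2" & pe$transect_id == "A"] <- 1L
  SurveyDataset(makeLocations(ids), tr, pe)
}

## Three-location fixture with genuinely uncertain occupancy at two
## locations (reduced effort so the latent state mixes well):
##   L1: detection on trap-line AA (z forced to 1)
##   L2: one trap-line and one transect surveyed, nothing detected
##   L3: two transects surveyed, nothing detected (no trap data)
makeAmbiguousFixture <- function() {
  ids <- c("L1", "L2", "L3")
  tr <- rbind(fullTrapGrid("L1"), fullTrapGrid("L2", lines = "AA"))
  tr$possum_captures[tr$location_id == "L1" & tr$line_id == "AA" &
                       tr$night == 1] <- 2L
  pe <- rbind(fullPelletGrid("L1"),
              fullPelletGrid("L2", transects = "A"),
              fullPelletGrid("L3", transects = c("A", "D")))
  SurveyDataset(makeLocations(ids), tr, pe)
}

## Build a DetectionSummary directly (bypasses record bookkeeping so tests
## can state matrices explicitly).
makeDetSummary <- function(X, Y = NULL, E = NULL, C = NULL,
                           habitat = NULL, nights = "both") {
  n <- nrow(X)
  blank <- matrix(NA_real_, n, 4)
  if (is.null(Y)) Y <- blank
  if (is.null(E)) E <- blank
  if (is.null(C)) C <- blank
  if (is.null(habitat)) habitat <- rep("forest", n)
  if (is.null(rownames(X))) rownames(X) <- paste0("L", seq_len(n))
  new(Class = "DetectionSummary", X = X, Y = Y, E = E, C = C,
      habitat = habitat, nights = nights)
}

## Independent entry-by-entry evaluation of the joint data log-likelihood.
directLogLik <- function(z, p_trap, p_pellet, lambda, X, Y, E, C,
                         mode = "count_offset", habitat = NULL,
                         stratified = FALSE) {
  n <- nrow(X)
  lam <- if (!stratified) rep(lambda[1], n)
         else lambda[match(habitat, c("forest", "nonforest"))]
  ll <- 0
  for (i in seq_len(n)) {
    for (j in 1:8) {
      x <- X[i, j]
      if (is.na(x)) next
      p <- if (j <= 4) p_trap else p_pellet
      prob <- if (x == 1) z[i] * p else 1 - z[i] * p
      ll <- ll + if (prob > 0) log(prob) else -Inf
    }
    for (j in 1:4) {
      if (is.na(Y[i, j])) next
      if (mode == "count_offset") {
        mu <- z[i] * E[i, j] * lam[i] / 100
        k <- C[i, j]
      } else {
        mu <- z[i] * lam[i]
        k <- round(Y[i, j])
      }
      ll <- ll + if (mu == 0) (if (k == 0) 0 else -Inf)
                 else k * log(mu) - mu - lgamma(k + 1)
    }
  }
  ll
}

## Independent noncentral-t power of the equal-n two-sample two-sided test.
directTTestPower <- function(n, delta, sd, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tcrit <- qt(1 - alpha / 2, df)
  1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
}

## Rao-Blackwellised posterior cell masses of pooled psi from a fit:
## average the Beta full conditional over the occupied-count draws.
rbPsiMass <- function(fit, grid, n, priorPsi = c(1, 1)) {
  S <- fit@zTotals[, 1]
  tab <- table(S) / length(S)
  s_vals <- as.numeric(names(tab))
  dens <- numeric(length(grid))
  for (k in seq_along(s_vals))
    dens <- dens + tab[[k]] * dbeta(grid, priorPsi[1] + s_vals[k],
                                    priorPsi[2] + n - s_vals[k])
  dx <- diff(grid)
  w <- c(dx / 2, 0) + c(0, dx / 2)
  m <- dens * w
  m / sum(m)
}

## Short chain settings for desk-scale fits in tests.
quickConfig <- function(..., burnIn = 300L, keptIter = 1500L, seed = 42L) {
  modelConfig(nChains = 2L, burnIn = burnIn, keptIter = keptIter,
              seed = seed, ...)
}
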