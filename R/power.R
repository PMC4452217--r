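#' @include AllClasses.R
NULL

## Power machinery for detecting a change in mean TCI between two survey
## rounds, treated as a two-sided, equal-n, equal-variance two-sample
## t-test (the formulation of stats::power.t.test). The per-location SD of
## TCI is not published; sdFromAnchor() recovers it from a stated
## requirement such as "225 locations give 80% power to detect a change
## from TCI 5.0 to 5.5".

#' Locations per survey round needed to detect a change in mean TCI
#'
#' @param delta absolute change in mean TCI to detect.
#' @param sd per-location standard deviation of TCI.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return smallest integer per-group n achieving the target power.
#' @examples
#' sd <- sdFromAnchor(225, 0.5)
#' requiredN(0.5, sd)  # 225
#' @export
requiredN <- function(delta, sd, alpha = 0.05, power = 0.8) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  res <- stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                             power = power, type = "two.sample",
                             alternative = "two.sided", tol = 1e-10)
  ## tolerance absorbs residual root-finding error so an exact integer
  ## solution is not pushed up a unit
  as.integer(ceiling(res$n - 1e-6))
}

#' Change in mean TCI detectable at a given sample size and power
#'
#' @param n locations per survey round.
#' @param sd per-location standard deviation of TCI.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return absolute TCI change at which the t-test attains the target power.
#' @export
detectableDelta <- function(n, sd, alpha = 0.05, power = 0.8) {
  stopifnot(n >= 2, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  res <- stats::power.t.test(n = n, sd = sd, sig.level = alpha,
                             power = power, type = "two.sample",
                             alternative = "two.sided", tol = 1e-10)
  res$delta
}

#' Recover the TCI standard deviation from a stated power requirement
#'
#' Inverts the two-sample t-test power function: returns the per-location
#' SD at which `n` locations per round give exactly the stated power to
#' detect a change of `delta`.
#'
#' @param n locations per survey round in the anchoring statement.
#' @param delta absolute TCI change in the anchoring statement.
#' @param alpha two-sided significance level.
#' @param power power in the anchoring statement.
#' @return the implied per-location standard deviation of TCI.
#' @examples
#' sdFromAnchor(225, 0.5)  # ~1.89, i.e. CV ~38% of a baseline TCI of 5.0
#' @export
sdFromAnchor <- function(n, delta, alpha = 0.05, power = 0.8) {
  stopifnot(n >= 2, delta > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  res <- stats::power.t.test(n = n, delta = delta, sd = NULL,
                             sig.level = alpha, power = power,
                             type = "two.sample", alternative = "two.sided",
                             tol = 1e-10)
  res$sd
}

#' Detectable-change table over several power levels
#'
#' Reproduces the layout of the monitoring programme's detectable-change
#' table: for each power level, the absolute change in mean TCI detectable
#' at `n` locations per round and that change as a percentage of the
#' baseline TCI.
#'
#' @param n locations per survey round (the programme's forest stratum has
#'   786).
#' @param sd per-location SD of TCI, e.g. from [sdFromAnchor()].
#' @param baselineTci mean TCI at time 1 (default 5.0).
#' @param powers power levels (default 0.80, 0.90, 0.95).
#' @param alpha two-sided significance level.
#' @return data.frame: power, absolute_change, percent_change (of the
#'   baseline), at full precision; round at report time.
#' @export
powerTable <- function(n = 786, sd, baselineTci = 5.0,
                       powers = c(0.80, 0.90, 0.95), alpha = 0.05) {
  stopifnot(baselineTci > 0)
  delta <- vapply(powers, function(pw) detectableDelta(n, sd, alpha, pw),
                  numeric(1))
  data.frame(power = powers, n = n, absolute_change = delta,
             percent_change = 100 * delta / baselineTci)
}
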