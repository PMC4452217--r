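#' @include AllClasses.R AllGenerics.R
NULL

## Trap Catch Index (TCI): possums caught per 100 corrected trap-nights.
## The national protocol subtracts half a trap-night for every trap that was
## unavailable for part of a night: each non-target capture and each sprung-
## but-empty trap.

#' Corrected trap-nights for a trapping effort
#'
#' Raw trap-nights (`traps_set * nights`) minus 0.5 for each non-target
#' capture and each sprung-but-empty trap.
#'
#' @param trapsSet traps set per night.
#' @param nights number of nights the line was run.
#' @param nontarget non-target captures over those nights.
#' @param sprung sprung-but-empty traps over those nights.
#' @return corrected trap-nights (positive scalar or vector).
#' @examples
#' correctedTrapNights(10, 2, 0, 0)  # 20
#' correctedTrapNights(10, 1, 1, 1)  # 9
#' @export
correctedTrapNights <- function(trapsSet, nights, nontarget = 0, sprung = 0) {
  stopifnot(all(trapsSet >= 0), all(nights >= 0),
            all(nontarget >= 0), all(sprung >= 0))
  raw <- trapsSet * nights
  if (any(raw <= 0))
    stop("traps_set x nights must be positive")
  ctn <- raw - 0.5 * (nontarget + sprung)
  if (any(ctn <= 0))
    stop("corrections drive corrected trap-nights to <= 0 (malformed record?)")
  ctn
}

#' Trap Catch Index from captures and corrected trap-nights
#'
#' @param captures possums caught.
#' @param correctedTn corrected trap-nights (> 0).
#' @return TCI on the 0-100 percentage scale.
#' @examples
#' computeTci(2, 39)   # 5.128...
#' computeTci(1, 9.5)  # one night, 10 traps, 1 sprung trap
#' @export
computeTci <- function(captures, correctedTn) {
  stopifnot(all(captures >= 0))
  if (any(correctedTn <= 0)) stop("corrected trap-nights must be positive")
  100 * captures / correctedTn
}

#' Per-line Trap Catch Index table for a survey dataset
#'
#' Aggregates captures and trap-night corrections across the selected nights
#' for each (location, trap-line) before dividing, as the protocol specifies
#' (total catch over total corrected trap-nights, not a per-night average).
#'
#' @param dataset a [SurveyDataset-class].
#' @param nights `"both"` (default) or `"first_only"`.
#' @return data.frame with columns `location_id`, `line_id`, `nights`,
#'   `captures`, `corrected_trap_nights`, `tci`. One row per surveyed line
#'   (lines with no record under the night selection are absent).
#' @export
lineTci <- function(dataset, nights = c("both", "first_only")) {
  stopifnot(is(dataset, "SurveyDataset"))
  nights <- match.arg(nights)
  tr <- trapRecords(dataset)
  if (nights == "first_only") tr <- tr[tr$night == 1L, , drop = FALSE]
  if (!nrow(tr)) {
    return(data.frame(location_id = character(), line_id = character(),
                      nights = character(), captures = integer(),
                      corrected_trap_nights = numeric(), tci = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(tr$location_id, tr$line_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tr, key), function(d) {
    ctn <- tryCatch(
      sum(correctedTrapNights(d$traps_set, 1L, d$nontarget_captures,
                              d$sprung_empty)),
      error = function(e) stop(sprintf(
        "location %s line %s: %s", d$location_id[1], d$line_id[1],
        conditionMessage(e)), call. = FALSE))
    data.frame(location_id = d$location_id[1], line_id = d$line_id[1],
               nights = nights, captures = sum(d$possum_captures),
               corrected_trap_nights = ctn,
               tci = computeTci(sum(d$possum_captures), ctn),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$location_id, match(agg$line_id, TRAP_LINES)), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
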