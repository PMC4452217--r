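#' @include AllClasses.R
NULL

## Monitoring cost model. All money is handled in integer cents so reported
## totals are exact to the cent; display rounding is half-up.

#' Create a CostSchedule
#'
#' Defaults are the programme's published 2013 NZD rates; see
#' [CostSchedule-class].
#'
#' @param vehiclePerLocation,helicopterPerLocation,equipmentPerLocation
#'   fixed per-location costs (NZD).
#' @param labourRate NZD per person-hour.
#' @param allowancePerPersonDay,foodPerPersonDay NZD per person-day.
#' @param crewSize persons per team.
#' @param hoursPerDay,daysOnSite named `c(two_night=, one_night=)`.
#' @param locationsPerYear sampling locations measured annually.
#' @param seasonDays potential field days in a season.
#' @param weatherLossFraction proportion of days lost to weather.
#' @return a [CostSchedule-class].
#' @export
costSchedule <- function(vehiclePerLocation = 498.00,
                         helicopterPerLocation = 2445.00,
                         equipmentPerLocation = 335.00,
                         labourRate = 22.50,
                         allowancePerPersonDay = 21.00,
                         foodPerPersonDay = 22.61,
                         crewSize = 2L,
                         hoursPerDay = c(two_night = 8, one_night = 10),
                         daysOnSite = c(two_night = 3, one_night = 2),
                         locationsPerYear = 271L,
                         seasonDays = 172L,
                         weatherLossFraction = 0.30) {
  new("CostSchedule", vehiclePerLocation = vehiclePerLocation,
      helicopterPerLocation = helicopterPerLocation,
      equipmentPerLocation = equipmentPerLocation, labourRate = labourRate,
      allowancePerPersonDay = allowancePerPersonDay,
      foodPerPersonDay = foodPerPersonDay, crewSize = as.integer(crewSize),
      hoursPerDay = hoursPerDay, daysOnSite = daysOnSite,
      locationsPerYear = as.integer(locationsPerYear),
      seasonDays = as.integer(seasonDays),
      weatherLossFraction = weatherLossFraction)
}

setMethod("show", "CostSchedule", function(object) {
  cat("CostSchedule (NZD):\n")
  cat(sprintf("  fixed/location: transport %s + equipment %s\n",
              formatMoney(object@vehiclePerLocation +
                            object@helicopterPerLocation),
              formatMoney(object@equipmentPerLocation)))
  cat(sprintf("  labour %s/h, allowance %s, food %s per person-day, crew %d\n",
              formatMoney(object@labourRate),
              formatMoney(object@allowancePerPersonDay),
              formatMoney(object@foodPerPersonDay), object@crewSize))
  cat(sprintf("  %d locations/yr, %d-day season, %.0f%% weather loss\n",
              object@locationsPerYear, object@seasonDays,
              100 * object@weatherLossFraction))
})

## exact cents; half-up rounding for rates that do not land on a cent
toCents <- function(x) round(x * 100)

roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format NZD amounts with thousands separators
#' @param x numeric dollars
#' @return character, e.g. `"$4,619.66"`
#' @export
formatMoney <- function(x) {
  paste0(ifelse(x < 0, "-$", "$"),
         formatC(abs(roundHalfUp(x, 2)), format = "f", digits = 2,
                 big.mark = ","))
}

#' Per-location monitoring cost under a trapping regime
#'
#' Fixed costs (transport + equipment) do not depend on the number of
#' nights; variable costs are labour (`rate x crew x hours/day x days`) plus
#' allowance and food (`rate x crew x days`).
#'
#' @param schedule a [CostSchedule-class].
#' @param regime `"two_night"` or `"one_night"`.
#' @return data.frame with one row per line item (`transport`, `equipment`,
#'   `labour`, `allowance`, `food`, plus `fixed`, `variable` and `total`
#'   subtotals), `units` describing the quantity, and exact NZD `cost`.
#' @export
costPerLocation <- function(schedule = costSchedule(),
                            regime = c("two_night", "one_night")) {
  stopifnot(is(schedule, "CostSchedule"))
  validObject(schedule)
  regime <- match.arg(regime)
  days <- schedule@daysOnSite[regime]
  hours <- schedule@hoursPerDay[regime]
  crew <- schedule@crewSize

  transport_c <- toCents(schedule@vehiclePerLocation) +
    toCents(schedule@helicopterPerLocation)
  equipment_c <- toCents(schedule@equipmentPerLocation)
  labour_hours <- crew * hours * days
  labour_c <- toCents(schedule@labourRate) * labour_hours
  person_days <- crew * days
  allowance_c <- toCents(schedule@allowancePerPersonDay) * person_days
  food_c <- toCents(schedule@foodPerPersonDay) * person_days
  fixed_c <- transport_c + equipment_c
  variable_c <- labour_c + allowance_c + food_c

  data.frame(
    item = c("transport", "equipment", "labour", "allowance", "food",
             "fixed", "variable", "total"),
    units = c("1 location", "1 location",
              sprintf("%d x %g h x %g d = %g h", crew, hours, days,
                      labour_hours),
              sprintf("%d x %g d = %g person-days", crew, days, person_days),
              sprintf("%d x %g d = %g person-days", crew, days, person_days),
              "", "", ""),
    cost = c(transport_c, equipment_c, labour_c, allowance_c, food_c,
             fixed_c, variable_c, fixed_c + variable_c) / 100,
    stringsAsFactors = FALSE)
}

#' Annual monitoring plan: field days, teams and the one-night saving
#'
#' Field days are `locations x days on site` per regime; a team has
#' `floor(seasonDays x (1 - weatherLossFraction))` workable days, and the
#' number of teams is the ceiling of field days over workable days. The
#' annual saving from one-night trapping is `locations x (two-night total -
#' one-night total)` — a difference of variable costs only, invariant to
#' the transport and equipment rates.
#'
#' @param schedule a [CostSchedule-class].
#' @return list with `per_location` (cost tables per regime and the
#'   per-location saving), `field_days`, `available_days_per_team`,
#'   `teams`, `annual_total` per regime, `annual_saving` and
#'   `annual_saving_rounded_100`.
#' @export
annualPlan <- function(schedule = costSchedule()) {
  stopifnot(is(schedule, "CostSchedule"))
  validObject(schedule)
  two <- costPerLocation(schedule, "two_night")
  one <- costPerLocation(schedule, "one_night")
  total2 <- two$cost[two$item == "total"]
  total1 <- one$cost[one$item == "total"]
  nloc <- schedule@locationsPerYear
  available <- floor(schedule@seasonDays * (1 - schedule@weatherLossFraction))
  if (available <= 0) stop("no workable field days after weather loss")
  field_days <- c(two_night = nloc * unname(schedule@daysOnSite["two_night"]),
                  one_night = nloc * unname(schedule@daysOnSite["one_night"]))
  teams <- ceiling(field_days / available)
  saving_per_loc <- total2 - total1
  annual_saving <- nloc * saving_per_loc
  list(per_location = list(two_night = two, one_night = one,
                           saving = saving_per_loc,
                           saving_percent = 100 * saving_per_loc / total2),
       field_days = field_days,
       available_days_per_team = available,
       teams = teams,
       annual_total = c(two_night = nloc * total2, one_night = nloc * total1),
       annual_saving = annual_saving,
       annual_saving_rounded_100 = roundHalfUp(annual_saving / 100) * 100)
}

#' Render a cost comparison table as aligned text
#'
#' @param schedule a [CostSchedule-class].
#' @return character vector of report lines (also printed invisibly usable
#'   with `writeLines()`).
#' @export
formatCostTable <- function(schedule = costSchedule()) {
  two <- costPerLocation(schedule, "two_night")
  one <- costPerLocation(schedule, "one_night")
  rows <- c("transport", "equipment", "labour", "allowance", "food", "total")
  lines <- sprintf("%-12s %-24s %12s %-24s %12s",
                   "Item", "Units (two nights)", "Cost",
                   "Units (one night)", "Cost")
  for (r in rows) {
    i2 <- two[two$item == r, ]; i1 <- one[one$item == r, ]
    lines <- c(lines, sprintf("%-12s %-24s %12s %-24s %12s",
                              r, i2$units, formatMoney(i2$cost),
                              i1$units, formatMoney(i1$cost)))
  }
  lines
}
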