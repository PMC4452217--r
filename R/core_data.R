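#' @include AllClasses.R AllGenerics.R tci.R
NULL

#' Construct a SurveyDataset
#'
#' @param locations data.frame with `location_id`, `habitat`.
#' @param traps data.frame of trap-line records (may be empty).
#' @param pellets data.frame of pellet-transect records with either a
#'   `presence` bit or `plot_01..plot_NN` columns, which are collapsed to the
#'   transect-level presence bit the model consumes.
#' @return a validated [SurveyDataset-class]; records are stored in canonical
#'   order (location, then line/transect, then night).
#' @export
SurveyDataset <- function(locations, traps = emptyTrapFrame(),
                          pellets = emptyPelletFrame()) {
  locations <- as.data.frame(locations, stringsAsFactors = FALSE)
  traps <- as.data.frame(traps, stringsAsFactors = FALSE)
  pellets <- collapsePelletPlots(as.data.frame(pellets,
                                               stringsAsFactors = FALSE))
  locations$location_id <- as.character(locations$location_id)
  locations <- locations[order(locations$location_id), , drop = FALSE]
  rownames(locations) <- NULL
  if (nrow(traps)) {
    traps$location_id <- as.character(traps$location_id)
    traps$night <- as.integer(traps$night)
    for (nm in c("traps_set", "possum_captures", "nontarget_captures",
                 "sprung_empty"))
      traps[[nm]] <- as.integer(traps[[nm]])
    traps <- traps[order(traps$location_id, match(traps$line_id, TRAP_LINES),
                         traps$night), , drop = FALSE]
    rownames(traps) <- NULL
  }
  if (nrow(pellets)) {
    pellets$location_id <- as.character(pellets$location_id)
    pellets$presence <- as.integer(pellets$presence)
    pellets <- pellets[order(pellets$location_id,
                             match(pellets$transect_id, PELLET_TRANSECTS)), ,
                       drop = FALSE]
    rownames(pellets) <- NULL
  }
  keep_tr <- c("location_id", "line_id", "night", "traps_set",
               "possum_captures", "nontarget_captures", "sprung_empty")
  keep_pe <- c("location_id", "transect_id", "presence")
  new("SurveyDataset",
      locations = locations[c("location_id", "habitat")],
      traps = if (nrow(traps)) traps[keep_tr] else emptyTrapFrame(),
      pellets = if (nrow(pellets)) pellets[keep_pe] else emptyPelletFrame())
}

emptyTrapFrame <- function() {
  data.frame(location_id = character(), line_id = character(),
             night = integer(), traps_set = integer(),
             possum_captures = integer(), nontarget_captures = integer(),
             sprung_empty = integer(), stringsAsFactors = FALSE)
}

emptyPelletFrame <- function() {
  data.frame(location_id = character(), transect_id = character(),
             presence = integer(), stringsAsFactors = FALSE)
}

## Accept plot-level pellet rows (plot_01..plot_NN) and collapse to the
## transect presence bit; the model only ever consumes transect presence.
collapsePelletPlots <- function(pe) {
  plot_cols <- grep("^plot_[0-9]+$", names(pe), value = TRUE)
  if (length(plot_cols)) {
    if (length(plot_cols) != 30L)
      stop(sprintf("expected 30 plot columns, found %d", length(plot_cols)))
    bits <- as.matrix(pe[plot_cols])
    if (any(!bits %in% c(0L, 1L)))
      stop("pellet plot flags must be 0/1")
    pe$presence <- as.integer(rowSums(bits) > 0)
  } else if (!"presence" %in% names(pe) && "transect_presence" %in% names(pe)) {
    pe$presence <- as.integer(pe$transect_presence)
  }
  pe
}

#' @describeIn SurveyDataset number of sampling locations
#' @param x a SurveyDataset
#' @export
setMethod("nLocations", "SurveyDataset", function(x) nrow(x@locations))

#' @describeIn SurveyDataset location identifiers
#' @export
setMethod("locationIds", "SurveyDataset", function(x) x@locations$location_id)

#' @describeIn SurveyDataset habitat labels, named by location id
#' @export
setMethod("habitats", "SurveyDataset", function(x) {
  stats::setNames(x@locations$habitat, x@locations$location_id)
})

#' @describeIn SurveyDataset trap-line records
#' @export
setMethod("trapRecords", "SurveyDataset", function(x) x@traps)

#' @describeIn SurveyDataset pellet-transect records
#' @export
setMethod("pelletRecords", "SurveyDataset", function(x) x@pellets)

#' @describeIn SurveyDataset logical n x 8 matrix of surveyed units
#' @export
setMethod("surveyedMask", "SurveyDataset", function(x) {
  ids <- locationIds(x)
  m <- matrix(FALSE, length(ids), 8L,
              dimnames = list(ids, UNIT_COLUMNS))
  tr <- x@traps
  if (nrow(tr))
    m[cbind(match(tr$location_id, ids), match(tr$line_id, TRAP_LINES))] <- TRUE
  pe <- x@pellets
  if (nrow(pe))
    m[cbind(match(pe$location_id, ids),
            4L + match(pe$transect_id, PELLET_TRANSECTS))] <- TRUE
  m
})

setMethod("show", "SurveyDataset", function(object) {
  mask <- surveyedMask(object)
  complete <- if (nrow(mask)) mean(rowSums(mask) == 8L) else NA_real_
  cat("SurveyDataset with", nLocations(object), "sampling locations (",
      sum(object@locations$habitat == "forest"), "forest,",
      sum(object@locations$habitat == "nonforest"), "non-forest )\n")
  cat("  trap records:   ", nrow(object@traps), "\n")
  cat("  pellet records: ", nrow(object@pellets), "\n")
  if (!is.na(complete))
    cat(sprintf("  %.0f%% of locations have all 8 units surveyed\n",
                100 * complete))
})

#' Read survey tables from the canonical CSV pair
#'
#' The traps file has one row per (location, line, night) with header
#' `location_id,habitat,line_id,night,traps_set,possum_captures,`
#' `nontarget_captures,sprung_empty`; the pellets file one row per
#' (location, transect) with header `location_id,habitat,transect_id` plus
#' either `transect_presence` or `plot_01..plot_30`. Lines that were not
#' surveyed simply have no row and are reported by [surveyedMask()]. Rows
#' violating the record invariants are rejected with row-level diagnostics.
#' Lines starting with `#` are ignored.
#'
#' @param trapsPath,pelletsPath paths to the two CSV files.
#' @return a validated [SurveyDataset-class].
#' @export
readSurveyCsv <- function(trapsPath, pelletsPath) {
  tr <- utils::read.csv(trapsPath, stringsAsFactors = FALSE,
                        comment.char = "#")
  pe <- utils::read.csv(pelletsPath, stringsAsFactors = FALSE,
                        comment.char = "#")
  need_tr <- c("location_id", "habitat", "line_id", "night", "traps_set",
               "possum_captures", "nontarget_captures", "sprung_empty")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss))
    stop("traps file missing column(s): ", paste(miss, collapse = ", "))
  need_pe <- c("location_id", "habitat", "transect_id")
  miss <- setdiff(need_pe, names(pe))
  if (length(miss))
    stop("pellets file missing column(s): ", paste(miss, collapse = ", "))
  if (!any(c("transect_presence", "presence") %in% names(pe)) &&
      !any(grepl("^plot_[0-9]+$", names(pe))))
    stop("pellets file needs transect_presence or plot_01..plot_30 columns")

  ## row-level validation before assembly, so errors name the input rows
  bad <- which(with(tr, possum_captures + nontarget_captures + sprung_empty >
                      traps_set))
  if (length(bad))
    stop(sprintf(
      "traps file row(s) %s: captures + non-target + sprung exceed traps_set",
      paste(bad, collapse = ", ")))
  bad <- which(!tr$night %in% c(1, 2))
  if (length(bad))
    stop(sprintf("traps file row(s) %s: night must be 1 or 2",
                 paste(bad, collapse = ", ")))

  hab <- rbind(
    data.frame(location_id = as.character(tr$location_id),
               habitat = tr$habitat, stringsAsFactors = FALSE),
    data.frame(location_id = as.character(pe$location_id),
               habitat = pe$habitat, stringsAsFactors = FALSE))
  hab <- unique(hab)
  if (anyDuplicated(hab$location_id))
    stop("conflicting habitat labels for location(s): ",
         paste(unique(hab$location_id[duplicated(hab$location_id)]),
               collapse = ", "))
  SurveyDataset(locations = hab, traps = tr, pellets = pe)
}

#' Write a survey dataset to the canonical CSV pair
#'
#' Inverse of [readSurveyCsv()]: `readSurveyCsv()` on the written pair
#' reproduces the dataset exactly (pellet data are written at transect
#' level). Unsurveyed lines produce no rows, so the surveyed mask survives
#' the round trip.
#'
#' @param dataset a [SurveyDataset-class].
#' @param trapsPath,pelletsPath output paths.
#' @param comment optional comment line (written prefixed with `#`).
#' @return invisibly, the two paths.
#' @export
writeSurveyCsv <- function(dataset, trapsPath, pelletsPath, comment = NULL) {
  stopifnot(is(dataset, "SurveyDataset"))
  hab <- habitats(dataset)
  tr <- trapRecords(dataset)
  tr_out <- cbind(tr[, "location_id", drop = FALSE],
                  habitat = unname(hab[tr$location_id]),
                  tr[, setdiff(names(tr), "location_id"), drop = FALSE])
  pe <- pelletRecords(dataset)
  pe_out <- data.frame(location_id = pe$location_id,
                       habitat = unname(hab[pe$location_id]),
                       transect_id = pe$transect_id,
                       transect_presence = pe$presence,
                       stringsAsFactors = FALSE)
  writeCsvWithComment(tr_out, trapsPath, comment)
  writeCsvWithComment(pe_out, pelletsPath, comment)
  invisible(c(traps = trapsPath, pellets = pelletsPath))
}

writeCsvWithComment <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Assemble model-ready detection matrices from a survey dataset
#'
#' Builds the location x 8 detection matrix `X` (j = 1-4 trap-lines AA, DD,
#' MM, PP; j = 5-8 pellet transects A, D, M, P), the per-line TCI matrix `Y`,
#' its corrected trap-night denominators `E`, and raw capture counts `C`.
#' With `nights = "first_only"` only night-1 trap records enter `Y`, `E`,
#' `C` and the trap columns of `X`; pellet columns are unaffected by the
#' night selection. Unsurveyed units are `NA`. Locations with no surveyed
#' units at all are dropped with a warning.
#'
#' @param dataset a [SurveyDataset-class].
#' @param nights `"both"` (default) or `"first_only"`.
#' @return a [DetectionSummary-class].
#' @export
summarizeDetections <- function(dataset, nights = c("both", "first_only")) {
  stopifnot(is(dataset, "SurveyDataset"))
  nights <- match.arg(nights)
  ids <- locationIds(dataset)
  n <- length(ids)
  X <- matrix(NA_real_, n, 8L, dimnames = list(ids, UNIT_COLUMNS))
  Y <- E <- C <- matrix(NA_real_, n, 4L, dimnames = list(ids, TRAP_LINES))

  tl <- lineTci(dataset, nights = nights)
  if (nrow(tl)) {
    idx <- cbind(match(tl$location_id, ids), match(tl$line_id, TRAP_LINES))
    C[idx] <- tl$captures
    E[idx] <- tl$corrected_trap_nights
    Y[idx] <- tl$tci
    X[, 1:4][idx] <- as.numeric(tl$captures > 0)
  }
  pe <- pelletRecords(dataset)
  if (nrow(pe)) {
    X[cbind(match(pe$location_id, ids),
            4L + match(pe$transect_id, PELLET_TRANSECTS))] <- pe$presence
  }
  empty <- rowSums(!is.na(X)) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d location(s) with no surveyed units: %s",
                    sum(empty), paste(ids[empty], collapse = ", ")))
    keep <- !empty
    X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
    E <- E[keep, , drop = FALSE]; C <- C[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  ## Class= named explicitly: a slot named C would otherwise partially
  ## match new()'s Class argument
  new(Class = "DetectionSummary", X = X, Y = Y, E = E, C = C,
      habitat = unname(habitats(dataset)[ids]), nights = nights)
}

#' @describeIn summarizeDetections number of (retained) locations
#' @param x a DetectionSummary
#' @export
setMethod("nLocations", "DetectionSummary", function(x) nrow(x@X))

#' @describeIn summarizeDetections location identifiers
#' @export
setMethod("locationIds", "DetectionSummary", function(x) rownames(x@X))

#' @describeIn summarizeDetections habitat labels
#' @export
setMethod("habitats", "DetectionSummary", function(x) {
  stats::setNames(x@habitat, rownames(x@X))
})

setMethod("show", "DetectionSummary", function(object) {
  cat("DetectionSummary:", nrow(object@X), "locations, nights =",
      object@nights, "\n")
  det <- rowSums(object@X == 1, na.rm = TRUE) > 0
  cat(sprintf("  naive detection at %.0f%% of locations\n", 100 * mean(det)))
  ytot <- suppressWarnings(mean(rowMeans(object@Y, na.rm = TRUE), na.rm = TRUE))
  if (is.finite(ytot))
    cat(sprintf("  mean per-location TCI (surveyed lines): %.2f\n", ytot))
})
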