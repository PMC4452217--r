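#' @include AllClasses.R
NULL

#' Number of sampling locations in an object
#' @param x a [SurveyDataset-class] or [DetectionSummary-class]
#' @return integer count
#' @export
setGeneric("nLocations", function(x) standardGeneric("nLocations"))

#' Sampling-location identifiers
#' @param x a [SurveyDataset-class] or [DetectionSummary-class]
#' @return character vector of location ids
#' @export
setGeneric("locationIds", function(x) standardGeneric("locationIds"))

#' Per-location habitat labels
#' @param x a [SurveyDataset-class] or [DetectionSummary-class]
#' @return character vector, values `"forest"`/`"nonforest"`
#' @export
setGeneric("habitats", function(x) standardGeneric("habitats"))

#' Trap-line records
#' @param x a [SurveyDataset-class]
#' @return data.frame of (location, line, night) trap records
#' @export
setGeneric("trapRecords", function(x) standardGeneric("trapRecords"))

#' Pellet-transect records
#' @param x a [SurveyDataset-class]
#' @return data.frame of (location, transect) presence records
#' @export
setGeneric("pelletRecords", function(x) standardGeneric("pelletRecords"))

#' Which of the 8 detection units were surveyed at each location
#'
#' @param x a [SurveyDataset-class]
#' @return n x 8 logical matrix (columns AA, DD, MM, PP, A, D, M, P);
#'   `FALSE` marks a unit with no survey record.
#' @export
setGeneric("surveyedMask", function(x) standardGeneric("surveyedMask"))

#' Combined posterior draws
#' @param x a [PosteriorResult-class]
#' @return matrix of draws, one column per parameter
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Posterior summary table
#' @param x a [PosteriorResult-class]
#' @return data.frame with mean, sd, 95% credible interval, CV and R-hat
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' Did all parameters pass the R-hat convergence threshold?
#' @param x a [PosteriorResult-class]
#' @return logical flag
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
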