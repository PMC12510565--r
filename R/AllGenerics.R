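#' @include hazecast-package.R
NULL

#' City identifiers of a panel
#'
#' @param x an object holding multi-city data.
#' @return Character vector of city identifiers, in the fixed panel order.
#' @export
setGeneric("cities", function(x) standardGeneric("cities"))

#' Hourly timestamps of a panel
#'
#' @param x an object holding hourly data.
#' @return `POSIXct` vector of strictly increasing hourly instants.
#' @export
setGeneric("hourlyTimes", function(x) standardGeneric("hourlyTimes"))

#' Variables stored in a panel
#'
#' @param x an object holding multi-variable data.
#' @return Character vector of variable names (always includes `"PM25"`).
#' @export
setGeneric("panelVariables", function(x) standardGeneric("panelVariables"))

#' Extract one variable of a panel as a city-by-time matrix
#'
#' @param x an [HourlyPanel-class] object.
#' @param variable variable name, e.g. `"PM25"`.
#' @return Numeric matrix, rows = cities, columns = hours; `NA` marks
#'   missing observations.
#' @export
setGeneric("panelMatrix", function(x, variable = "PM25")
  standardGeneric("panelMatrix"))
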