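#' @include AllGenerics.R
NULL

#' HourlyPanel: a multi-city hourly air-quality panel
#'
#' An `HourlyPanel` is a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are cities, whose columns are consecutive hourly instants,
#' and whose assays are the measured variables (one city-by-time matrix
#' per variable; `"PM25"` is mandatory). Missing observations are `NA`.
#' Timestamps are timezone-naive local standard time, stored as UTC
#' `POSIXct` so that no daylight-saving shifts are ever applied.
#'
#' Validity requires: a `PM25` assay; strictly increasing timestamps at
#' exactly one-hour spacing with no duplicates; and no negative
#' non-missing values for concentration-like variables (pollutants,
#' relative humidity, rain, wind).
#'
#' @seealso [HourlyPanel()], [readHourlyPanel()], [simulateRegion()]
#' @aliases HourlyPanel-class
#' @export
setClass("HourlyPanel", contains = "SummarizedExperiment")

setValidity("HourlyPanel", function(object) {
  msg <- character()
  if (!"PM25" %in% assayNames(object))
    msg <- c(msg, "panel must contain a 'PM25' assay")
  tm <- colData(object)$time
  if (is.null(tm)) {
    msg <- c(msg, "colData must contain a 'time' column of POSIXct instants")
  } else {
    dt <- diff(as.numeric(tm))
    if (length(dt) && any(dt != 3600))
      msg <- c(msg, "timestamps must be strictly increasing at 1-hour spacing")
  }
  if (!isTRUE(metadata(object)$normalized)) {
    # measurement-scale panels: concentrations cannot be negative
    # (normalized panels may hold out-of-fit-range values below 0)
    for (v in intersect(assayNames(object), .CONC_VARS)) {
      a <- assay(object, v)
      if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("non-missing values of '%s' must be >= 0", v))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an HourlyPanel
#'
#' @param values either a named list of city-by-time matrices (one per
#'   variable) or a 3-d array indexed `[city, time, variable]` with a
#'   dimnames entry for variables.
#' @param timestamps `POSIXct` vector (or anything coercible via
#'   [as.POSIXct()] with `tz = "UTC"`) of hourly instants, one per column.
#' @param cities character vector of city identifiers, one per row.
#' @return A validated [HourlyPanel-class] object.
#' @examples
#' tm <- seq(as.POSIXct("2023-01-01", tz = "UTC"), by = "hour", length.out = 4)
#' pm <- matrix(10 + 1:8, nrow = 2, dimnames = list(c("A", "B"), NULL))
#' p <- HourlyPanel(list(PM25 = pm), tm, c("A", "B"))
#' cities(p)
#' @export
HourlyPanel <- function(values, timestamps, cities) {
  if (is.array(values) && length(dim(values)) == 3L) {
    vars <- dimnames(values)[[3]]
    if (is.null(vars)) stop("3-d 'values' needs variable dimnames")
    values <- setNames(lapply(vars, function(v) values[, , v, drop = TRUE]),
                       vars)
    values <- lapply(values, function(m) {
      if (is.null(dim(m))) m <- matrix(m, nrow = length(cities))
      m
    })
  }
  if (!is.list(values) || is.null(names(values)))
    stop("'values' must be a named list of matrices or a named 3-d array")
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  values <- lapply(values, function(m) {
    dimnames(m) <- list(cities, NULL)
    m
  })
  se <- SummarizedExperiment(
    assays = values,
    rowData = DataFrame(city = cities, row.names = cities),
    colData = DataFrame(time = timestamps)
  )
  new("HourlyPanel", se)
}

#' @rdname cities
#' @export
setMethod("cities", "HourlyPanel", function(x) rownames(x))

#' @rdname hourlyTimes
#' @export
setMethod("hourlyTimes", "HourlyPanel", function(x) colData(x)$time)

#' @rdname panelVariables
#' @export
setMethod("panelVariables", "HourlyPanel", function(x) assayNames(x))

#' @rdname panelMatrix
#' @export
setMethod("panelMatrix", "HourlyPanel", function(x, variable = "PM25") {
  if (!variable %in% assayNames(x))
    stop(sprintf("variable '%s' not present in panel", variable))
  assay(x, variable)
})

#' Missingness mask of a panel
#'
#' @param x an [HourlyPanel-class].
#' @return Named list of logical city-by-time matrices, `TRUE` where the
#'   observation is missing.
#' @export
missingMask <- function(x) {
  stopifnot(is(x, "HourlyPanel"))
  lapply(setNames(assayNames(x), assayNames(x)),
         function(v) is.na(assay(x, v)))
}

#' Panel values as a 3-d array
#'
#' @param x an [HourlyPanel-class].
#' @return Numeric array `[city, time, variable]`.
#' @export
panelArray <- function(x) {
  stopifnot(is(x, "HourlyPanel"))
  vars <- assayNames(x)
  arr <- array(NA_real_, c(nrow(x), ncol(x), length(vars)),
               dimnames = list(cities(x), NULL, vars))
  for (v in vars) arr[, , v] <- assay(x, v)
  arr
}

setMethod("show", "HourlyPanel", function(object) {
  tm <- hourlyTimes(object)
  cat(sprintf(
    "HourlyPanel: %d cities x %d hours x %d variables\n",
    nrow(object), ncol(object), length(assayNames(object))))
  if (length(tm))
    cat(sprintf("  time: %s .. %s\n", format(tm[1]), format(tm[length(tm)])))
  cat("  variables:", paste(assayNames(object), collapse = ", "), "\n")
  nmiss <- sum(vapply(missingMask(object), sum, 0L))
  cat(sprintf("  missing cells: %d\n", nmiss))
  invisible(NULL)
})

# replace assays wholesale, keeping metadata / dims
.withAssays <- function(panel, newAssays) {
  HourlyPanel(newAssays, hourlyTimes(panel), cities(panel))
}
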