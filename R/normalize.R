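#' @include hourly-panel.R
NULL

#' MinMaxScaler: per-series min-max normalization parameters
#'
#' Holds, for every (city, variable) series, the extremes `xmin` and
#' `xmax` observed in the fitting window. Normalization maps `x` to
#' `(x - xmin) / (xmax - xmin)`, so values inside the fitting window
#' land in `[0, 1]`; values outside it may fall outside that range and
#' are deliberately not clipped.
#'
#' @aliases MinMaxScaler-class
#' @export
setClass("MinMaxScaler",
         representation(table = "data.frame"),
         validity = function(object) {
           tb <- object@table
           need <- c("city", "variable", "xmin", "xmax")
           if (!all(need %in% names(tb)))
             return("scaler table needs columns city, variable, xmin, xmax")
           if (any(tb$xmax < tb$xmin)) return("xmax must be >= xmin")
           TRUE
         })

setMethod("show", "MinMaxScaler", function(object) {
  tb <- object@table
  cat(sprintf("MinMaxScaler: %d series (%d cities x %d variables)\n",
              nrow(tb), length(unique(tb$city)),
              length(unique(tb$variable))))
  invisible(NULL)
})

.scalerKey <- function(city, variable) paste(city, variable, sep = "\r")

.scalerLookup <- function(scaler, city, variable) {
  tb <- scaler@table
  i <- match(.scalerKey(city, variable), .scalerKey(tb$city, tb$variable))
  if (anyNA(i))
    stop(sprintf("scaler has no entry for city '%s', variable '%s'",
                 city[which(is.na(i))[1]], variable))
  tb[i, , drop = FALSE]
}

#' Fit min-max normalization parameters
#'
#' Extremes are taken per (city, variable) within `fitRange` only, so a
#' scaler fitted on the training period is immune to leakage from later
#' data. A constant series is an error: the normalization denominator
#' would vanish.
#'
#' @param panel an imputed [HourlyPanel-class].
#' @param fitRange `NULL` for the whole panel, or a length-2 `POSIXct`
#'   (or coercible) giving the inclusive time interval to fit on.
#' @return A [MinMaxScaler-class].
#' @export
fitMinMax <- function(panel, fitRange = NULL) {
  stopifnot(is(panel, "HourlyPanel"))
  tm <- hourlyTimes(panel)
  sel <- if (is.null(fitRange)) rep(TRUE, length(tm)) else {
    fr <- as.POSIXct(fitRange, tz = "UTC")
    tm >= fr[1] & tm <= fr[2]
  }
  if (!any(sel)) stop("empty fitting range")
  rows <- list()
  for (v in panelVariables(panel)) {
    m <- panelMatrix(panel, v)[, sel, drop = FALSE]
    mn <- apply(m, 1, min, na.rm = TRUE)
    mx <- apply(m, 1, max, na.rm = TRUE)
    if (any(mx == mn)) {
      ci <- which(mx == mn)[1]
      stop(sprintf(
        "constant series in fitting range (city '%s', variable '%s'): min-max normalization undefined",
        cities(panel)[ci], v))
    }
    rows[[v]] <- data.frame(city = cities(panel), variable = v,
                            xmin = mn, xmax = mx,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  new("MinMaxScaler", table = do.call(rbind, rows))
}

#' Normalize a panel with a fitted scaler
#'
#' @param panel an [HourlyPanel-class] covering only (city, variable)
#'   pairs known to the scaler.
#' @param scaler a [MinMaxScaler-class].
#' @param warnOutOfRange warn when normalized values fall outside
#'   `[0, 1]` (they are preserved, not clipped).
#' @return The normalized panel (plain `SummarizedExperiment` semantics
#'   preserved; concentrations are no longer on the µg/m³ scale, so the
#'   nonnegativity validity check is bypassed by storing normalized
#'   values as-is — they are nonnegative inside the fit range anyway).
#' @export
applyMinMax <- function(panel, scaler, warnOutOfRange = TRUE) {
  stopifnot(is(panel, "HourlyPanel"), is(scaler, "MinMaxScaler"))
  out <- list()
  nOut <- 0L
  for (v in panelVariables(panel)) {
    m <- panelMatrix(panel, v)
    e <- .scalerLookup(scaler, cities(panel), v)
    m2 <- (m - e$xmin) / (e$xmax - e$xmin)
    nOut <- nOut + sum(m2 < 0 | m2 > 1, na.rm = TRUE)
    out[[v]] <- m2
  }
  if (warnOutOfRange && nOut > 0)
    warning(sprintf(
      "%d normalized values fall outside [0, 1] (outside the fit range); preserved unclipped",
      nOut))
  se <- SummarizedExperiment(
    assays = out,
    rowData = DataFrame(city = cities(panel), row.names = cities(panel)),
    colData = DataFrame(time = hourlyTimes(panel)),
    metadata = list(normalized = TRUE))
  new("HourlyPanel", se)
}

#' Invert min-max normalization
#'
#' @param values numeric vector or matrix of normalized values. For a
#'   matrix, columns correspond to `city` (one per column); for a
#'   vector, `city` must be a single identifier.
#' @param scaler a [MinMaxScaler-class].
#' @param city city identifier(s) matching the columns of `values`.
#' @param variable variable name (default `"PM25"`).
#' @return Values on the original measurement scale.
#' @export
invertMinMax <- function(values, scaler, city, variable = "PM25") {
  stopifnot(is(scaler, "MinMaxScaler"))
  if (is.matrix(values)) {
    stopifnot(length(city) == ncol(values))
    e <- .scalerLookup(scaler, city, variable)
    sweep(sweep(values, 2, e$xmax - e$xmin, "*"), 2, e$xmin, "+")
  } else {
    stopifnot(length(city) == 1L)
    e <- .scalerLookup(scaler, city, variable)
    values * (e$xmax - e$xmin) + e$xmin
  }
}

#' Persist / restore a scaler as JSON
#'
#' @param scaler a [MinMaxScaler-class].
#' @param path JSON file path.
#' @return `writeScaler` returns `path` invisibly; `readScaler` returns
#'   the restored [MinMaxScaler-class].
#' @export
writeScaler <- function(scaler, path) {
  stopifnot(is(scaler, "MinMaxScaler"))
  write_json(scaler@table, path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeScaler
#' @export
readScaler <- function(path) {
  tb <- as.data.frame(read_json(path, simplifyVector = TRUE))
  new("MinMaxScaler", table = tb)
}
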