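#' @include hourly-panel.R
NULL

.defaultSchema <- function() {
  list(datetime = "datetime", city = "city",
       variable = "variable", value = "value")
}

#' Read a multi-city hourly panel from CSV
#'
#' Accepts the two common dialects. Long format has one row per
#' observation with datetime, city, variable and value columns. Wide
#' format has one row per (datetime, city) with one column per variable.
#' Column names are remapped through `schema`. Hours absent from the
#' file appear as missing cells on a complete hourly grid, never as
#' dropped columns.
#'
#' @param paths character vector of CSV file paths; multiple files are
#'   concatenated before gridding.
#' @param schema named list mapping roles to column names; defaults to
#'   `datetime`, `city`, `variable`, `value`. For wide files only
#'   `datetime` and `city` are used and every other known column is a
#'   variable.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return An [HourlyPanel-class].
#' @details Duplicate (city, hour, variable) records raise an error
#'   naming the first offender; non-monotone or unparseable datetimes
#'   raise an error; columns whose names are not recognized variables
#'   are dropped with a warning.
#' @export
readHourlyPanel <- function(paths, schema = .defaultSchema(),
                            format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  schema <- modifyList(.defaultSchema(), as.list(schema))
  stopifnot(all(file.exists(paths)))
  tabs <- lapply(paths, read.csv, check.names = FALSE,
                 stringsAsFactors = FALSE)
  tab <- do.call(rbind, tabs)
  for (role in c("datetime", "city"))
    if (!schema[[role]] %in% names(tab))
      stop(sprintf("column '%s' (role %s) not found", schema[[role]], role))
  if (format == "auto") {
    format <- if (schema$variable %in% names(tab) &&
                  schema$value %in% names(tab)) "long" else "wide"
  }
  if (format == "wide") {
    varcols <- setdiff(names(tab), c(schema$datetime, schema$city))
    unknown <- setdiff(varcols, .KNOWN_VARS)
    if (length(unknown)) {
      warning("ignoring unknown variable columns: ",
              paste(unknown, collapse = ", "))
      varcols <- setdiff(varcols, unknown)
    }
    if (!length(varcols)) stop("wide CSV contains no known variable columns")
    long <- do.call(rbind, lapply(varcols, function(v) {
      data.frame(datetime = tab[[schema$datetime]],
                 city = tab[[schema$city]],
                 variable = v, value = as.numeric(tab[[v]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    for (role in c("variable", "value"))
      if (!schema[[role]] %in% names(tab))
        stop(sprintf("column '%s' (role %s) not found", schema[[role]], role))
    long <- data.frame(datetime = tab[[schema$datetime]],
                       city = tab[[schema$city]],
                       variable = tab[[schema$variable]],
                       value = as.numeric(tab[[schema$value]]),
                       stringsAsFactors = FALSE)
    unknown <- setdiff(unique(long$variable), .KNOWN_VARS)
    if (length(unknown)) {
      warning("ignoring unknown variables: ", paste(unknown, collapse = ", "))
      long <- long[!long$variable %in% unknown, , drop = FALSE]
    }
  }
  long <- long[!is.na(long$value), , drop = FALSE]
  tm <- as.POSIXct(long$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(tm))) stop("unparseable datetimes in input")
  key <- paste(long$city, as.numeric(tm), long$variable)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate record for city '%s', time %s, variable '%s'",
                 long$city[d], format(tm[d]), long$variable[d]))
  }
  grid <- seq(min(tm), max(tm), by = 3600)
  cityIds <- sort(unique(long$city))
  vars <- intersect(.KNOWN_VARS, unique(long$variable))
  tidx <- match(as.numeric(tm), as.numeric(grid))
  if (any(is.na(tidx)))
    stop("timestamps are not aligned to the hourly grid")
  cidx <- match(long$city, cityIds)
  assaysL <- lapply(setNames(vars, vars), function(v) {
    m <- matrix(NA_real_, length(cityIds), length(grid))
    sel <- long$variable == v
    m[cbind(cidx[sel], tidx[sel])] <- long$value[sel]
    m
  })
  HourlyPanel(assaysL, grid, cityIds)
}

#' Write a panel to long-format CSV
#'
#' @param panel an [HourlyPanel-class].
#' @param path output CSV path.
#' @return `path`, invisibly. Missing cells are written as empty values.
#' @export
writeHourlyPanel <- function(panel, path) {
  stopifnot(is(panel, "HourlyPanel"))
  tm <- format(hourlyTimes(panel), "%Y-%m-%d %H:%M:%S")
  rows <- lapply(panelVariables(panel), function(v) {
    m <- panelMatrix(panel, v)
    data.frame(datetime = rep(tm, each = nrow(m)),
               city = rep(cities(panel), times = ncol(m)),
               variable = v, value = as.vector(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$value), , drop = FALSE]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
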