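#' @include events.R
NULL

#' Sample skewness (third standardized moment)
#'
#' @param x numeric vector; `NA`s dropped.
#' @return `m3 / m2^(3/2)` with population moments; `NA` for constant
#'   input.
#' @export
sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

#' Excess kurtosis (fourth standardized moment minus 3)
#'
#' Reported in excess form, so a normal distribution scores 0.
#'
#' @param x numeric vector; `NA`s dropped.
#' @return `m4 / m2^2 - 3`; `NA` for constant input.
#' @export
excessKurtosis <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Per-city descriptive statistics of a panel variable
#'
#' For each city: max, min, mean, standard deviation, skewness,
#' excess kurtosis, and the Lilliefors normality test p-value
#' (Kolmogorov-Smirnov distance from the fitted normal with the
#' standard small-sample critical-value approximation). A constant
#' series reports zero standard deviation and `NA` for the shape
#' statistics.
#'
#' @param panel an [HourlyPanel-class].
#' @param variable variable to describe (default `"PM25"`).
#' @param timeRange optional length-2 interval restricting the rows
#'   used (e.g. one calendar year).
#' @return `data.frame` with one row per city.
#' @export
panelReport <- function(panel, variable = "PM25", timeRange = NULL) {
  stopifnot(is(panel, "HourlyPanel"))
  m <- panelMatrix(panel, variable)
  if (!is.null(timeRange)) {
    tr <- as.POSIXct(timeRange, tz = "UTC")
    sel <- hourlyTimes(panel) >= tr[1] & hourlyTimes(panel) <= tr[2]
    m <- m[, sel, drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(m)), function(ci) {
    x <- m[ci, ]
    x <- x[!is.na(x)]
    s <- sd(x)
    lp <- if (s > 0 && length(x) >= 5)
      suppressWarnings(lillie.test(x)$p.value) else NA_real_
    data.frame(city = cities(panel)[ci],
               max = max(x), min = min(x), mean = mean(x), std = s,
               skewness = sampleSkewness(x),
               kurtosis = excessKurtosis(x),
               lillieforsP = lp, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
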