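#' @include hourly-panel.R
NULL

#' Imputation policy for hourly panels
#'
#' Two fill methods are supported per series. `adjacent_mean` replaces a
#' missing run by the arithmetic mean of the nearest valid observation
#' before and after the run; `cubic_spline` interpolates the valid
#' points of the (city, variable) series with a cubic spline
#' (Forsythe-Malcolm-Moler end conditions, so data lying exactly on a
#' cubic polynomial are reproduced exactly). The default policy uses
#' adjacent-mean for pollutant gaps of at most `maxGap` hours and cubic
#' splines for longer pollutant gaps and for all meteorological
#' variables. Runs touching a series boundary are filled with the
#' nearest valid value.
#'
#' @param pollutants method for pollutant gaps of length `<= maxGap`:
#'   `"adjacent_mean"` or `"cubic_spline"`.
#' @param longGaps method for pollutant gaps longer than `maxGap`.
#' @param meteorology method for meteorological variables (all gap
#'   lengths).
#' @param maxGap gap length (hours) up to which `pollutants` applies.
#' @return A policy list consumed by [imputeMissing()].
#' @export
imputePolicy <- function(pollutants = "adjacent_mean",
                         longGaps = "cubic_spline",
                         meteorology = "cubic_spline",
                         maxGap = 2L) {
  ok <- c("adjacent_mean", "cubic_spline")
  stopifnot(pollutants %in% ok, longGaps %in% ok, meteorology %in% ok,
            maxGap >= 0)
  list(pollutants = pollutants, longGaps = longGaps,
       meteorology = meteorology, maxGap = as.integer(maxGap))
}

# runs of NA in a logical vector -> data.frame(start, end)
.naRuns <- function(isna) {
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# fill one series; 'method' is a function(runLength) -> method name
.fillSeries <- function(x, methodFor, nonneg, label) {
  if (!anyNA(x)) return(x)
  valid <- which(!is.na(x))
  if (!length(valid))
    stop(sprintf("series entirely missing: %s", label))
  runs <- .naRuns(is.na(x))
  n <- length(x)
  needSpline <- FALSE
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    before <- if (s > 1) x[s - 1L] else NA_real_
    after <- if (e < n) x[e + 1L] else NA_real_
    if (is.na(before) || is.na(after)) {
      # boundary run: nearest valid value
      x[s:e] <- if (is.na(before)) after else before
    } else if (methodFor(e - s + 1L) == "adjacent_mean") {
      x[s:e] <- (before + after) / 2
    } else {
      needSpline <- TRUE
    }
  }
  if (needSpline) {
    miss <- which(is.na(x))
    valid <- which(!is.na(x))
    if (length(valid) < 2L)
      stop(sprintf("too few valid points to spline-impute: %s", label))
    x[miss] <- spline(valid, x[valid], xout = miss, method = "fmm")$y
  }
  if (nonneg) x <- pmax(x, 0)
  x
}

#' Impute missing observations in an hourly panel
#'
#' Applies [imputePolicy()] per (city, variable) series. Non-missing
#' values are left bit-identical; imputed concentrations are clipped at
#' zero; a fully-missing series is an error.
#'
#' @param panel an [HourlyPanel-class].
#' @param policy a policy from [imputePolicy()], or a single method name
#'   (`"adjacent_mean"` / `"cubic_spline"`) applied to every gap.
#' @return The panel with all missing cells filled.
#' @export
imputeMissing <- function(panel, policy = imputePolicy()) {
  stopifnot(is(panel, "HourlyPanel"))
  if (is.character(policy) && length(policy) == 1L)
    policy <- imputePolicy(pollutants = policy, longGaps = policy,
                           meteorology = policy)
  newA <- lapply(setNames(panelVariables(panel), panelVariables(panel)),
    function(v) {
      m <- panelMatrix(panel, v)
      isMet <- v %in% .MET_VARS
      methodFor <- if (isMet) {
        function(len) policy$meteorology
      } else {
        function(len)
          if (len <= policy$maxGap) policy$pollutants else policy$longGaps
      }
      nonneg <- v %in% .CONC_VARS
      for (ci in seq_len(nrow(m)))
        m[ci, ] <- .fillSeries(m[ci, ], methodFor, nonneg,
                               sprintf("city '%s', variable '%s'",
                                       cities(panel)[ci], v))
      m
    })
  .withAssays(panel, newA)
}
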