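#' @include hourly-panel.R
NULL

.CITY_LEVELS <- c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS")
.EVENT_LEVELS <- c("NONE", "MILD_REGIONAL", "MODERATE_REGIONAL",
                   "SEVERE_REGIONAL")

#' City-level 24-h PM2.5 breakpoints
#'
#' Thresholds on the 24-hour mean PM2.5 (µg/m³) mapping to city
#' pollution grades, following the national AQI breakpoint scheme:
#' a day is `CLEAN` up to the first threshold, then `MILD`, `MODERATE`,
#' `HEAVY`, `SERIOUS` on half-open intervals (a boundary value belongs
#' to the lower grade).
#'
#' @param mild,moderate,heavy,serious strictly increasing thresholds
#'   (µg/m³); the defaults 75/115/150/250 are the 24-h PM2.5 cut
#'   points of the national index scheme.
#' @return Named numeric vector of class `BreakpointTable`.
#' @export
breakpointTable <- function(mild = 75, moderate = 115, heavy = 150,
                            serious = 250) {
  v <- c(mild = mild, moderate = moderate, heavy = heavy,
         serious = serious)
  if (any(diff(v) <= 0)) stop("breakpoints must be strictly increasing")
  structure(v, class = "BreakpointTable")
}

#' Grade city-days by 24-h mean PM2.5
#'
#' @param pm25Daily nonnegative 24-h mean PM2.5 values (µg/m³);
#'   vectorized.
#' @param table a [breakpointTable()].
#' @return Ordered factor with levels CLEAN < MILD < MODERATE < HEAVY
#'   < SERIOUS.
#' @export
classifyCityDay <- function(pm25Daily, table = breakpointTable()) {
  if (any(pm25Daily < 0, na.rm = TRUE))
    stop("daily mean PM2.5 must be >= 0")
  idx <- findInterval(pm25Daily, unclass(table), left.open = TRUE) + 1L
  factor(.CITY_LEVELS[idx], levels = .CITY_LEVELS, ordered = TRUE)
}

#' Daily 24-h mean PM2.5 per city
#'
#' Arithmetic mean of the available (non-missing) hours of each
#' calendar day. Days with fewer than `minHours` valid hours are
#' flagged invalid rather than dropped.
#'
#' @param panel an [HourlyPanel-class] (µg/m³ scale).
#' @param minHours minimum valid hours for a day to count (default 20).
#' @param variable variable to aggregate (default `"PM25"`).
#' @return `data.frame` with columns `date`, `city`, `mean`, `nHours`,
#'   `valid`.
#' @export
dailyMean <- function(panel, minHours = 20L, variable = "PM25") {
  stopifnot(is(panel, "HourlyPanel"))
  m <- panelMatrix(panel, variable)
  dates <- as.Date(format(hourlyTimes(panel), "%Y-%m-%d"))
  ud <- unique(dates)
  rows <- lapply(seq_along(ud), function(di) {
    sel <- dates == ud[di]
    vals <- m[, sel, drop = FALSE]
    nH <- rowSums(!is.na(vals))
    data.frame(date = ud[di], city = cities(panel),
               mean = rowMeans(vals, na.rm = TRUE),
               nHours = nH, valid = nH >= minHours,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean[is.nan(out$mean)] <- NA_real_
  out
}

#' Connected clusters of polluted cities
#'
#' Breadth-first connected components of the subgraph induced by
#' cities at grade MILD or worse.
#'
#' @param levels named factor/character of city grades (names = city
#'   identifiers).
#' @param adjacency symmetric 0/1 matrix covering every city in
#'   `levels` (a missing city is an error).
#' @return List of character vectors (the components), possibly empty.
#' @export
contiguousClusters <- function(levels, adjacency) {
  cityIds <- names(levels)
  if (is.null(cityIds)) stop("'levels' must be named by city")
  missing <- setdiff(cityIds, rownames(adjacency))
  if (length(missing))
    stop(sprintf("city missing from adjacency: %s", missing[1]))
  polluted <- cityIds[as.character(levels) != "CLEAN"]
  if (!length(polluted)) return(list())
  A <- adjacency[polluted, polluted, drop = FALSE]
  seen <- setNames(rep(FALSE, length(polluted)), polluted)
  comps <- list()
  for (s in polluted) {
    if (seen[s]) next
    queue <- s
    comp <- character()
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- polluted[A[v, ] != 0 & !seen]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Classify one day's regional pollution event
#'
#' The spatial gate requires a connected cluster of at least
#' `minCluster` polluted cities. Counts of moderately (`nM`) and
#' heavily-or-worse (`nH`) polluted cities are taken region-wide.
#' Decision: `SEVERE_REGIONAL` if the gate holds and `nH >= 5`;
#' `MODERATE_REGIONAL` if the gate holds and either `1 <= nH <= 4` or
#' (`nH == 0` and `nM >= 5`); `MILD_REGIONAL` if the gate holds with
#' `nH == 0` and `nM <= 4`; otherwise `NONE`. The tree is total and
#' mutually exclusive.
#'
#' @param levels named city grades (see [classifyCityDay()]).
#' @param adjacency symmetric 0/1 adjacency matrix.
#' @param minCluster contiguity gate size (default 5).
#' @return List with `eventLevel` (ordered factor), `cluster` (largest
#'   qualifying cluster, or empty), and `counts`
#'   (`nPolluted`, `nModerate`, `nHeavyPlus`).
#' @export
classifyRegionDay <- function(levels, adjacency, minCluster = 5L) {
  lv <- as.character(levels)
  names(lv) <- names(levels)
  comps <- contiguousClusters(levels, adjacency)
  sizes <- vapply(comps, length, 0L)
  gate <- length(comps) && max(sizes) >= minCluster
  nH <- sum(lv %in% c("HEAVY", "SERIOUS"))
  nM <- sum(lv == "MODERATE")
  nP <- sum(lv != "CLEAN")
  level <- if (!gate) "NONE"
  else if (nH >= 5) "SEVERE_REGIONAL"
  else if (nH >= 1 || nM >= 5) "MODERATE_REGIONAL"
  else "MILD_REGIONAL"
  cluster <- if (gate) comps[[which.max(sizes)]] else character()
  list(eventLevel = factor(level, levels = .EVENT_LEVELS, ordered = TRUE),
       cluster = cluster,
       counts = c(nPolluted = nP, nModerate = nM, nHeavyPlus = nH))
}

#' Daily regional pollution events for a whole panel
#'
#' Aggregates to 24-h city means, grades each city-day, and classifies
#' every calendar day. A day on which any city lacks `minHours` valid
#' hours is flagged invalid and classified `NONE`.
#'
#' @param panel an [HourlyPanel-class] on the µg/m³ scale.
#' @param adjacency adjacency matrix (default the packaged 16-city
#'   graph).
#' @param table a [breakpointTable()].
#' @param minHours see [dailyMean()].
#' @param minCluster contiguity gate size.
#' @return `data.frame` with one row per day: `date`, `eventLevel`,
#'   `nPolluted`, `nModerate`, `nHeavyPlus`, `clusterSize`, `cluster`
#'   (comma-separated), `valid`.
#' @export
classifyRegion <- function(panel, adjacency = chengduAdjacency(),
                           table = breakpointTable(), minHours = 20L,
                           minCluster = 5L) {
  dm <- dailyMean(panel, minHours = minHours)
  days <- unique(dm$date)
  rows <- lapply(days, function(d) {
    sub <- dm[dm$date == d, , drop = FALSE]
    ok <- all(sub$valid)
    if (!ok) {
      return(data.frame(date = d, eventLevel = "NONE", nPolluted = NA,
                        nModerate = NA, nHeavyPlus = NA, clusterSize = NA,
                        cluster = "", valid = FALSE,
                        stringsAsFactors = FALSE))
    }
    lv <- classifyCityDay(setNames(sub$mean, sub$city), table)
    names(lv) <- sub$city
    ev <- classifyRegionDay(lv, adjacency, minCluster)
    data.frame(date = d, eventLevel = as.character(ev$eventLevel),
               nPolluted = ev$counts["nPolluted"],
               nModerate = ev$counts["nModerate"],
               nHeavyPlus = ev$counts["nHeavyPlus"],
               clusterSize = length(ev$cluster),
               cluster = paste(ev$cluster, collapse = ","),
               valid = TRUE, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$eventLevel <- factor(out$eventLevel, levels = .EVENT_LEVELS,
                           ordered = TRUE)
  out
}

#' Season of a date
#'
#' Meteorological seasons: spring = Mar-May, summer = Jun-Aug,
#' autumn = Sep-Nov, winter = Jan, Feb and Dec of the same calendar
#' year.
#'
#' @param dates `Date` vector.
#' @return Factor with levels Spring, Summer, Autumn, Winter.
#' @export
seasonOf <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- ifelse(m %in% 3:5, "Spring",
              ifelse(m %in% 6:8, "Summer",
                     ifelse(m %in% 9:11, "Autumn", "Winter")))
  factor(s, levels = c("Spring", "Summer", "Autumn", "Winter"))
}

#' Annual and seasonal tallies of regional pollution days
#'
#' @param events the per-day table from [classifyRegion()].
#' @param year calendar year to tally.
#' @return `data.frame` with one row per event class (mild, moderate,
#'   severe) and columns `Year`, `Spring`, `Summer`, `Autumn`,
#'   `Winter`; seasonal counts sum to the annual count.
#' @export
countEvents <- function(events, year) {
  d <- as.Date(events$date)
  sel <- as.integer(format(d, "%Y")) == year
  ev <- events[sel, , drop = FALSE]
  seas <- seasonOf(ev$date)
  classes <- c(MILD_REGIONAL = "Mild regional pollution",
               MODERATE_REGIONAL = "Moderate regional pollution",
               SEVERE_REGIONAL = "Severe regional pollution")
  rows <- lapply(names(classes), function(cl) {
    hit <- as.character(ev$eventLevel) == cl
    data.frame(Class = classes[[cl]],
               Year = sum(hit),
               Spring = sum(hit & seas == "Spring"),
               Summer = sum(hit & seas == "Summer"),
               Autumn = sum(hit & seas == "Autumn"),
               Winter = sum(hit & seas == "Winter"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
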