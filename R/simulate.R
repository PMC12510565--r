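#' @include adjacency.R
NULL

#' Configuration for the synthetic multi-city region generator
#'
#' Defines a stationary stochastic model of hourly PM2.5 over a city
#' graph: per-city baseline plus winter-peaking seasonal and
#' morning-peaking diurnal sinusoids, an AR(1) anomaly with lagged
#' transport from adjacent cities, signed couplings to smooth synthetic
#' meteorology (wind and rain suppress, humidity amplifies),
#' right-skewed innovations (standardized lognormal), optional pollution
#' episodes injected on chosen city subsets, and truncation at zero.
#'
#' @param adjacency symmetric 0/1 matrix with city dimnames.
#' @param baseline per-city mean level (µg/m³); scalar or named vector.
#' @param seasonalAmp,diurnalAmp sinusoid amplitudes (µg/m³).
#' @param arCoef hourly AR(1) coefficient of the anomaly, in (-1, 1).
#' @param transportWeight either a scalar in `[0, 1)` applied to every
#'   adjacency edge, or a full (possibly directed) weight matrix.
#' @param transportLag transport delay in hours; scalar or matrix.
#' @param noiseSd innovation standard deviation of the persistent
#'   anomaly process (µg/m³); scalar or per-city vector.
#' @param obsNoiseSd standard deviation of the iid observation noise
#'   added to the hourly PM2.5 reading (µg/m³): instrument and
#'   sub-hourly sampling error at the monitor, which does not persist
#'   from hour to hour.
#' @param covariateEffects named coefficients (µg/m³ per standard
#'   deviation of the covariate anomaly); names among the meteorological
#'   variables.
#' @param episodeSchedule list of episodes, each a list with
#'   `startDay`, `durationDays`, `cities`, `boost` (µg/m³).
#' @param missingRate Bernoulli missingness applied after generation.
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @param startDate first day (midnight local standard time).
#' @return A validated `RegionSimConfig` list.
#' @export
regionSimConfig <- function(adjacency,
                            baseline = 35,
                            seasonalAmp = 20,
                            diurnalAmp = 5,
                            arCoef = 0.85,
                            transportWeight = 0.05,
                            transportLag = 2L,
                            noiseSd = 6,
                            obsNoiseSd = 3,
                            covariateEffects = c(wind = -3, rain = -2.5,
                                                 rh = 2),
                            episodeSchedule = list(),
                            missingRate = 0,
                            seed = 1L,
                            startDate = "2023-01-01") {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  cityIds <- rownames(adjacency)
  if (is.null(cityIds)) cityIds <- paste0("C", seq_len(nrow(adjacency)))
  M <- length(cityIds)
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (length(baseline) == 1L) baseline <- rep(baseline, M)
  if (length(noiseSd) == 1L) noiseSd <- rep(noiseSd, M)
  stopifnot(length(baseline) == M, length(noiseSd) == M,
            abs(arCoef) < 1, seasonalAmp >= 0, diurnalAmp >= 0,
            all(noiseSd >= 0), obsNoiseSd >= 0,
            missingRate >= 0, missingRate < 1)
  TW <- if (is.matrix(transportWeight)) transportWeight else
    transportWeight * (adjacency != 0)
  if (max(Mod(eigen(TW, only.values = TRUE)$values)) >= 1)
    stop("unstable transport configuration: spectral radius of the transport weight matrix must be < 1")
  if (max(Mod(eigen(arCoef * diag(M) + TW, only.values = TRUE)$values)) >= 1)
    stop("unstable transport configuration: AR + transport spectral radius must be < 1")
  LAG <- if (is.matrix(transportLag)) transportLag else
    matrix(as.integer(transportLag), M, M)
  stopifnot(all(LAG >= 1))
  for (ep in episodeSchedule) {
    stopifnot(all(c("startDay", "durationDays", "cities", "boost") %in%
                    names(ep)))
    if (!all(ep$cities %in% cityIds))
      stop("episode references unknown cities")
  }
  structure(list(cities = cityIds, adjacency = adjacency,
                 baseline = setNames(baseline, cityIds),
                 seasonalAmp = seasonalAmp, diurnalAmp = diurnalAmp,
                 arCoef = arCoef, TW = TW, LAG = LAG,
                 noiseSd = setNames(noiseSd, cityIds),
                 obsNoiseSd = obsNoiseSd,
                 covariateEffects = covariateEffects,
                 episodeSchedule = episodeSchedule,
                 missingRate = missingRate, seed = as.integer(seed),
                 startDate = startDate),
            class = "RegionSimConfig")
}

# standardized lognormal draws: mean 0, sd 1, positive skew
.skewNoise <- function(n, sdlog = 0.5) {
  mu <- exp(sdlog^2 / 2)
  s <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  (rlnorm(n, 0, sdlog) - mu) / s
}

# smooth AR(1) process, coef phi, innovation sd s
.ar1 <- function(n, phi, s) {
  e <- rnorm(n, 0, s)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
  x
}

#' Simulate a multi-city hourly air-quality panel
#'
#' @param config a [regionSimConfig()].
#' @param nDays number of simulated days (>= 2).
#' @return An [HourlyPanel-class] with PM25, co-pollutants
#'   (SO2, NO2, CO, PM10, O3) and meteorology (temp, rh, pressure,
#'   rain, wind). Fully deterministic given `config$seed`.
#' @export
simulateRegion <- function(config, nDays) {
  stopifnot(inherits(config, "RegionSimConfig"), nDays >= 2)
  M <- length(config$cities)
  nH <- as.integer(nDays * 24)
  tm <- seq(as.POSIXct(paste(config$startDate, "00:00:00"), tz = "UTC"),
            by = 3600, length.out = nH)
  set.seed(config$seed)
  hod <- as.numeric(format(tm, "%H"))
  doy <- as.numeric(format(tm, "%j"))
  winterCos <- cos(2 * pi * (doy - 15) / 365.25)   # peaks mid-January
  seasonal <- config$seasonalAmp * winterCos
  diurnal <- config$diurnalAmp * cos(2 * pi * (hod - 9) / 24)
  aftCos <- cos(2 * pi * (hod - 15) / 24)          # afternoon peak

  # --- meteorology: smooth seeded processes per city -------------------
  met <- list(temp = matrix(0, M, nH), rh = matrix(0, M, nH),
              pressure = matrix(0, M, nH), rain = matrix(0, M, nH),
              wind = matrix(0, M, nH))
  for (ci in seq_len(M)) {
    met$temp[ci, ] <- 16 - 9 * winterCos + 4 * aftCos + .ar1(nH, 0.95, 0.4)
    met$rh[ci, ] <- pmin(pmax(76 + 5 * winterCos - 6 * aftCos + .ar1(nH, 0.95, 1.2), 25), 100)
    met$pressure[ci, ] <- 955 + 7 * winterCos + .ar1(nH, 0.98, 0.3)
    met$wind[ci, ] <- pmax(1.6 + .ar1(nH, 0.95, 0.35), 0)
    wet <- .ar1(nH, 0.97, 0.25)
    thr <- quantile(wet, probs = 0.90) - 0.35 * (-winterCos) # wetter summers
    met$rain[ci, ] <- ifelse(wet > thr, pmax(wet - thr, 0) * 6, 0)
  }

  # --- covariate coupling on standardized anomalies --------------------
  covTerm <- matrix(0, M, nH)
  for (v in names(config$covariateEffects)) {
    if (!v %in% names(met)) next
    m <- met[[v]]
    an <- (m - rowMeans(m)) / pmax(apply(m, 1, sd), 1e-12)
    covTerm <- covTerm + config$covariateEffects[[v]] * an
  }

  # --- episode boosts: trapezoid profile, 12 h build-up and decay ------
  # (haze episodes accumulate and disperse over hours, never stepwise)
  boost <- matrix(0, M, nH, dimnames = list(config$cities, NULL))
  rampH <- 12
  for (ep in config$episodeSchedule) {
    h0 <- (ep$startDay - 1) * 24 + 1
    if (h0 > nH) next                   # beyond the simulated span
    len <- ep$durationDays * 24
    hrs <- h0:min(h0 + len - 1, nH)
    rel <- seq_along(hrs)
    prof <- pmin(1, rel / rampH, (length(rel) - rel + 1) / rampH)
    boost[ep$cities, hrs] <- boost[ep$cities, hrs] +
      ep$boost * rep(prof, each = length(ep$cities))
  }

  # --- anomaly recursion: AR(1) + lagged transport + skewed noise ------
  eps <- matrix(.skewNoise(M * nH), M, nH) * config$noiseSd
  a <- matrix(0, M, nH)
  lags <- sort(unique(as.vector(config$LAG[config$TW != 0])))
  TWl <- lapply(lags, function(L) config$TW * (config$LAG == L))
  for (t in seq_len(nH)) {
    x <- eps[, t]
    if (t > 1) x <- x + config$arCoef * a[, t - 1]
    for (k in seq_along(lags)) {
      L <- lags[k]
      if (t > L) x <- x + TWl[[k]] %*% a[, t - L]
    }
    a[, t] <- x
  }

  pm <- sweep(a + covTerm + boost, 2, seasonal + diurnal, "+") +
    config$baseline
  pm <- pmax(pm, 0)

  # observed PM2.5: latent process plus iid monitor noise
  pmObs <- pmax(pm + matrix(rnorm(M * nH, 0, config$obsNoiseSd), M, nH), 0)

  # --- co-pollutants: noisy affine functions of PM2.5 + covariates -----
  nz <- function(s) matrix(rnorm(M * nH, 0, s), M, nH)
  windAn <- (met$wind - rowMeans(met$wind)) /
    pmax(apply(met$wind, 1, sd), 1e-12)
  pollut <- list(
    SO2 = pmax(7 + 0.10 * pm + nz(1.5), 0),
    NO2 = pmax(22 + 0.35 * pm - 3 * windAn + nz(4), 0),
    CO = pmax(0.55 + 0.010 * pm + nz(0.08), 0),
    PM10 = pmax(12 + 1.45 * pm + nz(6), 0),
    O3 = pmax(55 - 18 * winterCosMat(winterCos, M) + 22 *
                matrix(aftCos, M, nH, byrow = TRUE) - 0.15 * pm + nz(6), 0)
  )

  assaysL <- c(list(PM25 = pmObs), pollut, met)
  assaysL <- lapply(assaysL, function(m) {
    dimnames(m) <- list(config$cities, NULL)
    m
  })
  panel <- HourlyPanel(assaysL, tm, config$cities)
  if (config$missingRate > 0)
    panel <- injectMissing(panel, config$missingRate, config$seed + 1L)
  panel
}

winterCosMat <- function(w, M) matrix(w, M, length(w), byrow = TRUE)

#' Mask a random subset of panel cells as missing
#'
#' Bernoulli(rate) masking of (city, hour, variable) cells, reproducible
#' by seed. If a draw would mask an entire (city, variable) series it is
#' redrawn; after 10 failed attempts an error is raised.
#'
#' @param panel an [HourlyPanel-class].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The masked panel.
#' @export
injectMissing <- function(panel, rate, seed = 1L) {
  stopifnot(is(panel, "HourlyPanel"), rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  vars <- panelVariables(panel)
  nT <- ncol(panel)
  for (attempt in seq_len(10L)) {
    set.seed(seed + attempt - 1L)
    masks <- lapply(vars, function(v)
      matrix(runif(nrow(panel) * nT) < rate, nrow(panel), nT))
    full <- any(vapply(masks, function(m) any(rowSums(m) == nT), TRUE))
    if (!full) {
      newA <- Map(function(v, mk) {
        m <- panelMatrix(panel, v)
        m[mk] <- NA_real_
        m
      }, vars, masks)
      names(newA) <- vars
      return(.withAssays(panel, newA))
    }
  }
  stop("missingness rate would mask entire series; retries exhausted")
}

#' The packaged 16-city synthetic fixture
#'
#' A seeded Chengdu-Chongqing-like panel: 16 cities on the packaged
#' border adjacency, city baselines in the 28-42 µg/m³ range, a
#' winter-peaking seasonal cycle, and a winter episode schedule on
#' connected city subsets sized to produce all three regional pollution
#' event classes (mild, moderate, severe).
#'
#' @param nDays simulated days (default 400, covering a full year plus
#'   the following January).
#' @param seed integer seed.
#' @param missingRate optional Bernoulli missingness.
#' @return An [HourlyPanel-class].
#' @export
makeFixture16City <- function(nDays = 400, seed = 2023L, missingRate = 0) {
  A <- chengduAdjacency()
  cityIds <- rownames(A)
  baseline <- setNames(
    c(32, 34, 30, 24, 36, 33, 25, 31, 29, 35, 37, 35, 38, 33, 31, 26),
    c("Chengdu", "Deyang", "Mianyang", "Suining", "Nanchong", "Guangan",
      "Dazhou", "Chongqing", "Ziyang", "Neijiang", "Zigong", "Luzhou",
      "Yibin", "Leshan", "Meishan", "Yaan"))[cityIds]
  south <- c("Zigong", "Neijiang", "Luzhou", "Yibin", "Leshan", "Ziyang",
             "Chongqing", "Meishan")
  west <- c("Chengdu", "Deyang", "Ziyang", "Meishan", "Yaan", "Leshan")
  episodes <- list(
    list(startDay = 8, durationDays = 2, cities = west, boost = 35),
    list(startDay = 18, durationDays = 3, cities = south, boost = 75),
    list(startDay = 26, durationDays = 2, cities = south[1:7], boost = 140),
    list(startDay = 320, durationDays = 2, cities = west, boost = 36),
    list(startDay = 345, durationDays = 2, cities = south, boost = 75),
    list(startDay = 352, durationDays = 2, cities = west, boost = 35))
  cfg <- regionSimConfig(
    adjacency = A, baseline = baseline, seasonalAmp = 22, diurnalAmp = 6,
    arCoef = 0.85, transportWeight = 0.025, transportLag = 2L,
    noiseSd = 6.5, obsNoiseSd = 3.5,
    episodeSchedule = episodes, missingRate = missingRate,
    seed = seed, startDate = "2023-01-01")
  simulateRegion(cfg, nDays)
}
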