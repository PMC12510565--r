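#' @include report.R train.R simulate.R
NULL

# polynomial rolling hash of a serialized config, for run logging
.configHash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.logRun <- function(cmd, config) {
  message(sprintf("[hazecast] %s | seed=%s | config=%s | R %s",
                  cmd, config$seed %||% "NA", .configHash(config),
                  getRversion()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr; on error remove the listed output files, then rethrow
.cleanOnFailure <- function(files, expr) {
  tryCatch(expr, error = function(e) {
    unlink(files[file.exists(files)])
    stop(e)
  })
}

.loadPanel <- function(config) {
  if (!is.null(config$panelPath)) {
    if (!file.exists(config$panelPath))
      stop(sprintf("panel file not found: %s", config$panelPath))
    readHourlyPanel(config$panelPath,
                    schema = config$schema %||% .defaultSchema())
  } else {
    makeFixture16City(nDays = config$nDays %||% 400,
                      seed = config$seed %||% 2023L,
                      missingRate = config$missingRate %||% 0)
  }
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any of: `panelPath`, `schema`, `nDays`,
#'   `seed`, `missingRate`, `outputDir`, `targetCity`, `W`, `horizon`,
#'   `kernelSize`, `epochs`, `batchSize`, `learningRate`, `year`,
#'   `adjacencyPath`, `breakpoints`, `minHours`, `minCluster`.
#' @return Config list for the `run*()` commands.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  read_yaml(path)
}

.outDir <- function(config) {
  d <- config$outputDir %||% "."
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate a synthetic region and write it as CSV
#'
#' @param config list; uses `nDays`, `seed`, `missingRate`,
#'   `outputDir`.
#' @return Invisibly, the written panel CSV path.
#' @export
runSimulate <- function(config = list()) {
  .logRun("simulate", config)
  d <- .outDir(config)
  out <- file.path(d, "panel.csv")
  .cleanOnFailure(out, {
    panel <- .loadPanel(config)
    writeHourlyPanel(panel, out)
  })
  invisible(out)
}

#' Per-city descriptive statistics command
#'
#' Writes a per-city table of max, min, mean, std, skewness, excess
#' kurtosis and Lilliefors p for the chosen variable and year.
#'
#' @param config list; uses the panel source fields plus `variable`,
#'   `year`, `outputDir`.
#' @return Invisibly, the report `data.frame`.
#' @export
runReport <- function(config = list()) {
  .logRun("report", config)
  d <- .outDir(config)
  out <- file.path(d, "report.csv")
  .cleanOnFailure(out, {
    panel <- imputeMissing(.loadPanel(config))
    tr <- if (!is.null(config$year))
      c(sprintf("%d-01-01 00:00:00", config$year),
        sprintf("%d-12-31 23:00:00", config$year)) else NULL
    rep <- panelReport(panel, variable = config$variable %||% "PM25",
                       timeRange = tr)
    write.csv(rep, out, row.names = FALSE)
    invisible(rep)
  })
}

#' Regional pollution classification command
#'
#' Writes the per-day event table and the annual/seasonal tally.
#'
#' @param config list; panel source fields plus `adjacencyPath`,
#'   `breakpoints` (length-4 numeric), `minHours`, `minCluster`,
#'   `year`, `outputDir`.
#' @return Invisibly, a list with `events` and `tally`.
#' @export
runClassify <- function(config = list()) {
  .logRun("classify", config)
  d <- .outDir(config)
  outs <- file.path(d, c("events.csv", "event_tally.csv"))
  .cleanOnFailure(outs, {
    panel <- imputeMissing(.loadPanel(config))
    adj <- if (!is.null(config$adjacencyPath))
      readAdjacency(config$adjacencyPath) else chengduAdjacency()
    bp <- if (!is.null(config$breakpoints))
      do.call(breakpointTable, as.list(config$breakpoints)) else
        breakpointTable()
    events <- classifyRegion(panel, adj, bp,
                             minHours = config$minHours %||% 20L,
                             minCluster = config$minCluster %||% 5L)
    year <- config$year %||%
      as.integer(format(as.Date(events$date[1]), "%Y"))
    tally <- countEvents(events, year)
    write.csv(events, outs[1], row.names = FALSE)
    write.csv(tally, outs[2], row.names = FALSE)
    invisible(list(events = events, tally = tally))
  })
}

# drop variables with a constant (city, variable) series inside the
# fitting window: they carry no information and would break the
# min-max denominator (PM25 itself is never dropped)
.dropConstantVars <- function(panel, fitRange) {
  tm <- hourlyTimes(panel)
  sel <- tm >= fitRange[1] & tm <= fitRange[2]
  bad <- vapply(panelVariables(panel), function(v) {
    m <- panelMatrix(panel, v)[, sel, drop = FALSE]
    any(apply(m, 1, function(x) max(x, na.rm = TRUE) ==
                min(x, na.rm = TRUE)))
  }, TRUE)
  drop <- setdiff(names(bad)[bad], "PM25")
  if (length(drop)) {
    warning("dropping constant-in-training variables: ",
            paste(drop, collapse = ", "))
    keep <- setdiff(panelVariables(panel), drop)
    assaysL <- lapply(setNames(keep, keep),
                      function(v) panelMatrix(panel, v))
    panel <- HourlyPanel(assaysL, tm, cities(panel))
  }
  panel
}

# shared preparation: impute, fit scaler on the training fraction of
# the time axis, normalize, window, split
.prepareSupervised <- function(config) {
  panel <- imputeMissing(.loadPanel(config))
  tm <- hourlyTimes(panel)
  trainFrac <- (config$fractions %||% c(0.7, 0.1, 0.2))[1]
  fitEnd <- tm[max(2L, floor(trainFrac * length(tm)))]
  panel <- suppressWarnings(.dropConstantVars(panel, c(tm[1], fitEnd)))
  scaler <- fitMinMax(panel, c(tm[1], fitEnd))
  panelN <- suppressWarnings(applyMinMax(panel, scaler))
  ws <- makeWindows(panelN,
                    targetCity = config$targetCity %||% cities(panel)[1],
                    W = config$W %||% 24L,
                    horizon = config$horizon %||% 1L)
  sp <- chronologicalSplit(ws, config$fractions %||% c(0.7, 0.1, 0.2))
  mconfig <- modelConfig(
    W = config$W %||% 24L, M = length(ws@cities),
    E = length(ws@exoVars),
    lstmHidden = config$lstmHidden %||% 64L,
    kernelSize = config$kernelSize %||% 4L,
    pyramidLevels = config$pyramidLevels %||% 3L,
    channels = config$channels %||% 16L,
    fusionDim = config$fusionDim %||% 64L,
    seed = config$seed %||% 1L)
  tconfig <- trainConfig(
    learningRate = config$learningRate %||% 1e-4,
    batchSize = config$batchSize %||% 30L,
    maxEpochs = config$epochs %||% 100L,
    earlyStopPatience = config$earlyStopPatience %||% Inf,
    seed = config$seed %||% 1L)
  list(panel = panel, scaler = scaler, ws = ws, split = sp,
       mconfig = mconfig, tconfig = tconfig)
}

#' Train the forecaster end to end
#'
#' Simulates or loads a panel, imputes, fits the scaler on the
#' training period, windows, splits chronologically, trains, and
#' writes a checkpoint (RDS), the scaler (JSON) and the loss history
#' (CSV).
#'
#' @param config list; see [readRunConfig()].
#' @return Invisibly, the fitted object from [trainModel()] plus the
#'   preparation pieces.
#' @export
runTrain <- function(config = list()) {
  .logRun("train", config)
  d <- .outDir(config)
  outs <- file.path(d, c("checkpoint.rds", "scaler.json", "history.csv"))
  .cleanOnFailure(outs, {
    prep <- .prepareSupervised(config)
    fit <- trainModel(initParams(prep$mconfig), prep$mconfig,
                      prep$split$train, prep$split$val, prep$tconfig)
    saveRDS(list(params = fit$params, mconfig = prep$mconfig,
                 seed = config$seed %||% 1L), outs[1])
    writeScaler(prep$scaler, outs[2])
    write.csv(fit$history, outs[3], row.names = FALSE)
    invisible(c(fit, prep))
  })
}

#' Forecast with a trained checkpoint
#'
#' @param config list; needs `checkpointPath` and `scalerPath` (as
#'   written by [runTrain()]) plus the panel source fields.
#' @return Invisibly, the forecast matrix (µg/m³).
#' @export
runPredict <- function(config = list()) {
  .logRun("predict", config)
  d <- .outDir(config)
  out <- file.path(d, "forecast.csv")
  .cleanOnFailure(out, {
    ck <- readRDS(config$checkpointPath)
    scaler <- readScaler(config$scalerPath)
    prep <- .prepareSupervised(config)
    pred <- predictConcentrations(ck$params, ck$mconfig, prep$split$test,
                                  scaler)
    df <- data.frame(targetTime = format(attr(pred, "targetTime")),
                     as.data.frame(pred), check.names = FALSE)
    write.csv(df, out, row.names = FALSE)
    invisible(pred)
  })
}

#' Train and evaluate: annual and seasonal metrics
#'
#' Trains on the chronological split and writes per-city annual
#' metrics and per-season regional metrics (seasonal rows mask the
#' test split by target season).
#'
#' @param config list; see [readRunConfig()].
#' @return Invisibly, a list with `annual` (per-city + Regional) and
#'   `seasonal` metric tables.
#' @export
runEvaluate <- function(config = list()) {
  .logRun("evaluate", config)
  d <- .outDir(config)
  outs <- file.path(d, c("metrics_annual.csv", "metrics_seasonal.csv",
                         "metrics.json"))
  .cleanOnFailure(outs, {
    prep <- .prepareSupervised(config)
    fit <- trainModel(initParams(prep$mconfig), prep$mconfig,
                      prep$split$train, prep$split$val, prep$tconfig)
    te <- prep$split$test
    pred <- predictConcentrations(fit$params, prep$mconfig, te,
                                  prep$scaler)
    obs <- invertMinMax(te@Y, prep$scaler, te@cities, "PM25")
    colnames(obs) <- te@cities
    annual <- perCityMetrics(obs, pred)
    seas <- seasonOf(as.Date(format(te@targetTime, "%Y-%m-%d")))
    seasonal <- do.call(rbind, lapply(levels(seas), function(s) {
      sel <- seas == s
      if (sum(sel) < 2)
        return(data.frame(season = s, r2 = NA, mae = NA, rmse = NA))
      m <- evaluateForecast(as.vector(obs[sel, ]), as.vector(pred[sel, ]))
      data.frame(season = s, r2 = m["r2"], mae = m["mae"],
                 rmse = m["rmse"], row.names = NULL)
    }))
    write.csv(annual, outs[1], row.names = FALSE)
    write.csv(seasonal, outs[2], row.names = FALSE)
    write_json(list(annual = annual, seasonal = seasonal), outs[3],
               digits = NA, dataframe = "rows")
    invisible(list(annual = annual, seasonal = seasonal, fit = fit))
  })
}

#' Hyperparameter grid command
#'
#' @param config list; `kernelSizes` and `windowLengths` override the
#'   published grid; small model widths can be set as in [runTrain()].
#' @return Invisibly, the [tuneGrid()] result.
#' @export
runTune <- function(config = list()) {
  .logRun("tune", config)
  d <- .outDir(config)
  out <- file.path(d, "tuning.csv")
  .cleanOnFailure(out, {
    panel <- imputeMissing(.loadPanel(config))
    tm <- hourlyTimes(panel)
    fitEnd <- tm[max(2L, floor(0.7 * length(tm)))]
    panel <- suppressWarnings(.dropConstantVars(panel, c(tm[1], fitEnd)))
    scaler <- fitMinMax(panel, c(tm[1], fitEnd))
    panelN <- suppressWarnings(applyMinMax(panel, scaler))
    tg <- tuneGrid(panelN, scaler,
                   targetCity = config$targetCity %||% cities(panel)[1],
                   kernelSizes = config$kernelSizes %||% c(2, 4, 6, 8, 10),
                   windowLengths = config$windowLengths %||%
                     c(4, 12, 24, 120, 168),
                   tconfig = trainConfig(
                     learningRate = config$learningRate %||% 1e-4,
                     batchSize = config$batchSize %||% 30L,
                     maxEpochs = config$epochs %||% 100L,
                     seed = config$seed %||% 1L),
                   lstmHidden = config$lstmHidden %||% 64L,
                   pyramidLevels = config$pyramidLevels %||% 3L,
                   channels = config$channels %||% 16L,
                   fusionDim = config$fusionDim %||% 64L,
                   seed = config$seed %||% 1L)
    write.csv(tg$table, out, row.names = FALSE)
    invisible(tg)
  })
}
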