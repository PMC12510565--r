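#' @include backprop.R
NULL

# apply f to every numeric leaf of a (possibly nested) parameter list,
# in parallel over further trees with the same shape
.mapLeaves <- function(f, x, ...) {
  rest <- list(...)
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    byName <- !is.null(names(x)) && all(nzchar(names(x)))
    for (i in seq_along(x)) {
      key <- if (byName) names(x)[i] else i
      res <- do.call(.mapLeaves,
                     c(list(f, x[[i]]), lapply(rest, `[[`, key)))
      out[i] <- list(res)             # keeps NULL slots in place
    }
    return(out)
  }
  do.call(f, c(list(x), rest))
}

.zerosLike <- function(params) .mapLeaves(function(x) x * 0, params)

# flatten the numeric leaves of x in the traversal order of 'template',
# matching leaves by name where the template is named
.flattenLike <- function(template, x) {
  if (is.null(template)) return(NULL)
  if (is.list(template)) {
    nm <- names(template)
    parts <- vector("list", length(template))
    for (i in seq_along(template)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
      parts[[i]] <- .flattenLike(template[[i]], x[[key]])
    }
    return(unlist(parts, use.names = FALSE))
  }
  as.vector(x)
}

# inverse of unlist(): rebuild the template structure from a flat vector
.relistParams <- function(vec, template) {
  off <- 0L
  rec <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) {
      out <- vector("list", length(x))
      names(out) <- names(x)
      for (i in seq_along(x)) out[i] <- list(rec(x[[i]]))
      return(out)
    }
    n <- length(x)
    leaf <- vec[(off + 1L):(off + n)]
    off <<- off + n
    dim(leaf) <- dim(x)
    leaf
  }
  rec(template)
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, batch size 30, learning
#' rate 1e-4, at most 100 epochs.
#'
#' @param learningRate Adam step size (> 0; 0 is allowed and leaves
#'   parameters untouched, useful for diagnostics).
#' @param batchSize minibatch size.
#' @param maxEpochs maximum number of passes over the training set.
#' @param earlyStopPatience stop after this many epochs without
#'   validation improvement (`Inf` disables).
#' @param lrDecay multiplicative learning-rate decay per epoch
#'   (default 1 = constant rate).
#' @param weightDecay decoupled L2 weight decay per step (AdamW form;
#'   default 0).
#' @param averageFrom fraction of the epoch budget after which tail
#'   parameter averaging starts (Polyak averaging over the epochs'
#'   final iterates; the averaged model is kept when it validates
#'   better). `NULL` disables.
#' @param inputNoiseSd standard deviation of seeded Gaussian jitter
#'   added to the normalized inputs of each training batch (denoising
#'   augmentation; the validation pass always sees clean inputs).
#'   Default 0.
#' @param warmStartOutputBias initialize the output biases at the
#'   logit of the per-city training-target means before optimization,
#'   so the early epochs are not spent learning the climatology.
#' @param seed seed for the epoch-wise batch shuffling.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 30L,
                        maxEpochs = 100L, earlyStopPatience = Inf,
                        lrDecay = 1, weightDecay = 0,
                        averageFrom = NULL, inputNoiseSd = 0,
                        warmStartOutputBias = TRUE, seed = 1L) {
  stopifnot(learningRate >= 0, batchSize >= 1, maxEpochs >= 1,
            lrDecay > 0, lrDecay <= 1, weightDecay >= 0,
            inputNoiseSd >= 0,
            is.null(averageFrom) ||
              (averageFrom >= 0 && averageFrom < 1))
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 optimizer = "adam",
                 earlyStopPatience = earlyStopPatience,
                 lrDecay = lrDecay,
                 weightDecay = weightDecay,
                 averageFrom = averageFrom,
                 inputNoiseSd = inputNoiseSd,
                 warmStartOutputBias = isTRUE(warmStartOutputBias),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Train the forecaster by minibatch Adam on the multi-output loss
#'
#' Batches are drawn in a freshly shuffled (seeded) order every epoch.
#' After each epoch the validation loss is computed; the returned
#' parameters are those of the best validation epoch.
#'
#' @param params initial parameters from [initParams()].
#' @param mconfig the [modelConfig()].
#' @param trainWS,valWS training and validation [WindowSet-class]s
#'   (`valWS = NULL` validates on the training set).
#' @param tconfig a [trainConfig()].
#' @return List with `params` (best-validation checkpoint), `history`
#'   (per-epoch train and validation loss) and `bestEpoch`.
#' @export
trainModel <- function(params, mconfig, trainWS, valWS = NULL,
                       tconfig = trainConfig()) {
  stopifnot(is(trainWS, "WindowSet"), length(trainWS) >= 1)
  if (is.null(valWS)) valWS <- trainWS
  if (isTRUE(tconfig$warmStartOutputBias) && tconfig$learningRate > 0) {
    mu <- pmin(pmax(colMeans(trainWS@Y), 1e-4), 1 - 1e-4)
    params$fus$bout <- unname(log(mu / (1 - mu)))
  }
  lr <- tconfig$learningRate
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  template <- params
  pvec <- unlist(params, use.names = FALSE)
  mv <- numeric(length(pvec))
  vv <- numeric(length(pvec))
  step <- 0L
  n <- length(trainWS)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric())
  set.seed(tconfig$seed)
  sinceBest <- 0L
  avgStart <- if (is.null(tconfig$averageFrom)) Inf else
    max(1L, ceiling(tconfig$averageFrom * tconfig$maxEpochs))
  avgVec <- NULL
  nAvg <- 0L
  for (epoch in seq_len(tconfig$maxEpochs)) {
    lrEpoch <- lr * tconfig$lrDecay^(epoch - 1)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = tconfig$batchSize)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + tconfig$batchSize - 1L, n)]
      batch <- trainWS[idx]
      if (tconfig$inputNoiseSd > 0) {
        s <- tconfig$inputNoiseSd
        batch@Xh <- batch@Xh + rnorm(length(batch@Xh), 0, s)
        batch@Xe <- batch@Xe + rnorm(length(batch@Xe), 0, s)
        batch@Xt <- batch@Xt + rnorm(length(batch@Xt), 0, s)
      }
      g <- msfrpmGradients(batch, params, mconfig)
      if (!is.finite(g$loss))
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, bi))
      losses[bi] <- g$loss
      step <- step + 1L
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      gvec <- .flattenLike(template, g$grads)
      mv <- b1 * mv + (1 - b1) * gvec
      vv <- b2 * vv + (1 - b2) * gvec^2
      pvec <- pvec - lrEpoch * ((mv / corr1) / (sqrt(vv / corr2) + epsA) +
                                  tconfig$weightDecay * pvec)
      params <- .relistParams(pvec, template)
    }
    if (epoch >= avgStart) {
      nAvg <- nAvg + 1L
      avgVec <- if (is.null(avgVec)) pvec else
        avgVec + (pvec - avgVec) / nAvg
    }
    valLoss <- molfLoss(valWS@Y, msfrpmForward(valWS, params, mconfig))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   trainLoss = mean(losses),
                                   valLoss = valLoss))
    if (valLoss < best$val) {
      best <- list(val = valLoss, params = params, epoch = epoch)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= tconfig$earlyStopPatience) break
    }
  }
  if (!is.null(avgVec)) {
    avgParams <- .relistParams(avgVec, template)
    avgVal <- molfLoss(valWS@Y, msfrpmForward(valWS, avgParams, mconfig))
    if (avgVal < best$val)
      best <- list(val = avgVal, params = avgParams, epoch = NA_integer_)
  }
  list(params = best$params, history = hist, bestEpoch = best$epoch)
}

#' Forecast concentrations in measurement units
#'
#' Forward pass followed by per-city inversion of the min-max
#' normalization.
#'
#' @param params,mconfig trained parameters and [modelConfig()].
#' @param ws a [WindowSet-class].
#' @param scaler the training [MinMaxScaler-class]; must cover every
#'   panel city (a missing entry is an error).
#' @return `n x M` matrix of PM2.5 forecasts in µg/m³, columns named by
#'   city, with the target times as an attribute.
#' @export
predictConcentrations <- function(params, mconfig, ws, scaler) {
  stopifnot(is(ws, "WindowSet"))
  yhat <- msfrpmForward(ws, params, mconfig)
  out <- invertMinMax(yhat, scaler, ws@cities, "PM25")
  colnames(out) <- ws@cities
  attr(out, "targetTime") <- ws@targetTime
  out
}

#' Persistence baseline forecast
#'
#' Predicts each city's PM2.5 at the target hour by its last observed
#' value inside the input window (the minimal-skill reference).
#'
#' @param ws a [WindowSet-class].
#' @param scaler the [MinMaxScaler-class] used to normalize the panel.
#' @return `n x M` matrix of forecasts in µg/m³.
#' @export
persistenceForecast <- function(ws, scaler) {
  stopifnot(is(ws, "WindowSet"))
  last <- ws@Xt[, , ws@W, drop = FALSE]
  dim(last) <- dim(last)[1:2]
  out <- invertMinMax(last, scaler, ws@cities, "PM25")
  colnames(out) <- ws@cities
  out
}

#' Forecast evaluation metrics
#'
#' `R2 = 1 - SSE/SST`, `MAE = mean |error|`,
#' `RMSE = sqrt(mean error^2)`.
#'
#' @param yObs,yPred equal-length numeric vectors (µg/m³); `yObs` must
#'   not be constant (the R2 denominator would vanish).
#' @return Named numeric vector `c(r2, mae, rmse)`.
#' @export
evaluateForecast <- function(yObs, yPred) {
  yObs <- as.numeric(yObs); yPred <- as.numeric(yPred)
  if (length(yObs) != length(yPred)) stop("unequal lengths")
  if (length(yObs) < 2) stop("need at least 2 observations")
  sst <- sum((yObs - mean(yObs))^2)
  if (sst == 0) stop("constant observations: R2 undefined")
  err <- yObs - yPred
  c(r2 = 1 - sum(err^2) / sst,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)))
}

#' Per-city and regional metrics for multi-output forecasts
#'
#' One metrics row per city plus a `Regional` row holding the mean of
#' the per-city metrics.
#'
#' @param Yobs,Ypred `n x M` matrices in µg/m³, columns = cities.
#' @return `data.frame` with columns `city`, `r2`, `mae`, `rmse`.
#' @export
perCityMetrics <- function(Yobs, Ypred) {
  stopifnot(identical(dim(Yobs), dim(Ypred)))
  cityIds <- colnames(Yobs)
  if (is.null(cityIds)) cityIds <- paste0("C", seq_len(ncol(Yobs)))
  rows <- lapply(seq_len(ncol(Yobs)), function(j) {
    m <- evaluateForecast(Yobs[, j], Ypred[, j])
    data.frame(city = cityIds[j], r2 = m["r2"], mae = m["mae"],
               rmse = m["rmse"], row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(city = "Regional", r2 = mean(tab$r2),
                        mae = mean(tab$mae), rmse = mean(tab$rmse)))
}

#' Grid search over kernel size and input window length
#'
#' Trains one seeded model per grid cell and scores it by validation
#' MAE (µg/m³, pooled over cities). Cells whose training fails are
#' recorded as failed and excluded from the argmin.
#'
#' @param panelNorm normalized, imputed [HourlyPanel-class].
#' @param scaler the fitted [MinMaxScaler-class].
#' @param targetCity target city for the temporal/exogenous streams.
#' @param kernelSizes,windowLengths grid values; defaults are the
#'   published tuning grid.
#' @param tconfig a [trainConfig()].
#' @param fractions chronological split fractions.
#' @param ... further arguments to [modelConfig()] (e.g. smaller
#'   widths for desk-scale runs).
#' @return List with `best` (kernel size, window length) and `table`
#'   (one row per cell: kernelSize, W, valMAE, failed).
#' @export
tuneGrid <- function(panelNorm, scaler, targetCity = cities(panelNorm)[1],
                     kernelSizes = c(2, 4, 6, 8, 10),
                     windowLengths = c(4, 12, 24, 120, 168),
                     tconfig = trainConfig(), fractions = c(0.7, 0.1, 0.2),
                     ...) {
  grid <- expand.grid(kernelSize = kernelSizes, W = windowLengths)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ks <- grid$kernelSize[i]; W <- grid$W[i]
    tryCatch({
      ws <- makeWindows(panelNorm, targetCity, W = W)
      sp <- chronologicalSplit(ws, fractions)
      mc <- modelConfig(W = W, M = length(ws@cities),
                        E = length(ws@exoVars), kernelSize = ks, ...)
      fit <- trainModel(initParams(mc), mc, sp$train, sp$val, tconfig)
      pred <- predictConcentrations(fit$params, mc, sp$val, scaler)
      obs <- invertMinMax(sp$val@Y, scaler, sp$val@cities, "PM25")
      data.frame(kernelSize = ks, W = W,
                 valMAE = mean(abs(obs - pred)), failed = FALSE)
    }, error = function(e)
      data.frame(kernelSize = ks, W = W, valMAE = NA_real_, failed = TRUE))
  })
  tab <- do.call(rbind, res)
  ok <- which(!tab$failed)
  if (!length(ok)) stop("every grid cell failed")
  bi <- ok[which.min(tab$valMAE[ok])]
  list(best = list(kernelSize = tab$kernelSize[bi], W = tab$W[bi]),
       table = tab)
}

#' k-fold cross-validation of the forecaster
#'
#' `mode = "random"` follows the published protocol: a seeded random
#' partition into k near-equal subsets, each used once as the test
#' fold. `mode = "blocked"` uses contiguous chronological folds, which
#' avoids temporal leakage and is the stricter protocol for time
#' series.
#'
#' @param ws a [WindowSet-class].
#' @param k number of folds (>= 2).
#' @param mode `"random"` or `"blocked"` (`"random_paper"` is accepted
#'   as an alias of `"random"`).
#' @param seed partition seed.
#' @param mconfig,tconfig model and training configuration.
#' @param scaler the [MinMaxScaler-class] for reporting in µg/m³.
#' @return List with `perFold` (fold, r2, mae, rmse), `mean` and `sd`.
#' @export
kfoldCV <- function(ws, k = 10L, mode = c("random", "blocked",
                                          "random_paper"),
                    seed = 1L, mconfig, tconfig = trainConfig(),
                    scaler) {
  mode <- match.arg(mode)
  if (mode == "random_paper") mode <- "random"
  n <- length(ws)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer samples than folds")
  fold <- if (mode == "random") {
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  } else {
    as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  }
  rows <- lapply(seq_len(k), function(f) {
    tr <- ws[fold != f]
    te <- ws[fold == f]
    mc <- mconfig
    fit <- trainModel(initParams(mc), mc, tr, NULL, tconfig)
    pred <- predictConcentrations(fit$params, mc, te, scaler)
    obs <- invertMinMax(te@Y, scaler, te@cities, "PM25")
    m <- evaluateForecast(as.vector(obs), as.vector(pred))
    data.frame(fold = f, r2 = m["r2"], mae = m["mae"], rmse = m["rmse"],
               row.names = NULL)
  })
  perFold <- do.call(rbind, rows)
  list(perFold = perFold,
       mean = colMeans(perFold[, c("r2", "mae", "rmse")]),
       sd = vapply(perFold[, c("r2", "mae", "rmse")], sd, 0),
       fold = fold)
}
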