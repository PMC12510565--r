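test_that("metric definitions match hand arithmetic", {
  expect_equal(unname(evaluateForecast(c(1, 2, 3), c(1, 2, 3))),
               c(1, 0, 0))
  m <- evaluateForecast(c(0, 2), c(1, 1))
  expect_equal(unname(m), c(0, 1, 1))            # R2 = 1 - 2/2
  expect_error(evaluateForecast(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(evaluateForecast(1, 1), "at least 2")
  expect_error(evaluateForecast(1:3, 1:4), "unequal")
})

test_that("metrics agree with an independent brute-force oracle", {
  # oracle coded from the definitions, element by element
  oracle <- function(o, p) {
    sse <- 0; sab <- 0; sst <- 0
    ob <- sum(o) / length(o)
    for (i in seq_along(o)) {
      sse <- sse + (o[i] - p[i])^2
      sab <- sab + abs(o[i] - p[i])
      sst <- sst + (o[i] - ob)^2
    }
    c(1 - sse / sst, sab / length(o), sqrt(sse / length(o)))
  }
  set.seed(99)
  for (rep in 1:100) {
    o <- rnorm(20, 40, 15)
    p <- o + rnorm(20, 0, 5)
    expect_equal(unname(evaluateForecast(o, p)), oracle(o, p),
                 tolerance = 1e-10)
  }
})

test_that("RMSE is never below MAE", {
  set.seed(5)
  for (rep in 1:20) {
    o <- rnorm(30)
    p <- rnorm(30)
    m <- evaluateForecast(o, p)
    expect_gte(m["rmse"], m["mae"])
  }
})

test_that("zero learning rate leaves parameters untouched", {
  s <- smallSupervised(nDays = 3)
  sp <- chronologicalSplit(s$ws)
  mc <- modelConfig(W = 24, M = 3, E = length(s$ws@exoVars),
                    lstmHidden = 4, dnnLayers = 4, channels = 2,
                    fusionDim = 4, seed = 2)
  par <- initParams(mc)
  fit <- trainModel(par, mc, sp$train, sp$val,
                    trainConfig(learningRate = 0, maxEpochs = 2, seed = 1))
  expect_equal(fit$params, par, tolerance = 1e-14)
})

test_that("training history is seed-deterministic and checkpoint selection holds", {
  s <- smallSupervised(nDays = 3)
  sp <- chronologicalSplit(s$ws)
  mc <- modelConfig(W = 24, M = 3, E = length(s$ws@exoVars),
                    lstmHidden = 4, dnnLayers = 4, channels = 2,
                    fusionDim = 4, seed = 2)
  tc <- trainConfig(learningRate = 1e-3, maxEpochs = 3, batchSize = 16,
                    seed = 11)
  f1 <- trainModel(initParams(mc), mc, sp$train, sp$val, tc)
  f2 <- trainModel(initParams(mc), mc, sp$train, sp$val, tc)
  expect_identical(f1$history, f2$history)
  expect_true(all(is.finite(f1$history$trainLoss)))
  best <- min(f1$history$valLoss)
  expect_equal(f1$history$valLoss[f1$bestEpoch], best)
  expect_lte(best, f1$history$valLoss[1])
})

test_that("denormalized predictions invert the scaler exactly", {
  s <- smallSupervised(nDays = 3)
  sp <- chronologicalSplit(s$ws)
  mc <- modelConfig(W = 24, M = 3, E = length(s$ws@exoVars),
                    lstmHidden = 4, dnnLayers = 4, channels = 2,
                    fusionDim = 4, seed = 2)
  par <- hazecast:::.mapLeaves(function(x) x * 0, initParams(mc))
  pred <- predictConcentrations(par, mc, sp$test, s$scaler)
  # zero network predicts 0.5 for every city -> midpoint of each range
  tb <- s$scaler@table
  for (ci in sp$test@cities) {
    e <- tb[tb$city == ci & tb$variable == "PM25", ]
    expect_equal(unname(pred[1, ci]), e$xmin + 0.5 * (e$xmax - e$xmin),
                 tolerance = 1e-12)
  }
  expect_equal(dim(pred), c(length(sp$test), 3))
  expect_true(all(is.finite(pred)))
})

test_that("persistence baseline equals the last observed concentrations", {
  s <- smallSupervised(nDays = 3)
  ws <- s$ws
  pf <- persistenceForecast(ws, s$scaler)
  pm <- panelMatrix(s$panel, "PM25")
  tm <- hourlyTimes(s$panel)
  i <- 5
  tIdx <- match(ws@targetTime[i], tm)
  expect_equal(unname(pf[i, ]), unname(pm[, tIdx - 1]), tolerance = 1e-9)
})

test_that("cross-validation folds partition the samples with near-equal sizes", {
  s <- smallSupervised(nDays = 3)
  ws <- s$ws
  mc <- modelConfig(W = 24, M = 3, E = length(ws@exoVars), lstmHidden = 3,
                    dnnLayers = 3, channels = 2, fusionDim = 3, seed = 2)
  tc <- trainConfig(learningRate = 1e-3, maxEpochs = 1, batchSize = 16,
                    seed = 1)
  cv <- kfoldCV(ws[1:30], k = 3, mode = "random", seed = 4, mconfig = mc,
                tconfig = tc, scaler = s$scaler)
  expect_equal(sort(unique(cv$fold)), 1:3)
  expect_true(max(table(cv$fold)) - min(table(cv$fold)) <= 1)
  expect_equal(length(cv$fold), 30)
  expect_equal(nrow(cv$perFold), 3)
  expect_true(all(is.finite(cv$perFold$rmse)))
  # blocked folds are contiguous
  cvb <- kfoldCV(ws[1:30], k = 2, mode = "blocked", seed = 4, mconfig = mc,
                 tconfig = tc, scaler = s$scaler)
  expect_equal(cvb$fold, rep(1:2, each = 15))
  expect_error(kfoldCV(ws[1:30], k = 1, mconfig = mc, tconfig = tc,
                       scaler = s$scaler), "k must be")
})

test_that("grid tuning returns the argmin over non-failed cells", {
  s <- smallSupervised(nDays = 4)
  tc <- trainConfig(learningRate = 1e-3, maxEpochs = 1, batchSize = 32,
                    seed = 1)
  tg <- tuneGrid(s$panelN, s$scaler, targetCity = "A",
                 kernelSizes = c(2, 40), windowLengths = c(12, 24),
                 tconfig = tc, lstmHidden = 3, dnnLayers = 3,
                 channels = 2, fusionDim = 3, pyramidLevels = 1, seed = 2)
  expect_equal(nrow(tg$table), 4)
  # kernel 40 exceeds both windows -> those cells fail
  expect_equal(sum(tg$table$failed), 2)
  ok <- tg$table[!tg$table$failed, ]
  expect_equal(tg$best$W, ok$W[which.min(ok$valMAE)])
  expect_equal(tg$best$kernelSize, 2)
  # single-cell grid returns that cell
  tg1 <- tuneGrid(s$panelN, s$scaler, targetCity = "A",
                  kernelSizes = 2, windowLengths = 12, tconfig = tc,
                  lstmHidden = 3, dnnLayers = 3, channels = 2,
                  fusionDim = 3, pyramidLevels = 1, seed = 2)
  expect_equal(nrow(tg1$table), 1)
  expect_equal(tg1$best$W, 12)
})
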