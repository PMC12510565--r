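test_that("generation is bit-reproducible for a fixed seed", {
  p1 <- smallSimPanel(3, seed = 9)
  p2 <- smallSimPanel(3, seed = 9)
  expect_identical(panelArray(p1), panelArray(p2))
  p3 <- smallSimPanel(3, seed = 10)
  expect_false(identical(panelMatrix(p1), panelMatrix(p3)))
})

test_that("with all dynamics off PM2.5 equals the baseline", {
  cfg <- regionSimConfig(adjacency = pathAdjacency(2),
                         baseline = c(30, 50), seasonalAmp = 0,
                         diurnalAmp = 0, arCoef = 0, transportWeight = 0,
                         noiseSd = 0, obsNoiseSd = 0,
                         covariateEffects = c(), seed = 1)
  p <- simulateRegion(cfg, 2)
  expect_equal(panelMatrix(p)["A", ], rep(30, 48), ignore_attr = TRUE)
  expect_equal(panelMatrix(p)["B", ], rep(50, 48), ignore_attr = TRUE)
})

test_that("a pure lagged copy shows its cross-correlation peak at the lag", {
  # directed transport: B copies A's anomaly with a 3 h delay
  A <- pathAdjacency(2)
  TW <- matrix(0, 2, 2, dimnames = dimnames(A))
  TW["B", "A"] <- 1
  cfg <- regionSimConfig(adjacency = A, transportWeight = TW,
                         transportLag = 3L, baseline = c(40, 40),
                         seasonalAmp = 0, diurnalAmp = 0, arCoef = 0,
                         noiseSd = c(5, 0), obsNoiseSd = 0,
                         covariateEffects = c(), seed = 21)
  p <- simulateRegion(cfg, 20)
  a <- panelMatrix(p)["A", ] - 40
  b <- panelMatrix(p)["B", ] - 40
  cc <- vapply(0:8, function(L) {
    n <- length(a)
    cor(a[1:(n - L)], b[(1 + L):n])
  }, 0)
  expect_equal(which.max(cc) - 1, 3)
  expect_gt(max(cc), 0.95)
})

test_that("unstable transport configurations are rejected", {
  expect_error(regionSimConfig(adjacency = pathAdjacency(2),
                               transportWeight = 0.9, arCoef = 0.5),
               "unstable transport")
})

test_that("simulated PM2.5 marginals are right-skewed and anomalies stay bounded", {
  cfg <- regionSimConfig(adjacency = pathAdjacency(3),
                         baseline = c(30, 35, 40), seed = 4)
  p <- simulateRegion(cfg, 60)
  pm <- panelMatrix(p)
  for (ci in 1:3) expect_gt(sampleSkewness(pm[ci, ]), 0)
  # stationarity: variance of the late half comparable to the early half
  n <- ncol(pm)
  v1 <- var(pm[1, 1:(n / 2)])
  v2 <- var(pm[1, (n / 2 + 1):n])
  expect_lt(v2, 10 * v1)
})

test_that("missingness injection is seeded, bounded and never masks a full series", {
  p <- smallSimPanel(4)
  m0 <- injectMissing(p, 0, 1)
  expect_identical(panelArray(m0), panelArray(p))
  m1 <- injectMissing(p, 0.1, 5)
  m2 <- injectMissing(p, 0.1, 5)
  expect_identical(which(is.na(panelArray(m1))), which(is.na(panelArray(m2))))
  nCells <- prod(dim(panelArray(p)))
  nMasked <- sum(is.na(panelArray(m1)))
  # binomial 99% interval around rate 0.1
  expect_gt(nMasked, qbinom(0.005, nCells, 0.1))
  expect_lt(nMasked, qbinom(0.995, nCells, 0.1))
  for (v in panelVariables(m1))
    expect_true(all(rowSums(!is.na(panelMatrix(m1, v))) > 0))
})

test_that("the 16-city fixture has the advertised structure", {
  p <- makeFixture16City(nDays = 60, seed = 2023)
  expect_equal(nrow(p), 16)
  expect_setequal(cities(p), rownames(chengduAdjacency()))
  # winter-month mean exceeds what the seasonal term implies for later months
  pm <- panelMatrix(p)
  mo <- as.integer(format(hourlyTimes(p), "%m"))
  expect_gt(mean(pm[, mo == 1]), mean(pm[, mo == 2]))
})

test_that("fixture winters are dirtier than summers", {
  p <- makeFixture16City(nDays = 240, seed = 2023)
  pm <- panelMatrix(p)
  mo <- as.integer(format(hourlyTimes(p), "%m"))
  winter <- mean(pm[, mo %in% c(1, 2, 12)])
  summer <- mean(pm[, mo %in% 6:8])
  expect_gt(winter, summer)
})
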