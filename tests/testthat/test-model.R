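# zero out every parameter leaf
zeroParams <- function(par) hazecast:::.mapLeaves(function(x) x * 0, par)

test_that("single LSTM step with zero parameters matches the hand computation", {
  mc <- modelConfig(W = 1, M = 1, E = 1, lstmHidden = 1, dnnLayers = 1,
                    kernelSize = 1, pyramidLevels = 1, channels = 1,
                    fusionDim = 1, seed = 1)
  par <- zeroParams(initParams(mc))
  # all gates sigmoid(0) = 0.5; candidate (published sigmoid form) = 0.5
  # c1 = 0.5*0 + 0.5*0.5 = 0.25; h1 = 0.5 * tanh(0.25)
  h <- tdmForward(0.8, par, mc)
  expect_equal(h[1, 1], 0.5 * tanh(0.25), tolerance = 1e-12)
  # conventional tanh candidate: c1 = 0.5*tanh(0) = 0 -> h1 = 0
  mc2 <- modelConfig(W = 1, M = 1, E = 1, lstmHidden = 1, dnnLayers = 1,
                     kernelSize = 1, pyramidLevels = 1, channels = 1,
                     fusionDim = 1, candidateActivation = "tanh", seed = 1)
  expect_equal(tdmForward(0.8, par, mc2)[1, 1], 0)
})

test_that("a saturated output gate silences the hidden state", {
  mc <- tinyModelConfig()
  par <- initParams(mc)
  par$tdm$bo <- rep(-50, mc$lstmHidden)
  par$tdm$Wo <- par$tdm$Wo * 0
  par$tdm$Uo <- par$tdm$Uo * 0
  h <- tdmForward(runif(mc$W), par, mc)
  expect_true(all(abs(h) < 1e-15))
})

test_that("two recurrence steps equal the composition of one-step runs", {
  mc <- modelConfig(W = 2, M = 2, E = 1, lstmHidden = 3, dnnLayers = 3,
                    kernelSize = 2, pyramidLevels = 1, channels = 2,
                    fusionDim = 3, seed = 3)
  par <- initParams(mc)
  x <- c(0.3, 0.7)
  h2 <- tdmForward(x, par, mc, cache = TRUE)
  st <- attr(h2, "cache")
  # manual recurrence using the cached gates of step 2
  p <- par$tdm
  sig <- function(z) 1 / (1 + exp(-z))
  h1 <- st$hprev[1, , 2]
  c1 <- st$c[1, , 1]
  f2 <- sig(x[2] * p$Wf[1, ] + h1 %*% p$Uf + p$bf)
  i2 <- sig(x[2] * p$Wi[1, ] + h1 %*% p$Ui + p$bi)
  o2 <- sig(x[2] * p$Wo[1, ] + h1 %*% p$Uo + p$bo)
  g2 <- sig(x[2] * p$Wc[1, ] + h1 %*% p$Uc + p$bc)
  c2 <- f2 * c1 + i2 * g2
  expect_equal(as.vector(h2), as.vector(o2 * tanh(c2)), tolerance = 1e-12)
})

test_that("feed-forward stream with zero parameters reflects its activation", {
  mc <- tinyModelConfig()
  par <- zeroParams(initParams(mc))
  a <- nrmForward(matrix(runif(8), 1), par, mc)
  expect_equal(as.vector(a), rep(0, 3))          # relu(0) = 0
  mcS <- tinyModelConfig(dnnActivation = "sigmoid")
  aS <- nrmForward(matrix(runif(8), 1), zeroParams(initParams(mcS)), mcS)
  expect_equal(as.vector(aS), rep(0.5, 3))       # sigmoid(0) = 0.5
})

test_that("identity convolution with a silent parallel branch reproduces the input", {
  mc <- modelConfig(W = 4, M = 1, E = 1, lstmHidden = 2, dnnLayers = 2,
                    kernelSize = 1, pyramidLevels = 1, channels = 1,
                    pooling = "mean", fusionDim = 2, seed = 1)
  par <- initParams(mc)
  par$mspm[[1]]$K <- array(1, c(1, 1, 1))
  par$mspm[[1]]$b <- 0
  par$mspm[[1]]$Kn <- array(0, c(1, 1, 1))
  par$mspm[[1]]$bn <- 0
  xt <- matrix(c(0.1, 0.4, 0.2, 0.8), 1, 4)
  mf <- mspmForward(xt, par, mc)
  # direct branch = ReLU(Xt) = Xt (inputs >= 0), then mean pooling
  expect_equal(as.vector(mf), c(mean(c(0.1, 0.4)), mean(c(0.2, 0.8))),
               tolerance = 1e-12)
})

test_that("pyramid temporal lengths follow conv and stride-2 pooling arithmetic", {
  mc <- modelConfig(W = 24, M = 3, E = 1, kernelSize = 4,
                    pyramidLevels = 3, channels = 5, seed = 1)
  # conv: 24 -> 21 -> 18 -> 15; pooled: ceil(21/2), ceil(18/2), ceil(15/2)
  expect_equal(mc$convLens, c(21L, 18L, 15L))
  expect_equal(mc$pooledLens, c(11L, 9L, 8L))
  par <- initParams(mc)
  mf <- mspmForward(array(runif(3 * 24), c(1, 3, 24)), par, mc)
  expect_equal(ncol(mf), 5 * (11 + 9 + 8))
  expect_error(modelConfig(W = 6, M = 2, E = 1, kernelSize = 4,
                           pyramidLevels = 3, seed = 1),
               "reduce pyramidLevels or kernelSize")
})

test_that("all-zero parameters predict 0.5 everywhere and extreme biases saturate", {
  mc <- tinyModelConfig()
  par <- zeroParams(initParams(mc))
  b <- tinyBatch(4, mc)
  y <- msfrpmForward(b, par, mc)
  expect_equal(unname(y), matrix(0.5, 4, 2), tolerance = 1e-12)
  par$fus$bout <- rep(100, 2)
  expect_equal(unname(msfrpmForward(b, par, mc)),
               matrix(1, 4, 2), tolerance = 1e-10)
})

test_that("consistent city permutation permutes the forecasts", {
  mc <- tinyModelConfig()
  par <- initParams(mc)
  b <- tinyBatch(3, mc)
  y <- msfrpmForward(b, par, mc)
  perm <- c(2, 1)
  par2 <- par
  par2$mspm[[1]]$K <- par$mspm[[1]]$K[, perm, , drop = FALSE]
  par2$mspm[[1]]$Kn <- par$mspm[[1]]$Kn[, perm, , drop = FALSE]
  par2$fus$Wout <- par$fus$Wout[, perm]
  par2$fus$bout <- par$fus$bout[perm]
  b2 <- b
  b2$Xt <- b$Xt[, perm, , drop = FALSE]
  y2 <- msfrpmForward(b2, par2, mc)
  expect_equal(unname(y2), unname(y[, perm]), tolerance = 1e-12)
})

test_that("forward pass is deterministic and finite on extreme inputs", {
  mc <- tinyModelConfig()
  par <- initParams(mc)
  b <- tinyBatch(3, mc)
  expect_identical(msfrpmForward(b, par, mc), msfrpmForward(b, par, mc))
  bx <- b
  bx$Xh <- bx$Xh * 1e6
  bx$Xt <- bx$Xt * 1e6
  y <- msfrpmForward(bx, par, mc)
  expect_true(all(is.finite(y)))
  expect_true(all(y >= 0 & y <= 1))
  # on ordinary normalized inputs the range is strictly open
  y0 <- msfrpmForward(b, par, mc)
  expect_true(all(y0 > 0 & y0 < 1))
})

test_that("initialization is seed-deterministic with finite values", {
  mc <- tinyModelConfig()
  p1 <- initParams(mc)
  p2 <- initParams(mc)
  expect_identical(p1, p2)
  expect_true(all(is.finite(unlist(p1))))
  expect_equal(p1$tdm$bf, rep(0, 3))
  mcB <- tinyModelConfig(forgetBias = 1)
  expect_equal(initParams(mcB)$tdm$bf, rep(1, 3))
  p3 <- initParams(tinyModelConfig(seed = 6))
  expect_false(identical(p1$fus$Wout, p3$fus$Wout))
})

test_that("multi-output loss matches hand arithmetic and the flattened MSE", {
  Y <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(molfLoss(Y, Y), 0)
  Yh <- matrix(c(1, 3, 3, 6), 2, 2)
  expect_equal(molfLoss(Y, Yh), (0 + 0 + 1 + 4) / 4)   # = 1.25
  set.seed(2)
  A <- matrix(rnorm(20), 4, 5)
  B <- matrix(rnorm(20), 4, 5)
  expect_equal(molfLoss(A, B), mean((as.vector(A) - as.vector(B))^2))
  expect_error(molfLoss(A, B[, 1:3]), "shapes differ")
})
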