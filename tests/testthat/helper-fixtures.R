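# shared fixture builders; everything is generated in code

hoursFrom <- function(start, n)
  seq(as.POSIXct(start, tz = "UTC"), by = 3600, length.out = n)

# tiny deterministic panel: values are easy to reason about by hand
tinyPanel <- function(nCities = 2, nHours = 6, vars = c("PM25", "SO2")) {
  cityIds <- LETTERS[seq_len(nCities)]
  assaysL <- lapply(setNames(vars, vars), function(v) {
    base <- if (v == "PM25") 10 else 100
    matrix(base + seq_len(nCities * nHours), nCities, nHours)
  })
  HourlyPanel(assaysL, hoursFrom("2023-01-01", nHours), cityIds)
}

# small simulated region on a 3-city path graph
pathAdjacency <- function(n = 3, ids = LETTERS[seq_len(n)]) {
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- 1L
    A[i + 1, i] <- 1L
  }
  A
}

smallSimPanel <- function(nDays = 8, seed = 7, ...) {
  cfg <- regionSimConfig(adjacency = pathAdjacency(3),
                         baseline = c(30, 35, 40), seed = seed, ...)
  simulateRegion(cfg, nDays)
}

# hand-built panel with guaranteed variation in every series: PM2.5
# diurnal sinusoid + seeded noise, two exogenous variables
madePanel <- function(nDays = 3, seed = 7, nCities = 3) {
  n <- nDays * 24
  cityIds <- LETTERS[seq_len(nCities)]
  set.seed(seed)
  hour <- rep(0:23, length.out = n)
  mk <- function(base, amp)
    t(vapply(seq_len(nCities), function(ci)
      pmax(base + 5 * ci + amp * sin(2 * pi * hour / 24) +
             rnorm(n, 0, 2), 0), numeric(n)))
  HourlyPanel(list(PM25 = mk(30, 8), temp = mk(10, 4), wind = mk(2, 1)),
              hoursFrom("2023-01-01", n), cityIds)
}

# normalized supervised data ready for model tests
smallSupervised <- function(nDays = 3, seed = 7, W = 24) {
  p <- madePanel(nDays, seed)
  sc <- fitMinMax(p)
  pn <- suppressWarnings(applyMinMax(p, sc))
  ws <- makeWindows(pn, "A", W = W)
  list(panel = p, scaler = sc, panelN = pn, ws = ws)
}

# tiny model configuration for fast exact checks
tinyModelConfig <- function(seed = 5, ...) {
  modelConfig(W = 4, M = 2, E = 2, lstmHidden = 3, dnnLayers = c(3),
              kernelSize = 2, pyramidLevels = 2, channels = 2,
              fusionDim = 3, seed = seed, ...)
}

tinyBatch <- function(n = 3, mc = tinyModelConfig(), seed = 42) {
  set.seed(seed)
  list(Xh = matrix(runif(n * mc$W), n, mc$W),
       Xe = array(runif(n * mc$W * mc$E), c(n, mc$W, mc$E)),
       Xt = array(runif(n * mc$M * mc$W), c(n, mc$M, mc$W)),
       Y = matrix(runif(n * mc$M), n, mc$M))
}

# parameter-tree helpers used by the gradient checks
getIn <- function(p, path) {
  for (k in path) p <- p[[k]]
  p
}
setIn <- function(p, path, val) {
  if (length(path) == 1) {
    p[[path[[1]]]] <- val
    return(p)
  }
  p[[path[[1]]]] <- setIn(p[[path[[1]]]], path[-1], val)
  p
}

# finite-difference check of every analytic gradient leaf
leafPaths <- function(p, prefix = list()) {
  if (!is.list(p)) return(list(prefix))
  out <- list()
  for (i in seq_along(p)) {
    if (is.null(p[[i]])) next
    key <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
    out <- c(out, leafPaths(p[[i]], c(prefix, list(key))))
  }
  out
}

checkAllGradients <- function(mc, n = 3, tol = 1e-4) {
  par <- initParams(mc)
  b <- tinyBatch(n, mc)
  g <- msfrpmGradients(b, par, mc, Y = b$Y)
  eps <- 1e-6
  for (path in leafPaths(par)) {
    ref <- getIn(par, path)
    gr <- as.vector(getIn(g$grads, path))
    for (i in seq_along(ref)) {
      xa <- ref; xa[i] <- xa[i] + eps
      xb <- ref; xb[i] <- xb[i] - eps
      nd <- (molfLoss(b$Y, msfrpmForward(b, setIn(par, path, xa), mc)) -
             molfLoss(b$Y, msfrpmForward(b, setIn(par, path, xb), mc))) /
        (2 * eps)
      rel <- abs(nd - gr[i]) / max(abs(nd) + abs(gr[i]), 1e-8)
      if (rel > tol)
        return(sprintf("gradient mismatch at %s[%d]: analytic %g vs fd %g",
                       paste(unlist(path), collapse = "$"), i, gr[i], nd))
    }
  }
  TRUE
}

# named city levels helper
cityLevels <- function(...) {
  v <- c(...)
  factor(v, levels = c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS"),
         ordered = TRUE)
}

# independent brute-force re-implementation of the regional decision
# rules, used as an oracle against classifyRegionDay
bruteRegionDay <- function(levels, adjacency, minCluster = 5L) {
  lv <- as.character(levels)
  ids <- names(levels)
  polluted <- ids[lv != "CLEAN"]
  # connected components by repeated neighbourhood expansion
  comps <- list()
  left <- polluted
  while (length(left)) {
    comp <- left[1]
    repeat {
      nb <- unique(unlist(lapply(comp, function(v)
        polluted[adjacency[v, polluted] != 0])))
      grown <- union(comp, nb)
      if (setequal(grown, comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1]] <- comp
    left <- setdiff(left, comp)
  }
  gate <- any(vapply(comps, length, 0L) >= minCluster)
  nH <- sum(lv %in% c("HEAVY", "SERIOUS"))
  nM <- sum(lv == "MODERATE")
  if (!gate) return("NONE")
  if (nH >= 5) return("SEVERE_REGIONAL")
  if (nH >= 1) return("MODERATE_REGIONAL")
  if (nM >= 5) return("MODERATE_REGIONAL")
  "MILD_REGIONAL"
}
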