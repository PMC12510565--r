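#' @include normalize.R
NULL

#' WindowSet: supervised sliding-window samples
#'
#' A batch container of supervised forecasting examples built from a
#' normalized panel. Sample `i` predicts the PM2.5 of all `M` cities at
#' `targetTime[i]` from three inputs that end strictly before the
#' target: `Xh` (target city's PM2.5 history, `n x W`), `Xe` (target
#' city's exogenous variables, `n x W x E`) and `Xt` (all-city PM2.5
#' history, `n x M x W`, fixed city order). `Y` (`n x M`) holds the
#' normalized targets.
#'
#' @aliases WindowSet-class
#' @export
setClass("WindowSet",
         representation(Xh = "matrix", Xe = "array", Xt = "array",
                        Y = "matrix", targetTime = "POSIXct",
                        W = "integer", horizon = "integer",
                        cities = "character", exoVars = "character",
                        targetCity = "character"))

setValidity("WindowSet", function(object) {
  n <- nrow(object@Xh)
  if (nrow(object@Y) != n || dim(object@Xt)[1] != n ||
      dim(object@Xe)[1] != n || length(object@targetTime) != n)
    return("inconsistent sample counts across slots")
  if (ncol(object@Xh) != object@W) return("Xh must have W columns")
  TRUE
})

#' @describeIn WindowSet-class number of samples
#' @param x a `WindowSet`.
#' @export
setMethod("length", "WindowSet", function(x) nrow(x@Xh))

#' @describeIn WindowSet-class subset samples by index
#' @param i integer or logical index of samples.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
             Xh = x@Xh[i, , drop = FALSE],
             Xe = x@Xe[i, , , drop = FALSE],
             Xt = x@Xt[i, , , drop = FALSE],
             Y = x@Y[i, , drop = FALSE],
             targetTime = x@targetTime[i])
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf(
    "WindowSet: %d samples | W = %d, horizon = %d | target city '%s'\n",
    length(object), object@W, object@horizon, object@targetCity))
  cat(sprintf("  %d cities, %d exogenous variables\n",
              length(object@cities), length(object@exoVars)))
  invisible(NULL)
})

#' Build supervised sliding windows from a normalized panel
#'
#' One sample is produced for every admissible target hour, i.e.
#' `T - W - horizon + 1` samples for a panel of `T` hours. All three
#' input blocks use hours `t - horizon - W + 1` through `t - horizon`,
#' strictly before the target hour `t` (no leakage).
#'
#' @param panel an imputed, normalized [HourlyPanel-class].
#' @param targetCity one or more cities whose own history and exogenous
#'   variables feed the temporal and exogenous streams (default: first
#'   city). With several target cities the per-city sample streams are
#'   concatenated in order, which enlarges and diversifies a training
#'   set: the regional block and the targets are shared, only the
#'   city-specific inputs differ.
#' @param W input window length in hours.
#' @param horizon forecast lead in hours (default 1).
#' @param exoVars exogenous variables for `Xe`; default every non-PM25
#'   variable in the panel.
#' @return A [WindowSet-class].
#' @export
makeWindows <- function(panel, targetCity = cities(panel)[1], W = 24L,
                        horizon = 1L, exoVars = NULL) {
  stopifnot(is(panel, "HourlyPanel"), W >= 1, horizon >= 1)
  W <- as.integer(W); horizon <- as.integer(horizon)
  if (length(targetCity) > 1) {
    parts <- lapply(targetCity, function(tc)
      makeWindows(panel, tc, W = W, horizon = horizon, exoVars = exoVars))
    out <- parts[[1]]
    cat3 <- function(f) {
      arrs <- lapply(parts, f)
      do.call(abind3, arrs)
    }
    return(initialize(out,
                      Xh = do.call(rbind, lapply(parts, slot, "Xh")),
                      Xe = cat3(function(p) p@Xe),
                      Xt = cat3(function(p) p@Xt),
                      Y = do.call(rbind, lapply(parts, slot, "Y")),
                      targetTime = do.call(c, lapply(parts, slot,
                                                     "targetTime")),
                      targetCity = as.character(targetCity)))
  }
  tm <- hourlyTimes(panel)
  Tn <- length(tm)
  if (W + horizon > Tn)
    stop(sprintf("window (%d) + horizon (%d) exceeds panel length (%d)",
                 W, horizon, Tn))
  if (!targetCity %in% cities(panel))
    stop(sprintf("unknown target city '%s'", targetCity))
  if (is.null(exoVars)) exoVars <- setdiff(panelVariables(panel), "PM25")
  M <- nrow(panel)
  pm <- panelMatrix(panel, "PM25")            # M x T
  if (anyNA(pm)) stop("panel must be imputed before windowing")
  targets <- seq.int(W + horizon, Tn)
  n <- length(targets)
  offs <- seq.int(-horizon - W + 1L, -horizon)  # relative feature hours
  featIdx <- outer(targets, offs, "+")          # n x W
  tcRow <- pm[targetCity, ]
  Xh <- matrix(tcRow[featIdx], n, W)
  Xe <- array(0, c(n, W, length(exoVars)),
              dimnames = list(NULL, NULL, exoVars))
  for (v in exoVars) {
    row <- panelMatrix(panel, v)[targetCity, ]
    Xe[, , v] <- matrix(row[featIdx], n, W)
  }
  Xt <- array(0, c(n, M, W), dimnames = list(NULL, cities(panel), NULL))
  for (ci in seq_len(M))
    Xt[, ci, ] <- matrix(pm[ci, ][featIdx], n, W)
  Y <- t(pm[, targets, drop = FALSE])
  dimnames(Y) <- list(NULL, cities(panel))
  new("WindowSet", Xh = Xh, Xe = Xe, Xt = Xt, Y = Y,
      targetTime = tm[targets], W = W, horizon = horizon,
      cities = cities(panel), exoVars = as.character(exoVars),
      targetCity = targetCity)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, c(n, d[2], d[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[2:3]))
  off <- 0L
  for (a in arrs) {
    out[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  out
}

#' Chronological train / validation / test split
#'
#' Order-preserving contiguous partition; boundaries at
#' `floor(cumsum(fractions) * n)`.
#'
#' @param ws a [WindowSet-class] (samples in chronological order).
#' @param fractions positive fractions summing to 1; default `7:1:2`.
#' @return Named list of `WindowSet`s: `train`, `val`, `test`.
#' @export
chronologicalSplit <- function(ws, fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(is(ws, "WindowSet"), all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(ws)
  if (n < 10) stop("too few samples to split (need >= 10)")
  b <- floor(cumsum(fractions) * n + sqrt(.Machine$double.eps))
  b[length(b)] <- n
  starts <- c(1L, head(b, -1) + 1L)
  if (any(starts > b)) stop("fractions produce an empty split part")
  parts <- Map(function(s, e) ws[seq.int(s, e)], starts, b)
  names(parts) <- c("train", "val", "test")[seq_along(parts)]
  parts
}
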