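#' @include model.R
NULL

#' Loss and analytic gradients of the forecaster
#'
#' Runs the full forward pass with caches and backpropagates the
#' multi-output squared-error loss through the fusion head, the
#' convolutional pyramid (including pooling and both branches), the
#' feed-forward exogenous stream and the recurrent temporal stream
#' (backpropagation through time). The gradient structure mirrors the
#' parameter structure exactly.
#'
#' @param ws a [WindowSet-class] batch or a list with `Xh`, `Xe`, `Xt`.
#' @param Y observed normalized targets (`n x M`); defaults to `ws@Y`.
#' @param params,config model parameters and [modelConfig()].
#' @return List with `loss` (scalar) and `grads` (nested list shaped
#'   like `params`).
#' @export
msfrpmGradients <- function(ws, params, config, Y = NULL) {
  if (is(ws, "WindowSet")) {
    if (is.null(Y)) Y <- ws@Y
    ws <- list(Xh = ws@Xh, Xe = ws@Xe, Xt = ws@Xt)
  }
  stopifnot(!is.null(Y))
  yhat <- msfrpmForward(ws, params, config, cache = TRUE)
  cch <- attr(yhat, "cache")
  n <- nrow(yhat)
  loss <- mean((Y - yhat)^2)

  # --- fusion head ---------------------------------------------------
  p <- params$fus
  dYhat <- 2 * (yhat - Y) / length(Y)
  dLogits <- dYhat * yhat * (1 - yhat)
  Fmat <- cch$fus$F
  gFus <- list(Wout = crossprod(Fmat, dLogits),
               bout = colSums(dLogits))
  dF <- dLogits %*% t(p$Wout)
  gFus$P1 <- crossprod(cch$h, dF)
  gFus$P2 <- crossprod(cch$a, dF)
  gFus$b <- colSums(dF)
  dh <- dF %*% t(p$P1)
  da <- dF %*% t(p$P2)
  if (config$useMSPM) {
    gFus$P3 <- crossprod(cch$mf, dF)
    dmf <- dF %*% t(p$P3)
  }

  # --- exogenous stream ----------------------------------------------
  act <- .actFun(config$dnnActivation)
  nst <- cch$nrm
  gNrm <- vector("list", length(params$nrm))
  dA <- da
  for (l in rev(seq_along(params$nrm))) {
    dZ <- dA * act$df(nst$pre[[l]], nst$post[[l]])
    gNrm[[l]] <- list(W = crossprod(nst$inputs[[l]], dZ),
                      b = colSums(dZ))
    dA <- dZ %*% t(params$nrm[[l]]$W)
  }

  # --- regional pyramid ----------------------------------------------
  gMspm <- NULL
  if (config$useMSPM) {
    gMspm <- vector("list", config$pyramidLevels)
    mst <- cch$mspm
    # split flattened gradient back into per-level blocks
    sizes <- config$channels * config$pooledLens
    offs <- cumsum(c(0, sizes))
    dZnext <- NULL                                # grad wrt level input Z
    for (k in rev(seq_len(config$pyramidLevels))) {
      lev <- params$mspm[[k]]
      stt <- mst$levels[[k]]
      dMF <- array(dmf[, (offs[k] + 1):offs[k + 1], drop = FALSE],
                   stt$MFdim)
      dAd <- .poolBackward(dMF, stt$pd, config$pooling)
      if (!is.null(dZnext)) dAd <- dAd + dZnext
      dAn <- .poolBackward(dMF, stt$pn, config$pooling)
      dPreD <- dAd * (stt$Ad > 0)
      dPreN <- dAn * (stt$An > 0)
      bd <- .conv1dBackward(dPreD, stt$Zcol, lev$K, stt$Zdim)
      bn <- .conv1dBackward(dPreN, stt$ZcolN, lev$Kn, stt$Zdim)
      gMspm[[k]] <- list(K = bd$dK, b = bd$db, Kn = bn$dK, bn = bn$db)
      dZnext <- bd$dZ + bn$dZ
    }
  }

  # --- temporal stream (BPTT, compiled) ------------------------------
  tp <- params$tdm
  tst <- cch$tdm
  candTanh <- config$candidateActivation == "tanh"
  Xh <- ws$Xh
  if (!is.matrix(Xh)) Xh <- matrix(Xh, nrow = 1)
  bp <- .lstmBackwardCpp(Xh, dh, tst$f, tst$i, tst$o, tst$g, tst$c,
                         tst$hprev, tp$Uf, tp$Ui, tp$Uo, tp$Uc, candTanh)
  gT <- list(Wf = bp$Wf, Wi = bp$Wi, Wo = bp$Wo, Wc = bp$Wc,
             Uf = bp$Uf, Ui = bp$Ui, Uo = bp$Uo, Uc = bp$Uc,
             bf = as.vector(bp$bf), bi = as.vector(bp$bi),
             bo = as.vector(bp$bo), bc = as.vector(bp$bc))

  grads <- list(tdm = gT, nrm = gNrm, mspm = gMspm, fus = gFus)
  list(loss = loss, grads = .stripNames(grads), yhat = yhat)
}

# drop dim/element names picked up from inputs so that optimizer
# updates never decorate the parameter arrays
.stripNames <- function(x) {
  if (is.list(x)) return(lapply(x, .stripNames))
  if (is.null(x)) return(NULL)
  dimnames(x) <- NULL
  names(x) <- NULL
  x
}
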