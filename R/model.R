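## The 2D-to-3D encoder-decoder. A U-Net-style 2D convolutional network over
## the (lateral, Z) localizer plane whose final layer emits one channel per
## AP bin of the coronal output volume: the 2D skeleton keeps the quoted
## 2 x 2 stride meaningful while producing a full 3D volume. All convolutions
## are 3x3 (zero pad 1); encoder levels downsample by stride 2 with batch
## normalization and ReLU, decoder levels upsample (nearest x2), concatenate
## the mirrored encoder activation and convolve at stride 1. Training is
## plain per-sample (batch size 1) Adam on MSE; no augmentation, no
## scheduler. Everything is seeded and bit-reproducible.

#' Network architecture configuration
#'
#' @param depth encoder/decoder level count (full-scale default 5).
#' @param baseChannels channels of the first encoder level; each level
#'   doubles up to 8x the base.
#' @param outputApBins AP bins emitted as output channels (full-scale default 184).
#' @param inputShape c(lateral, Z) localizer matrix (full-scale default 144 x 64);
#'   shapes not divisible by 2^depth are reflect-padded internally and the
#'   output cropped back.
#' @param batchNorm use batch normalization (per-sample statistics at batch
#'   size 1).
#' @param outputActivation "sigmoid" (default) squashes the head's output
#'   into (0,1); intensity targets live on plateaus (air, lung, couch, soft
#'   tissue), and a saturating output makes crisp plateau predictions easy
#'   to express, which the downstream thresholding relies on. "linear" keeps
#'   the raw head output.
#' @param globalContext broadcast the spatially pooled bottleneck features
#'   into the output head. The table height of a case is a single global
#'   quantity read from absolute-position cues (couch edge magnification);
#'   this shortcut gives the head a one-layer path from those global
#'   features to the anterior-posterior placement of the output mass.
#' @param stride downsampling factor per level; the architecture is defined
#'   for stride 2.
#' @return Validated config list (class \code{ModelConfig}).
#' @export
modelConfig <- function(depth = 5L, baseChannels = 8L, outputApBins = 184L,
                        inputShape = c(144L, 64L), batchNorm = TRUE,
                        outputActivation = c("sigmoid", "linear"),
                        globalContext = TRUE, stride = 2L) {
  outputActivation <- match.arg(outputActivation)
  if (depth < 1) stop("depth must be >= 1")
  if (stride != 2L) stop("the encoder is defined for stride 2")
  if (outputApBins < 1 || baseChannels < 1) stop("channel counts must be >= 1")
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 outputApBins = as.integer(outputApBins),
                 inputShape = as.integer(inputShape),
                 batchNorm = isTRUE(batchNorm),
                 outputActivation = outputActivation,
                 globalContext = isTRUE(globalContext), stride = 2L),
            class = "ModelConfig")
}

#' Training configuration
#'
#' Defaults follow the training protocol: 50 epochs, batch size 1, Adam,
#' no data augmentation. Loss and learning rate are configurable (MSE and
#' 1e-3 by default).
#'
#' @param epochs training epochs (0 leaves the model untouched).
#' @param batchSize only 1 is supported (per-sample updates).
#' @param optimizer "adam".
#' @param lr learning rate.
#' @param loss "mse" or "l1".
#' @param seed integer controlling shuffling (weights are seeded at build
#'   time).
#' @param augmentation must be "none".
#' @param shuffle reshuffle case order each epoch.
#' @param tailAverage average the weights over the last \code{tailAverage}
#'   epochs (0 disables). Per-sample updates leave substantial gradient
#'   noise in the final weights; tail averaging removes it without any
#'   learning-rate schedule.
#' @return Validated config list (class \code{TrainConfig}).
#' @export
trainConfig <- function(epochs = 50L, batchSize = 1L, optimizer = "adam",
                        lr = 1e-3, loss = c("mse", "l1"), seed = 1L,
                        augmentation = "none", shuffle = TRUE,
                        tailAverage = 0L) {
  loss <- match.arg(loss)
  if (epochs < 0) stop("epochs must be >= 0")
  if (batchSize != 1L) stop("only batch size 1 is supported")
  if (!identical(optimizer, "adam")) stop("only the Adam optimizer is supported")
  if (!identical(augmentation, "none")) stop("no augmentation is implemented")
  if (tailAverage < 0 || tailAverage > epochs)
    stop("tailAverage must be between 0 and epochs")
  structure(list(epochs = as.integer(epochs), batchSize = 1L,
                 optimizer = "adam", lr = lr, loss = loss,
                 seed = as.integer(seed), augmentation = "none",
                 shuffle = isTRUE(shuffle), tailAverage = as.integer(tailAverage)),
            class = "TrainConfig")
}

encChannels <- function(config) {
  config$baseChannels * 2L^pmin(seq_len(config$depth) - 1L, 3L)
}

nextMultiple <- function(x, m) as.integer(ceiling(x / m) * m)

#' Padded bottleneck spatial size of a configuration
#' @param config a \code{\link{modelConfig}}.
#' @return c(lateral, Z) spatial size at the deepest encoder level.
#' @export
bottleneckShape <- function(config) {
  m <- as.integer(2^config$depth)
  as.integer(nextMultiple(config$inputShape, m) %/% m)
}

initConv <- function(inCh, outCh, bn) {
  l <- list(W = matrix(rnorm(9 * inCh * outCh, sd = sqrt(2 / (9 * inCh))),
                       9 * inCh, outCh),
            b = numeric(outCh))
  if (bn) { l$gamma <- rep(1, outCh); l$beta <- numeric(outCh) }
  l
}

## each level is the usual double-convolution block: a (strided) conv-BN-ReLU
## followed by a stride-1 conv-BN-ReLU
initBlock <- function(inCh, outCh, bn) {
  list(a = initConv(inCh, outCh, bn), b = initConv(outCh, outCh, bn))
}

#' Build an encoder-decoder model
#'
#' Weight initialization is He-normal and fully determined by \code{seed}:
#' two builds with the same config and seed are bit-identical.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed integer for weight initialization.
#' @return Model handle (class \code{CTModel}) holding parameters and config.
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ModelConfig"))
  set.seed(as.integer(seed))
  chs <- encChannels(config)
  d <- config$depth
  params <- list()
  inCh <- 3L                 # image + two coordinate channels
  for (k in seq_len(d)) {
    params[[paste0("enc", k)]] <- initBlock(inCh, chs[k], config$batchNorm)
    inCh <- chs[k]
  }
  for (k in rev(seq_len(d))) {
    skipCh <- if (k > 1) chs[k - 1] else 3L
    outCh <- if (k > 1) chs[k - 1] else config$baseChannels
    params[[paste0("dec", k)]] <- initBlock(chs[k] + skipCh, outCh,
                                            config$batchNorm)
  }
  headIn <- config$baseChannels +
    if (config$globalContext) chs[d] else 0L
  params$fin <- initConv(headIn, config$outputApBins, FALSE)
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "CTModel")
}

#' Number of trainable parameters
#' @param model a \code{CTModel}.
#' @return Integer parameter count.
#' @export
countParams <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' @export
print.CTModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "CTModel: depth %d encoder-decoder, input %s, %d AP output bins, %d parameters\n",
    cfg$depth, paste(cfg$inputShape, collapse = " x "), cfg$outputApBins,
    countParams(x)))
  invisible(x)
}

reluF <- function(x) { x[x < 0] <- 0; x }

bnFwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, hw, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = hw)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(y = array(y, d), xhat = xhat, invstd = invstd)
}

bnBwd <- function(dy, cache, gamma) {
  d <- dim(dy); hw <- d[1] * d[2]
  dyM <- matrix(dy, hw, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dyM * xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * rep(gamma, each = hw)
  dx <- (dxhat - rep(colMeans(dxhat), each = hw) -
           xhat * rep(colMeans(dxhat * xhat), each = hw)) *
    rep(cache$invstd, each = hw)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

up2Bwd <- function(dy) {
  d <- dim(dy)
  a <- dy[seq(1, d[1], 2), , , drop = FALSE] +
    dy[seq(2, d[1], 2), , , drop = FALSE]
  a[, seq(1, d[2], 2), , drop = FALSE] + a[, seq(2, d[2], 2), , drop = FALSE]
}

reflectPad2 <- function(m, targetDim) {
  p1 <- targetDim[1] - nrow(m); p2 <- targetDim[2] - ncol(m)
  if (p1 > 0) m <- rbind(m, m[nrow(m) - seq_len(p1), , drop = FALSE])
  if (p2 > 0) m <- cbind(m, m[, ncol(m) - seq_len(p2), drop = FALSE])
  m
}

convUnitFwd <- function(x, layer, stride, bn) {
  conv <- cpp_conv_fwd(x, layer$W, layer$b, stride)
  if (bn) {
    nb <- bnFwd(conv, layer$gamma, layer$beta)
    act <- reluF(nb$y)
    list(out = act, xin = x, bn = nb, mask = nb$y > 0)
  } else {
    act <- reluF(conv)
    list(out = act, xin = x, bn = NULL, mask = conv > 0)
  }
}

convUnitBwd <- function(dout, cache, layer, stride, bn) {
  dact <- dout * cache$mask
  g <- list()
  if (bn) {
    bb <- bnBwd(dact, cache$bn, layer$gamma)
    g$gamma <- bb$dgamma; g$beta <- bb$dbeta
    dconv <- bb$dx
  } else {
    dconv <- dact
  }
  cb <- cpp_conv_bwd(cache$xin, layer$W, dconv, stride)
  g$W <- cb$dW; g$b <- as.numeric(cb$db)
  list(dx = cb$dx, grads = g)
}

convBlockFwd <- function(x, block, stride, bn) {
  ua <- convUnitFwd(x, block$a, stride, bn)
  ub <- convUnitFwd(ua$out, block$b, 1L, bn)
  list(out = ub$out, a = ua, b = ub)
}

convBlockBwd <- function(dout, cache, block, stride, bn) {
  bb <- convUnitBwd(dout, cache$b, block$b, 1L, bn)
  ba <- convUnitBwd(bb$dx, cache$a, block$a, stride, bn)
  list(dx = ba$dx, grads = list(a = ba$grads, b = bb$grads))
}

forwardNet <- function(model, xMat) {
  cfg <- model$config
  if (!identical(dim(xMat), cfg$inputShape))
    stop(sprintf("input shape %s does not match the model's %s",
                 paste(dim(xMat), collapse = "x"),
                 paste(cfg$inputShape, collapse = "x")))
  d <- cfg$depth
  m <- as.integer(2^d)
  padded <- nextMultiple(cfg$inputShape, m)
  xp <- reflectPad2(xMat, padded)
  ## absolute-position cues (magnified couch edges and body contours in the
  ## localizer) are what carry table height; plain convolutions are
  ## translation-equivariant, so feed normalized coordinate channels
  ## alongside the image
  latCoord <- matrix(seq(-1, 1, length.out = nrow(xp)), nrow(xp), ncol(xp))
  zCoord <- matrix(seq(-1, 1, length.out = ncol(xp)), nrow(xp), ncol(xp),
                   byrow = TRUE)
  x <- array(c(xp, latCoord, zCoord), dim = c(dim(xp), 3L))
  skips <- vector("list", d + 1L)
  skips[[1]] <- x
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  a <- x
  for (k in seq_len(d)) {
    bl <- convBlockFwd(a, model$params[[paste0("enc", k)]], 2L, cfg$batchNorm)
    caches$enc[[k]] <- bl
    a <- bl$out
    skips[[k + 1L]] <- a
  }
  bottleneck <- a
  for (k in rev(seq_len(d))) {
    u <- up2(a)
    skip <- skips[[k]]
    cat3 <- array(c(u, skip), dim = c(dim(u)[1:2], dim(u)[3] + dim(skip)[3]))
    bl <- convBlockFwd(cat3, model$params[[paste0("dec", k)]], 1L,
                       cfg$batchNorm)
    bl$upCh <- dim(u)[3]
    caches$dec[[k]] <- bl
    a <- bl$out
  }
  decCh <- dim(a)[3]
  if (cfg$globalContext) {
    db <- dim(bottleneck)
    gvec <- colMeans(matrix(bottleneck, db[1] * db[2], db[3]))
    da <- dim(a)
    a <- array(c(a, rep(gvec, each = da[1] * da[2])),
               dim = c(da[1], da[2], da[3] + db[3]))
  }
  outFull <- cpp_conv_fwd(a, model$params$fin$W, model$params$fin$b, 1L)
  if (identical(cfg$outputActivation, "sigmoid"))
    outFull <- 1 / (1 + exp(-outFull))
  out <- outFull[seq_len(cfg$inputShape[1]), seq_len(cfg$inputShape[2]), ,
                 drop = FALSE]
  list(out = out, caches = caches, lastAct = a, padded = padded,
       outFull = outFull, decCh = decCh, bottleneckDim = dim(bottleneck))
}

backwardNet <- function(model, fw, dout) {
  cfg <- model$config
  d <- cfg$depth
  grads <- list()
  dFull <- array(0, dim = c(fw$padded, cfg$outputApBins))
  dFull[seq_len(cfg$inputShape[1]), seq_len(cfg$inputShape[2]), ] <- dout
  if (identical(cfg$outputActivation, "sigmoid"))
    dFull <- dFull * fw$outFull * (1 - fw$outFull)
  cb <- cpp_conv_bwd(fw$lastAct, model$params$fin$W, dFull, 1L)
  grads$fin <- list(W = cb$dW, b = as.numeric(cb$db))
  da <- cb$dx
  dGlobal <- NULL
  if (cfg$globalContext) {
    dcat <- da
    da <- dcat[, , seq_len(fw$decCh), drop = FALSE]
    dctx <- dcat[, , fw$decCh + seq_len(dim(dcat)[3] - fw$decCh),
                 drop = FALSE]
    dc <- dim(dctx)
    ## gradient into the pooled bottleneck features: sum over the broadcast,
    ## then spread uniformly over the pooled positions
    dgvec <- colSums(matrix(dctx, dc[1] * dc[2], dc[3]))
    bd <- fw$bottleneckDim
    dGlobal <- array(rep(dgvec / (bd[1] * bd[2]), each = bd[1] * bd[2]),
                     dim = bd)
  }
  ## decoder blocks ran k = d..1 in the forward pass, so unwind k = 1..d;
  ## dskips[[k]] collects the gradient flowing into encoder activation k-1
  ## through the skip connection of decoder level k
  dskips <- vector("list", d)
  for (k in seq_len(d)) {
    cache <- fw$caches$dec[[k]]
    bl <- convBlockBwd(da, cache, model$params[[paste0("dec", k)]], 1L,
                       cfg$batchNorm)
    grads[[paste0("dec", k)]] <- bl$grads
    upCh <- cache$upCh
    dU <- bl$dx[, , seq_len(upCh), drop = FALSE]
    dskips[[k]] <- bl$dx[, , upCh + seq_len(dim(bl$dx)[3] - upCh),
                         drop = FALSE]
    da <- up2Bwd(dU)
  }
  dnext <- da   # gradient into the deepest encoder output
  if (!is.null(dGlobal)) dnext <- dnext + dGlobal
  for (k in rev(seq_len(d))) {
    dIn <- dnext
    if (k < d) dIn <- dIn + dskips[[k + 1L]]
    bl <- convBlockBwd(dIn, fw$caches$enc[[k]],
                       model$params[[paste0("enc", k)]], 2L, cfg$batchNorm)
    grads[[paste0("enc", k)]] <- bl$grads
    dnext <- bl$dx
  }
  grads
}

## ---- optimization ---------------------------------------------------------

zerosLike <- function(p) rapply(p, function(x) x * 0, how = "replace")

adamLeaf <- function(p, g, m, v, lr, corr1, corr2, eps) {
  m2 <- 0.9 * m + 0.1 * g
  v2 <- 0.999 * v + 0.001 * g * g
  list(p = p - lr * (m2 / corr1) / (sqrt(v2 / corr2) + eps), m = m2, v = v2)
}

adamRecurse <- function(params, grads, m, v, lr, corr1, corr2, eps) {
  if (is.list(params)) {
    for (nm in names(grads)) {
      r <- adamRecurse(params[[nm]], grads[[nm]], m[[nm]], v[[nm]],
                       lr, corr1, corr2, eps)
      params[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = params, m = m, v = v)
  } else {
    adamLeaf(params, grads, m, v, lr, corr1, corr2, eps)
  }
}

adamStep <- function(params, grads, state, lr, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - 0.9^state$t
  corr2 <- 1 - 0.999^state$t
  r <- adamRecurse(params, grads, state$m, state$v, lr, corr1, corr2, eps)
  state$m <- r$m
  state$v <- r$v
  r$p
}

#' Train the encoder-decoder on preprocessed pairs
#'
#' Per-sample Adam updates on the configured loss; the per-epoch mean loss
#' is returned as the training history. A non-finite loss aborts with the
#' offending epoch and case. With a fixed build seed, train seed and
#' \code{shuffle} order, training is bit-reproducible.
#'
#' @param model a \code{\link{buildModel}} handle.
#' @param pairs list of \code{\link{TrainingPair-class}} objects with shapes
#'   matching the model config.
#' @param tc a \code{\link{trainConfig}}.
#' @return List with the trained \code{model} and numeric \code{history}
#'   (mean loss per epoch; empty for \code{epochs = 0}).
#' @export
trainModel <- function(model, pairs, tc = trainConfig()) {
  stopifnot(inherits(model, "CTModel"), inherits(tc, "TrainConfig"))
  if (!length(pairs)) stop("need at least one training pair")
  cfg <- model$config
  for (p in pairs) {
    if (!identical(dim(p@localizerIn), cfg$inputShape) ||
        !identical(dim(p@volumeOut),
                   c(cfg$outputApBins, cfg$inputShape)))
      stop("training pair shapes do not match the model configuration")
  }
  if (tc$epochs == 0L) return(list(model = model, history = numeric(0)))
  inputs <- lapply(pairs, function(p) p@localizerIn)
  targets <- lapply(pairs, function(p) aperm(p@volumeOut, c(2, 3, 1)))
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- zerosLike(model$params)
  state$v <- zerosLike(model$params)
  set.seed(tc$seed)
  history <- numeric(tc$epochs)
  n <- length(pairs)
  tailSum <- NULL
  tailFrom <- tc$epochs - tc$tailAverage + 1L
  for (e in seq_len(tc$epochs)) {
    ord <- if (tc$shuffle) sample.int(n) else seq_len(n)
    tot <- 0
    for (i in ord) {
      fw <- forwardNet(model, inputs[[i]])
      err <- fw$out - targets[[i]]
      loss <- if (tc$loss == "mse") mean(err^2) else mean(abs(err))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, case %d", e, i))
      dout <- if (tc$loss == "mse") 2 * err / length(err) else
        sign(err) / length(err)
      grads <- backwardNet(model, fw, dout)
      model$params <- adamStep(model$params, grads, state, tc$lr)
      tot <- tot + loss
    }
    history[e] <- tot / n
    if (tc$tailAverage > 0L && e >= tailFrom) {
      tailSum <- if (is.null(tailSum)) rapply(model$params, identity, how = "replace")
      else mapply2List(tailSum, model$params, `+`)
    }
  }
  if (!is.null(tailSum))
    model$params <- rapply(tailSum, function(x) x / tc$tailAverage,
                           how = "replace")
  list(model = model, history = history)
}

## elementwise combination of two parameter trees
mapply2List <- function(a, b, f) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- mapply2List(a[[nm]], b[[nm]], f)
    a
  } else f(a, b)
}

#' Predict an axial Volume3D from a preprocessed localizer
#'
#' Runs the network, permutes the coronal output (AP bins as channels) back
#' to axial axis order, clips intensities to [0,1] and attaches the
#' scanner-frame grid reconstructed from the crop record, so bounding boxes
#' measured on the prediction live in the same frame (and isocenter) as the
#' ground truth.
#'
#' @param model a trained \code{CTModel}.
#' @param localizer a \code{\link{TrainingPair-class}} (its crop record is
#'   used) or a (lateral x Z) matrix preprocessed identically to training.
#' @param cropRecord required when \code{localizer} is a bare matrix.
#' @return A \code{\link{Volume3D-class}} (axial, "predicted").
#' @export
predictVolume <- function(model, localizer, cropRecord = NULL) {
  if (is(localizer, "TrainingPair")) {
    if (is.null(cropRecord)) cropRecord <- localizer@cropRecord
    localizer <- localizer@localizerIn
  }
  if (is.null(cropRecord)) stop("cropRecord is required to place the prediction")
  fw <- forwardNet(model, localizer)
  arr <- clamp01(aperm(fw$out, c(3, 1, 2)))   # (AP, lateral, Z)
  Volume3D(arr, predictionGrid(cropRecord, dim(arr)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights and the model configuration; loading
#' restores a model producing bit-identical predictions.
#'
#' @param model a \code{CTModel}.
#' @param path checkpoint file.
#' @return \code{saveModel}: invisibly \code{path}; \code{loadModel}: the
#'   restored \code{CTModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "CTModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "CTModel")) stop("not a model checkpoint: ", path)
  model
}
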