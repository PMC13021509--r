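# Minimal 3D convolutional network framework (pure R).
#
# Provides exactly what the segmentation and registration UNets need:
# 3x3x3 convolutions (im2col + BLAS), non-affine instance normalization,
# ReLU / LeakyReLU, 2x average pooling, nearest-neighbor upsampling, skip
# concatenation, a 1x1x1 output convolution, and two heads (trainable
# multilevel activation for tissue labels, tanh for velocity fields).
# Backward passes are written by hand and verified against finite
# differences in the test suite. Everything is deterministic for a fixed
# seed on a single thread.

# memoized im2col index tables, keyed by spatial shape
.convIdxCache <- new.env(parent = emptyenv())

convIndices <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  pd <- d + 2L
  base <- voxelIndexGrid(d)
  V <- nrow(base)
  idx <- matrix(0L, V, 27L)
  k <- 0L
  for (c in 0:2) for (b in 0:2) for (a in 0:2) {
    k <- k + 1L
    idx[, k] <- 1L + (base[, 1] + a) +
      pd[1] * ((base[, 2] + b) + pd[2] * (base[, 3] + c))
  }
  .convIdxCache[[key]] <- idx
  idx
}

padSpatial <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1:3] + 2L, d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  xp
}

# x: (X, Y, Z, Cin); W: (27 * Cin) x Cout matrix; b: numeric(Cout)
conv3Forward <- function(x, W, b) {
  d <- dim(x)
  cin <- d[4]
  idx <- convIndices(d[1:3])
  V <- nrow(idx)
  xp <- padSpatial(x)
  npad <- prod(d[1:3] + 2L)
  M <- matrix(0, V, 27L * cin)
  for (c in seq_len(cin)) {
    xc <- xp[, , , c]
    M[, (c - 1L) * 27L + (1:27)] <- xc[idx]
  }
  y <- M %*% W
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(d[1:3], ncol(W))), M = M)
}

conv3Backward <- function(dy, cache, W, inShape) {
  d <- inShape                      # (X, Y, Z, Cin)
  cin <- d[4]
  V <- prod(d[1:3])
  dyM <- matrix(dy, V, length(dy) / V)
  dW <- crossprod(cache$M, dyM)
  db <- colSums(dyM)
  dM <- dyM %*% t(W)
  idx <- convIndices(d[1:3])
  pd <- d[1:3] + 2L
  dx <- array(0, d)
  for (c in seq_len(cin)) {
    dxc <- numeric(prod(pd))
    block <- dM[, (c - 1L) * 27L + (1:27), drop = FALSE]
    for (k in 1:27) {
      ii <- idx[, k]
      dxc[ii] <- dxc[ii] + block[, k]
    }
    dxc <- array(dxc, pd)
    dx[, , , c] <- dxc[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  }
  list(dx = dx, dW = dW, db = db)
}

instNormForward <- function(x, eps = 1e-5) {
  d <- dim(x)
  V <- prod(d[1:3])
  xm <- matrix(x, V, d[4])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  list(y = array(xhat, d), xhat = xhat, istd = istd)
}

instNormBackward <- function(dy, cache, shape) {
  V <- prod(shape[1:3])
  dyM <- matrix(dy, V, shape[4])
  mDy <- colMeans(dyM)
  mDyXhat <- colMeans(dyM * cache$xhat)
  dx <- sweep(dyM, 2, mDy) - sweep(cache$xhat, 2, mDyXhat, "*")
  dx <- sweep(dx, 2, cache$istd, "*")
  array(dx, shape)
}

actForward <- function(x, kind) {
  if (kind == "relu") {
    y <- pmax(x, 0)
  } else {                           # leakyrelu, slope 0.01
    y <- ifelse(x > 0, x, 0.01 * x)
  }
  list(y = array(y, dim(x)), x = x)
}

actBackward <- function(dy, cache, kind) {
  g <- if (kind == "relu") (cache$x > 0) * 1 else ifelse(cache$x > 0, 1, 0.01)
  dy * g
}

avgPool2Forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], 2); i2 <- seq(1, d[2], 2); i3 <- seq(1, d[3], 2)
  y <- (x[i1, i2, i3, , drop = FALSE]       + x[i1 + 1, i2, i3, , drop = FALSE] +
        x[i1, i2 + 1, i3, , drop = FALSE]   + x[i1, i2, i3 + 1, , drop = FALSE] +
        x[i1 + 1, i2 + 1, i3, , drop = FALSE] + x[i1 + 1, i2, i3 + 1, , drop = FALSE] +
        x[i1, i2 + 1, i3 + 1, , drop = FALSE] +
        x[i1 + 1, i2 + 1, i3 + 1, , drop = FALSE]) / 8
  y
}

avgPool2Backward <- function(dy, inShape) {
  r1 <- rep(seq_len(inShape[1] / 2), each = 2)
  r2 <- rep(seq_len(inShape[2] / 2), each = 2)
  r3 <- rep(seq_len(inShape[3] / 2), each = 2)
  dy[r1, r2, r3, , drop = FALSE] / 8
}

upsample2Forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2Backward <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], 2); i2 <- seq(1, d[2], 2); i3 <- seq(1, d[3], 2)
  dy[i1, i2, i3, , drop = FALSE]       + dy[i1 + 1, i2, i3, , drop = FALSE] +
  dy[i1, i2 + 1, i3, , drop = FALSE]   + dy[i1, i2, i3 + 1, , drop = FALSE] +
  dy[i1 + 1, i2 + 1, i3, , drop = FALSE] + dy[i1 + 1, i2, i3 + 1, , drop = FALSE] +
  dy[i1, i2 + 1, i3 + 1, , drop = FALSE] + dy[i1 + 1, i2 + 1, i3 + 1, , drop = FALSE]
}

#' Build a small 3D UNet
#'
#' Encoder-decoder with skip connections: `depth` pooling levels, channel
#' count doubling per level starting at `baseChannels`, one 3x3x3
#' convolution + instance normalization + activation per level, 2x average
#' pooling down and nearest-neighbor upsampling up, and a 1x1x1 output
#' convolution feeding the head. Heads: `"multilevel"` (single channel
#' through the trainable six-sigmoid activation, for tissue labels),
#' `"tanh"` (bounded (-1, 1) outputs, for velocity fields), or `"linear"`.
#'
#' @param inChannels,outChannels input/output channel counts (`outChannels`
#'   is forced to 1 for the multilevel head).
#' @param depth number of pooling levels; input dims must be divisible by
#'   `2^depth`.
#' @param baseChannels channels at the top level (doubling per level).
#' @param activation `"relu"` (segmentation) or `"leakyrelu"` (registration).
#' @param head `"multilevel"`, `"tanh"` or `"linear"`.
#' @param alphaInit initial multilevel slope parameter.
#' @param seed RNG seed for He-style weight initialization.
#' @return a network object (list with class `"vbmnetUNet"`).
#' @export
buildUNet <- function(inChannels, outChannels = 1L, depth = 2L,
                      baseChannels = 4L, activation = c("relu", "leakyrelu"),
                      head = c("multilevel", "tanh", "linear"),
                      alphaInit = 4, seed = 1L) {
  activation <- match.arg(activation)
  head <- match.arg(head)
  if (head == "multilevel") outChannels <- 1L
  ch <- baseChannels * 2^(0:depth)
  params <- list()
  withSeed(seed, {
    heConv <- function(cin, cout)
      matrix(stats::rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
             27 * cin, cout)
    for (i in seq_len(depth + 1L)) {
      cin <- if (i == 1L) inChannels else ch[i - 1L]
      params[[sprintf("enc%d_W", i)]] <- heConv(cin, ch[i])
      params[[sprintf("enc%d_b", i)]] <- numeric(ch[i])
    }
    for (i in seq_len(depth)) {
      cin <- ch[i + 1L] + ch[i]   # upsampled + skip
      params[[sprintf("dec%d_W", i)]] <- heConv(cin, ch[i])
      params[[sprintf("dec%d_b", i)]] <- numeric(ch[i])
    }
    params$final_W <- matrix(stats::rnorm(ch[1] * outChannels,
                                          sd = sqrt(2 / ch[1])),
                             ch[1], outChannels)
    params$final_b <- numeric(outChannels)
    if (head == "multilevel") {
      params$final_b <- 1.5       # start mid-range of the label scale
      params$alpha <- alphaInit
    }
  })
  structure(list(params = params, depth = depth, inChannels = inChannels,
                 outChannels = outChannels, activation = activation,
                 head = head, channels = ch),
            class = "vbmnetUNet")
}

convBlockForward <- function(net, x, wName, bName) {
  cv <- conv3Forward(x, net$params[[wName]], net$params[[bName]])
  nn <- instNormForward(cv$y)
  ac <- actForward(nn$y, net$activation)
  list(y = ac$y, conv = cv, norm = nn, act = ac, inShape = dim(x))
}

convBlockBackward <- function(net, dy, cache, wName) {
  dy <- actBackward(dy, cache$act, net$activation)
  dy <- instNormBackward(dy, cache$norm, dim(cache$act$x))
  conv3Backward(dy, cache$conv, net$params[[wName]], cache$inShape)
}

#' Forward pass of a UNet
#'
#' @param net network from [buildUNet()].
#' @param x input array (X, Y, Z, Cin) or 3D array for single-channel input.
#' @param wantCache keep intermediate activations for [unetBackward()].
#' @return list with `y` (output) and, if requested, `cache`.
#' @export
unetForward <- function(net, x, wantCache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (any(d[1:3] %% 2^net$depth != 0))
    stop("input dims must be divisible by 2^depth = ", 2^net$depth)
  cache <- list(enc = vector("list", net$depth + 1L),
                dec = vector("list", net$depth), skipShape = list())
  h <- x
  for (i in seq_len(net$depth)) {
    blk <- convBlockForward(net, h, sprintf("enc%d_W", i), sprintf("enc%d_b", i))
    cache$enc[[i]] <- blk
    h <- avgPool2Forward(blk$y)
  }
  blk <- convBlockForward(net, h, sprintf("enc%d_W", net$depth + 1L),
                          sprintf("enc%d_b", net$depth + 1L))
  cache$enc[[net$depth + 1L]] <- blk
  h <- blk$y
  for (i in rev(seq_len(net$depth))) {
    up <- upsample2Forward(h)
    skip <- cache$enc[[i]]$y
    hcat <- array(c(up, skip), c(dim(up)[1:3], dim(up)[4] + dim(skip)[4]))
    blk <- convBlockForward(net, hcat, sprintf("dec%d_W", i),
                            sprintf("dec%d_b", i))
    cache$dec[[i]] <- c(blk, list(upCh = dim(up)[4]))
    h <- blk$y
  }
  V <- prod(dim(h)[1:3])
  hM <- matrix(h, V, dim(h)[4])
  raw <- sweep(hM %*% net$params$final_W, 2, net$params$final_b, "+")
  raw <- array(raw, c(dim(h)[1:3], net$outChannels))
  y <- switch(net$head,
    multilevel = multilevelActivation(array(raw, dim(raw)[1:3]),
                                      net$params$alpha),
    tanh = tanh(raw),
    linear = raw)
  cache$hM <- hM
  cache$raw <- raw
  cache$topShape <- dim(h)
  list(y = y, cache = if (wantCache) cache else NULL)
}

#' Backward pass of a UNet
#'
#' @param net network object.
#' @param cache cache from `unetForward(..., wantCache = TRUE)`.
#' @param dy gradient of the loss with respect to the network output.
#' @return named list of parameter gradients (same names as `net$params`).
#' @export
unetBackward <- function(net, cache, dy) {
  grads <- list()
  raw <- cache$raw
  if (net$head == "multilevel") {
    mb <- multilevelBackward(array(raw, dim(raw)[1:3]), net$params$alpha,
                             array(dy, dim(raw)[1:3]))
    dRaw <- array(mb$dx, dim(raw))
    grads$alpha <- mb$dalpha
  } else if (net$head == "tanh") {
    dRaw <- dy * (1 - tanh(raw)^2)
  } else dRaw <- dy
  V <- prod(dim(raw)[1:3])
  dRawM <- matrix(dRaw, V, net$outChannels)
  grads$final_W <- crossprod(cache$hM, dRawM)
  grads$final_b <- colSums(dRawM)
  dh <- array(dRawM %*% t(net$params$final_W), cache$topShape)
  dSkip <- vector("list", net$depth)
  for (i in seq_len(net$depth)) {
    bk <- convBlockBackward(net, dh, cache$dec[[i]], sprintf("dec%d_W", i))
    grads[[sprintf("dec%d_W", i)]] <- bk$dW
    grads[[sprintf("dec%d_b", i)]] <- bk$db
    upCh <- cache$dec[[i]]$upCh
    dUp <- bk$dx[, , , seq_len(upCh), drop = FALSE]
    dSkip[[i]] <- bk$dx[, , , upCh + seq_len(dim(bk$dx)[4] - upCh),
                        drop = FALSE]
    dh <- upsample2Backward(dUp)
  }
  for (i in rev(seq_len(net$depth + 1L))) {
    if (i <= net$depth) dh <- avgPool2Backward(dh, dim(cache$enc[[i]]$y)) +
        dSkip[[i]]
    bk <- convBlockBackward(net, dh, cache$enc[[i]], sprintf("enc%d_W", i))
    grads[[sprintf("enc%d_W", i)]] <- bk$dW
    grads[[sprintf("enc%d_b", i)]] <- bk$db
    dh <- bk$dx
  }
  grads
}

#' Predict with a UNet (no cache)
#' @param net network object.
#' @param x input array.
#' @return network output.
#' @export
unetPredict <- function(net, x) unetForward(net, x, wantCache = FALSE)$y

# ---- losses ---------------------------------------------------------------

maeLossGrad <- function(pred, target) {
  n <- length(pred)
  list(loss = mean(abs(pred - target)),
       dpred = array(sign(pred - target) / n, dim(pred)))
}

mseLossGrad <- function(pred, target) {
  n <- length(pred)
  list(loss = mean((pred - target)^2),
       dpred = array(2 * (pred - target) / n, dim(pred)))
}

# ---- optimizer and schedule -----------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' One-cycle learning-rate schedule
#'
#' Cosine warm-up from `lrMax / div` to `lrMax` over the first
#' `pctStart` fraction of steps, then cosine annealing down to
#' `lrMax / div / divFinal`. The trace has a single maximum, exactly
#' `lrMax`, at the end of the warm-up phase.
#'
#' @param nSteps total number of optimizer steps.
#' @param lrMax maximal learning rate (default 0.001).
#' @param pctStart warm-up fraction.
#' @param div,divFinal initial and final divisors.
#' @return numeric vector of length `nSteps`.
#' @export
oneCycleLR <- function(nSteps, lrMax = 1e-3, pctStart = 0.25, div = 25,
                       divFinal = 1e5) {
  lr0 <- lrMax / div
  lrEnd <- lr0 / divFinal
  s1 <- max(1L, floor(pctStart * nSteps))
  t <- seq_len(nSteps)
  ifelse(t <= s1,
         lr0 + (lrMax - lr0) * (1 - cos(pi * t / s1)) / 2,
         lrEnd + (lrMax - lrEnd) *
           (1 + cos(pi * (t - s1) / max(1L, nSteps - s1))) / 2)
}
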