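# Registration network: a UNet mapping (GM, WM, template GM, template WM)
# to the pair of half velocity fields, trained against distilled targets.

#' Build the registration network
#'
#' UNet with LeakyReLU activations and a tanh final layer so the predicted
#' velocity components stay strictly inside (-1, 1), the normalized
#' coordinate range. Predicts 6 channels: the forward half field (3) and
#' the backward half field (3); with `antisymmetric = TRUE` only 3 channels
#' are predicted and the backward field is their negation.
#'
#' @param config list: `depth`, `baseChannels`, `antisymmetric`, `seed`.
#' @return network object with class `"vbmnetRegNet"`.
#' @export
buildRegNet <- function(config = list()) {
  cfg <- utils::modifyList(list(depth = 2L, baseChannels = 4L,
                                antisymmetric = FALSE, seed = 1L), config)
  outCh <- if (cfg$antisymmetric) 3L else 6L
  net <- buildUNet(inChannels = 4L, outChannels = outCh, depth = cfg$depth,
                   baseChannels = cfg$baseChannels, activation = "leakyrelu",
                   head = "tanh", seed = cfg$seed)
  # initialize the velocity head near zero so the untrained network
  # predicts a near-identity deformation (standard for registration nets)
  net$params$final_W <- net$params$final_W * 0.01
  net$antisymmetric <- cfg$antisymmetric
  class(net) <- c("vbmnetRegNet", class(net))
  net
}

# Stack the 4 input channels for the registration net.
regInput <- function(gm, wm, templateGm, templateWm) {
  arrs <- lapply(list(gm, wm, templateGm, templateWm),
                 function(v) if (is(v, "Volume")) v@data else v)
  d <- dim(arrs[[1]])
  array(unlist(arrs), c(d, 4L))
}

# Network output -> VelocityPair
regOutputToPair <- function(net, y) {
  if (isTRUE(net$antisymmetric)) {
    VelocityPair(y, -y)
  } else {
    d <- dim(y)
    VelocityPair(y[, , , 1:3, drop = FALSE],
                 y[, , , 4:6, drop = FALSE])
  }
}

#' Predict a velocity pair for one image pair
#'
#' @param net a [buildRegNet()] network.
#' @param gm,wm moving GM/WM probability [Volume-class] maps.
#' @param templateGm,templateWm template maps on the same grid.
#' @return [VelocityPair-class].
#' @export
predictVelocity <- function(net, gm, wm, templateGm, templateWm) {
  regOutputToPair(net, unetPredict(net, regInput(gm, wm, templateGm, templateWm)))
}

#' Train the registration network on supervised targets
#'
#' Minimizes the supervised velocity loss L_v over pairs of (input
#' channels, supervised target) with Adam under the one-cycle
#' learning-rate schedule (maximal rate 0.001 by default). The richer
#' objectives ([supervisedFullLoss()], [synLoss()]) are evaluation
#' objectives here: their gradients would require differentiating through
#' scaling and squaring, and the velocity-matching term is what drives
#' the distillation-supervised fit. No data augmentation is applied
#' during registration training.
#'
#' @param pairs list of `list(input = X*Y*Z*4 array, target =`
#'   [supervisedTarget()] `)`.
#' @param config list: `epochs` (default 50), `lrMax` (0.001), `depth`,
#'   `baseChannels`, `antisymmetric`.
#' @param seed RNG seed controlling initialization and pair order.
#' @return list with `net`, `log` (per-step loss and learning rate).
#' @export
trainRegistration <- function(pairs, config = list(), seed = 1L) {
  if (length(pairs) < 1) stop("empty dataset")
  cfg <- utils::modifyList(list(epochs = 50L, lrMax = 1e-3, depth = 2L,
                                baseChannels = 4L, antisymmetric = FALSE),
                           config)
  net <- buildRegNet(list(depth = cfg$depth, baseChannels = cfg$baseChannels,
                          antisymmetric = cfg$antisymmetric, seed = seed))
  nSteps <- cfg$epochs * length(pairs)
  lrs <- oneCycleLR(nSteps, cfg$lrMax)
  state <- adamInit(net$params)
  losses <- numeric(nSteps)
  step <- 0L
  order <- withSeed(seed, replicate(cfg$epochs, sample(length(pairs)),
                                    simplify = FALSE))
  for (ep in seq_len(cfg$epochs)) {
    for (i in order[[ep]]) {
      step <- step + 1L
      p <- pairs[[i]]
      fwd <- unetForward(net, p$input, wantCache = TRUE)
      pred <- regOutputToPair(net, fwd$y)
      tgt <- p$target$vTarget
      # dL_v/dy: mean over entries of each half field
      nF <- length(pred@vFwd)
      dF <- 2 * (pred@vFwd - tgt@vFwd) / nF
      dB <- 2 * (pred@vBwd - tgt@vBwd) / nF
      lv <- mean((pred@vFwd - tgt@vFwd)^2) + mean((pred@vBwd - tgt@vBwd)^2)
      if (isTRUE(net$antisymmetric)) {
        dy <- dF - dB
      } else {
        dy <- array(c(dF, dB), dim(fwd$y))
      }
      losses[step] <- lv
      grads <- unetBackward(net, fwd$cache, dy)
      upd <- adamStep(net$params, grads, state, lrs[step])
      net$params <- upd$params
      state <- upd$state
    }
  }
  list(net = net, log = list(loss = losses, lr = lrs))
}
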