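# Cascaded two-stage segmentation training and prediction.
#
# Stage 1: a UNet on the whole image at reduced resolution. Stage 2: one
# UNet per effective patch position (18 of 27, via sagittal weight
# sharing), warm-started from a foundation model trained across all
# effective positions. MAE loss against the continuous label map, the
# trainable multilevel activation as output head, one-cycle learning-rate
# schedule (maximal rate 0.001), batch size 1 (stage 1) / per-patch steps
# (stage 2). Desk-scale defaults keep everything CPU-trainable.

#' Segmentation training configuration
#'
#' @param patchShape patch shape for stage 2.
#' @param stage1Scale integer downsampling factor of the stage-1 grid.
#' @param stage1Epochs,foundationEpochs,finetuneEpochs epoch counts
#'   (reference-scale defaults are 60 / 2 / 20; the desk default scales
#'   the work to single-CPU runs).
#' @param depth,baseChannels UNet size.
#' @param lrMax one-cycle maximal learning rate.
#' @param finetuneLrMax peak rate for per-position fine-tuning; defaults to
#'   `lrMax / 4` so the warm start from the foundation model is refined
#'   rather than destroyed.
#' @param alphaInit initial multilevel slope.
#' @param flipAugment use sagittal flip augmentation for patches on the
#'   midline column (always disabled for lateral patches).
#' @return config list.
#' @export
segTrainConfig <- function(patchShape = c(16L, 16L, 16L), stage1Scale = 2L,
                           stage1Epochs = 8L, foundationEpochs = 2L,
                           finetuneEpochs = 4L, depth = 2L,
                           baseChannels = 4L, lrMax = 1e-3,
                           finetuneLrMax = lrMax / 4, alphaInit = 4,
                           flipAugment = FALSE) {
  list(patchShape = as.integer(patchShape), stage1Scale = as.integer(stage1Scale),
       stage1Epochs = as.integer(stage1Epochs),
       foundationEpochs = as.integer(foundationEpochs),
       finetuneEpochs = as.integer(finetuneEpochs), depth = as.integer(depth),
       baseChannels = as.integer(baseChannels), lrMax = lrMax,
       finetuneLrMax = finetuneLrMax, alphaInit = alphaInit,
       flipAugment = flipAugment)
}

# Block-average downsampling by an integer factor (stage-1 input).
downsampleBlock <- function(arr, factor) {
  if (factor == 1L) return(arr)
  d <- dim(arr)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  out <- array(0, dn)
  for (a in 0:(factor - 1)) for (b in 0:(factor - 1)) for (c in 0:(factor - 1))
    out <- out + arr[seq(1 + a, d[1], factor), seq(1 + b, d[2], factor),
                     seq(1 + c, d[3], factor), drop = FALSE]
  out / factor^3
}

segStep <- function(net, state, x, target, lr) {
  fwd <- unetForward(net, x, wantCache = TRUE)
  ml <- maeLossGrad(fwd$y, target)
  grads <- unetBackward(net, fwd$cache, ml$dpred)
  upd <- adamStep(net$params, grads, state, lr)
  net$params <- upd$params
  list(net = net, state = upd$state, loss = ml$loss)
}

#' Train the cascaded segmentation model bank
#'
#' @param dataset list of `list(image = Volume, labels = TissueLabelMap)`
#'   on the analysis grid, intensity-normalized.
#' @param config a [segTrainConfig()].
#' @param seed RNG seed (initialization and sample order).
#' @return model bank: list with `stage1`, `patchModels` (one per
#'   effective position), `grid` ([PatchGrid-class]), `config`, `log`
#'   (losses and learning-rate traces per phase).
#' @export
trainCascade <- function(dataset, config = segTrainConfig(), seed = 1L) {
  if (length(dataset) < 1) stop("empty dataset")
  gridShape <- dim(dataset[[1]]$image@data)
  masks <- lapply(dataset, function(s) s$labels@data > 0.5)
  grid <- optimizePatchPositions(masks, config$patchShape)

  log <- list()
  # ---- stage 1: full view at reduced resolution ---------------------------
  s1net <- buildUNet(1L, depth = config$depth, baseChannels = config$baseChannels,
                     activation = "relu", head = "multilevel",
                     alphaInit = config$alphaInit, seed = deriveSeed(seed, 1))
  s1state <- adamInit(s1net$params)
  n1 <- config$stage1Epochs * length(dataset)
  lr1 <- oneCycleLR(n1, config$lrMax)
  loss1 <- numeric(n1)
  step <- 0L
  ord <- withSeed(deriveSeed(seed, 2),
                  replicate(config$stage1Epochs, sample(length(dataset)),
                            simplify = FALSE))
  for (ep in seq_len(config$stage1Epochs)) for (i in ord[[ep]]) {
    step <- step + 1L
    x <- downsampleBlock(dataset[[i]]$image@data, config$stage1Scale)
    y <- downsampleBlock(dataset[[i]]$labels@data, config$stage1Scale)
    st <- segStep(s1net, s1state, x, y, lr1[step])
    s1net <- st$net; s1state <- st$state; loss1[step] <- st$loss
  }
  log$stage1 <- list(loss = loss1, lr = lr1)

  # stage-1 predictions upsampled to the analysis grid, cached per sample
  s1preds <- lapply(dataset, function(s)
    upsampleToShape(unetPredict(s1net, downsampleBlock(s$image@data,
                                                       config$stage1Scale)),
                    gridShape))

  nEff <- max(grid@modelIndex)
  effPatches <- which(!grid@flip)           # one representative per model
  lateral <- rep(FALSE, nEff)
  combo <- voxelIndexGrid(c(3L, 3L, 3L))
  for (p in effPatches) lateral[grid@modelIndex[p]] <- combo[p, 1] != 1L

  patchInput <- function(i, p) {
    o <- grid@origins[p, ]
    P <- grid@patchShape
    array(c(extractPatch(dataset[[i]]$image@data, o, P),
            extractPatch(s1preds[[i]], o, P)), c(P, 2L))
  }
  patchTarget <- function(i, p)
    extractPatch(dataset[[i]]$labels@data, grid@origins[p, ], grid@patchShape)

  # ---- foundation model across all effective positions --------------------
  fnet <- buildUNet(2L, depth = config$depth, baseChannels = config$baseChannels,
                    activation = "relu", head = "multilevel",
                    alphaInit = config$alphaInit, seed = deriveSeed(seed, 3))
  fstate <- adamInit(fnet$params)
  combos <- expand.grid(i = seq_along(dataset), p = effPatches)
  nf <- config$foundationEpochs * nrow(combos)
  lrf <- oneCycleLR(nf, config$lrMax)
  lossf <- numeric(nf)
  step <- 0L
  ordf <- withSeed(deriveSeed(seed, 4),
                   replicate(config$foundationEpochs, sample(nrow(combos)),
                             simplify = FALSE))
  for (ep in seq_len(config$foundationEpochs)) for (r in ordf[[ep]]) {
    step <- step + 1L
    st <- segStep(fnet, fstate, patchInput(combos$i[r], combos$p[r]),
                  patchTarget(combos$i[r], combos$p[r]), lrf[step])
    fnet <- st$net; fstate <- st$state; lossf[step] <- st$loss
  }
  log$foundation <- list(loss = lossf, lr = lrf)

  # ---- per-position fine-tuning -------------------------------------------
  patchModels <- vector("list", nEff)
  log$finetune <- vector("list", nEff)
  for (m in seq_len(nEff)) {
    p <- effPatches[[m]]
    stopifnot(grid@modelIndex[p] == m)
    net <- fnet
    state <- adamInit(net$params)
    nft <- config$finetuneEpochs * length(dataset)
    lrt <- oneCycleLR(nft, config$finetuneLrMax %||% config$lrMax)
    losst <- numeric(nft)
    step <- 0L
    ordm <- withSeed(deriveSeed(seed, 100 + m),
                     replicate(config$finetuneEpochs, sample(length(dataset)),
                               simplify = FALSE))
    doFlip <- withSeed(deriveSeed(seed, 200 + m),
                       stats::runif(nft) < 0.5) &
              config$flipAugment & !lateral[m]
    for (ep in seq_len(config$finetuneEpochs)) for (i in ordm[[ep]]) {
      step <- step + 1L
      x <- patchInput(i, p)
      y <- patchTarget(i, p)
      if (doFlip[step]) {
        x <- x[rev(seq_len(dim(x)[1])), , , , drop = FALSE]
        y <- flipAxis(y, 1L)
      }
      st <- segStep(net, state, x, y, lrt[step])
      net <- st$net; state <- st$state; losst[step] <- st$loss
    }
    patchModels[[m]] <- net
    log$finetune[[m]] <- list(loss = losst, lr = lrt)
  }
  list(stage1 = s1net, patchModels = patchModels, grid = grid,
       config = config, log = log)
}

#' Predict a tissue label map with a trained model bank
#'
#' Runs stage 1 at reduced resolution, upsamples its prediction
#' (trilinear), and accumulates the patchwise stage-2 predictions with
#' Gaussian importance weighting and hemispheric weight sharing.
#'
#' @param bank model bank from [trainCascade()].
#' @param v normalized [Volume-class] on the analysis grid.
#' @return [TissueLabelMap-class].
#' @export
predictTissue <- function(bank, v) {
  s1 <- upsampleToShape(
    unetPredict(bank$stage1, downsampleBlock(v@data, bank$config$stage1Scale)),
    dim(v@data))
  runPatchwise(bank$patchModels, v, s1, bank$grid)
}
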