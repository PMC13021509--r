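# Patch-grid construction and optimization, Gaussian importance weighting,
# and patchwise prediction with hemispheric weight sharing.

# Initial regular 3-per-axis origins for one axis: ends plus centered
# middle. When 3P < D the grid has gaps; coverage of actual tissue is
# checked downstream, which names any uncovered voxel.
initialAxisOrigins <- function(D, P) {
  if (P > D) stop("patch size ", P, " exceeds the axis extent ", D)
  as.integer(c(0L, floor((D - P) / 2), D - P))
}

#' Construct the patch grid over an analysis grid
#'
#' Subdivides the analysis grid into 3 x 3 x 3 = 27 patches. Right-hemisphere
#' patches (sagittal index 2) share the model of their mirrored left partner
#' and carry a flip flag, leaving 18 effective model positions.
#'
#' @param gridShape integer(3), e.g. `c(336, 384, 336)`.
#' @param patchShape integer(3), e.g. `c(128, 128, 128)`.
#' @param origins optional 27 x 3 matrix of 0-based origins (e.g. from
#'   [optimizePatchPositions()]); defaults to the regular starting grid.
#' @return a [PatchGrid-class].
#' @export
buildPatchGrid <- function(gridShape, patchShape, origins = NULL) {
  gridShape <- as.integer(gridShape); patchShape <- as.integer(patchShape)
  ax <- lapply(1:3, function(a) initialAxisOrigins(gridShape[a], patchShape[a]))
  combo <- voxelIndexGrid(c(3L, 3L, 3L))  # (ix, iy, iz), ix fastest
  if (is.null(origins)) {
    origins <- cbind(ax[[1]][combo[, 1] + 1L], ax[[2]][combo[, 2] + 1L],
                     ax[[3]][combo[, 3] + 1L])
  }
  storage.mode(origins) <- "integer"
  ixEff <- combo[, 1]
  ixEff[ixEff == 2L] <- 0L       # mirror sagittal index 2 onto 0
  effKey <- ixEff + 2L * (combo[, 2] + 3L * combo[, 3])
  modelIndex <- as.integer(match(effKey, sort(unique(effKey))))
  new("PatchGrid", origins = origins, patchShape = patchShape,
      gridShape = gridShape, modelIndex = modelIndex,
      flip = combo[, 1] == 2L)
}

# ---- patch-position optimization ------------------------------------------

# n-dimensional core (2D toys and the 3D grid share it). `maskUnion` is a
# logical array; patches form a 3-per-axis grid; mirror lockstep couples
# sagittal (axis 1) indices 0 and 2. Axis sweep order is (1, 2, ..., ndim),
# one voxel per pass, until a full pass yields no motion.
optimizePatchGridCore <- function(maskUnion, patchShape) {
  d <- dim(maskUnion)
  nd <- length(d)
  patchShape <- as.integer(rep_len(patchShape, nd))
  axOrig <- lapply(seq_len(nd), function(a) initialAxisOrigins(d[a], patchShape[a]))
  combo <- as.matrix(expand.grid(lapply(seq_len(nd), function(a) 0:2)))[,
             seq_len(nd), drop = FALSE]  # axis-1 index varies fastest
  colnames(combo) <- NULL
  nP <- nrow(combo)
  origins <- vapply(seq_len(nd), function(a) axOrig[[a]][combo[, a] + 1L],
                    integer(nP))
  origins <- matrix(as.integer(origins), nP, nd)

  covered <- function(orig) {
    cov <- array(FALSE, d)
    for (p in seq_len(nP)) {
      idx <- lapply(seq_len(nd), function(a) orig[p, a] + seq_len(patchShape[a]))
      cov <- do.call(`[<-`, c(list(cov), idx, list(TRUE)))
    }
    cov
  }
  if (any(maskUnion & !covered(origins))) {
    bad <- which(maskUnion & !covered(origins), arr.ind = TRUE)[1, ]
    stop("tissue voxel not coverable by the starting grid at index (",
         paste(bad, collapse = ", "), ")")
  }

  center <- (d - 1) / 2
  # leaders: patches with axis-1 index 0 or 1; index-2 patches follow their
  # mirrored partner
  leader <- which(combo[, 1] <= 1L)
  followerOf <- function(p) {
    key <- combo[p, ]; key[1] <- 2L
    which(apply(combo, 1, function(r) all(r == key)))[1]
  }

  repeat {
    moved <- FALSE
    for (p in leader) {
      isPair <- combo[p, 1] == 0L
      q <- if (isPair) followerOf(p) else NA_integer_
      for (a in seq_len(nd)) {
        pc <- origins[p, a] + (patchShape[a] - 1) / 2
        step <- sign(center[a] - pc)
        if (a == 1L && combo[p, 1] == 1L) step <- 0  # center column stays centered
        if (step == 0) next
        trial <- origins
        trial[p, a] <- trial[p, a] + step
        if (isPair) {
          if (a == 1L) trial[q, a] <- trial[q, a] - step  # mirrored move
          else trial[q, a] <- trial[q, a] + step          # lockstep move
        }
        if (any(trial < 0) ||
            any(sweep(trial, 2, d - patchShape, ">"))) next
        if (!any(maskUnion & !covered(trial))) {
          origins <- trial
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  origins
}

#' Optimize patch positions toward the image center
#'
#' Starting from the regular 3 x 3 x 3 grid, each patch is moved stepwise by
#' one voxel toward the image center for as long as every tissue voxel of
#' every supplied mask stays covered by at least one patch. Left-hemisphere
#' patches move in lockstep with their mirrored right-hemisphere partners so
#' that the sagittal-flip equivalence stays exact.
#'
#' @param tissueMasks list of binary [Volume-class] objects or arrays on the
#'   analysis grid (2D arrays are accepted for scaled-down checks).
#' @param patchShape patch shape (scalar or per-axis).
#' @return for 3D input, a [PatchGrid-class]; for 2D input, the origin matrix.
#' @export
optimizePatchPositions <- function(tissueMasks, patchShape) {
  arrs <- lapply(tissueMasks, function(m) {
    a <- if (is(m, "Volume")) m@data else m
    a > 0
  })
  u <- Reduce(`|`, arrs)
  origins <- optimizePatchGridCore(u, patchShape)
  if (length(dim(u)) == 3L)
    buildPatchGrid(dim(u), rep_len(as.integer(patchShape), 3L), origins)
  else origins
}

#' Gaussian importance weights for a patch
#'
#' Weight is maximal at the patch center and decreases toward the faces;
#' sigma defaults to patchShape / 8 per axis, following the patch-based
#' segmentation convention.
#'
#' @param patchShape integer(3).
#' @param sigma per-axis standard deviation in voxels.
#' @return array of positive weights of shape `patchShape`.
#' @export
gaussianImportance <- function(patchShape, sigma = patchShape / 8) {
  sigma <- rep_len(sigma, length(patchShape))
  axes <- lapply(seq_along(patchShape), function(a) {
    x <- seq_len(patchShape[a]) - 1 - (patchShape[a] - 1) / 2
    exp(-x^2 / (2 * sigma[a]^2))
  })
  w <- axes[[1]]
  for (a in 2:length(axes)) w <- outer(w, axes[[a]])
  array(w, patchShape)
}

# Extract a patch (0-based origin) from a 3D array.
extractPatch <- function(arr, origin, shape) {
  arr[origin[1] + seq_len(shape[1]), origin[2] + seq_len(shape[2]),
      origin[3] + seq_len(shape[3]), drop = FALSE]
}

# Trilinear upsampling of a full-volume array to a target shape.
upsampleToShape <- function(arr, targetShape) {
  idx <- voxelIndexGrid(targetShape)
  src <- sweep(idx, 2, (dim(arr) - 1) / pmax(targetShape - 1, 1), "*")
  array(sampleTrilinear(arr, src, fill = "clamp"), targetShape)
}

#' Patchwise prediction with Gaussian importance accumulation
#'
#' Runs the effective model of every patch position over the analysis grid
#' and accumulates the predictions into a full-size label map, weighting
#' each patch voxel by its Gaussian importance and normalizing the weights
#' to sum to one per voxel. Right-hemisphere patches are flipped along the
#' sagittal axis, predicted with the shared left-hemisphere model, and the
#' prediction is flipped back.
#'
#' @param models list of effective models (length =
#'   `max(grid@modelIndex)`); each is either a trained network (see
#'   [buildSegNet()]) or a function `f(patchInputArray)` returning a patch
#'   prediction (used in tests).
#' @param v normalized [Volume-class] on the analysis grid.
#' @param stage1Pred [TissueLabelMap-class] or array: the stage-1 prediction,
#'   upsampled to the analysis grid and concatenated as a second input
#'   channel. `NULL` for single-channel models.
#' @param grid a [PatchGrid-class].
#' @return [TissueLabelMap-class] on the analysis grid.
#' @export
runPatchwise <- function(models, v, stage1Pred, grid) {
  nEff <- max(grid@modelIndex)
  if (length(models) != nEff)
    stop("model bank size ", length(models), " does not match the ",
         nEff, " effective patch positions")
  img <- v@data
  s1 <- if (is.null(stage1Pred)) NULL
        else if (is(stage1Pred, "Volume")) stage1Pred@data else stage1Pred
  if (!is.null(s1) && !identical(dim(s1), dim(img)))
    s1 <- upsampleToShape(s1, dim(img))
  P <- grid@patchShape
  w <- gaussianImportance(P)
  acc <- array(0, grid@gridShape)
  wsum <- array(0, grid@gridShape)
  for (p in seq_len(nrow(grid@origins))) {
    o <- grid@origins[p, ]
    chans <- list(extractPatch(img, o, P))
    if (!is.null(s1)) chans <- c(chans, list(extractPatch(s1, o, P)))
    x <- array(unlist(chans), c(P, length(chans)))
    if (grid@flip[p]) x <- x[rev(seq_len(P[1])), , , , drop = FALSE]
    m <- models[[grid@modelIndex[p]]]
    pred <- if (is.function(m)) m(x) else unetPredict(m, x)
    pred <- array(pred, P)
    if (grid@flip[p]) pred <- flipAxis(pred, 1L)
    sl <- list(o[1] + seq_len(P[1]), o[2] + seq_len(P[2]), o[3] + seq_len(P[3]))
    acc[sl[[1]], sl[[2]], sl[[3]]] <- acc[sl[[1]], sl[[2]], sl[[3]]] + pred * w
    wsum[sl[[1]], sl[[2]], sl[[3]]] <- wsum[sl[[1]], sl[[2]], sl[[3]]] + w
  }
  # voxels outside every patch are background by construction: the position
  # optimizer only cedes coverage where no training mask contains tissue
  out <- array(0, grid@gridShape)
  cov <- wsum > 0
  out[cov] <- acc[cov] / wsum[cov]
  TissueLabelMap(pmin(pmax(out, 0), 3), spacing = v@spacing,
                 affine = v@affine, spaceTag = v@spaceTag)
}
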