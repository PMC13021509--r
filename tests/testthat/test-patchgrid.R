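# Patch-grid construction, position optimization, Gaussian importance and
# patchwise accumulation with hemispheric weight sharing.

test_that("the full-scale grid has 27 patches and 18 effective models", {
  g <- buildPatchGrid(c(336L, 384L, 336L), c(128L, 128L, 128L))
  expect_equal(nrow(g@origins), 27L)
  expect_equal(length(unique(g@modelIndex)), 18L)
  expect_equal(sum(g@flip), 9L)
  # every patch fully inside the grid
  expect_true(all(g@origins >= 0))
  expect_true(all(sweep(g@origins, 2, g@gridShape - g@patchShape, "<=")))
  # flipped patches are exact sagittal mirrors of their partners
  for (p in which(g@flip)) {
    partner <- which(g@modelIndex == g@modelIndex[p] & !g@flip)
    expect_equal(g@origins[p, 1],
                 g@gridShape[1] - g@patchShape[1] - g@origins[partner, 1])
    expect_equal(g@origins[p, 2:3], g@origins[partner, 2:3])
  }
})

test_that("optimizer keeps the regular grid when the mask fills the volume", {
  full <- array(TRUE, c(24L, 24L, 24L))
  g <- optimizePatchPositions(list(full), 8L)
  g0 <- buildPatchGrid(c(24L, 24L, 24L), c(8L, 8L, 8L))
  expect_equal(g@origins, g0@origins)
})

test_that("optimizer converges inward on empty masks and stays tight", {
  empty <- array(FALSE, c(24L, 24L, 24L))
  g <- optimizePatchPositions(list(empty), 8L)
  # all patches end at the centered position (origin 8 = (24-8)/2)
  expect_true(all(g@origins == 8L))
})

test_that("optimizer matches exhaustive search on a small 2D analogue", {
  # central blob on a 12x12 grid with 6-wide patches: enumerate all mirror-
  # constrained inward offsets and verify the greedy result attains the
  # maximal total displacement among covering configurations
  D <- 12L; P <- 6L
  mask <- matrix(FALSE, D, D)
  mask[5:8, 4:9] <- TRUE
  greedy <- optimizePatchPositions(list(mask), P)
  stopifnot(is.matrix(greedy))
  base <- as.matrix(expand.grid(ix = 0:2, iy = 0:2))
  axpos <- c(0L, (D - P) %/% 2L, D - P)
  covers <- function(orig) {
    cov <- matrix(FALSE, D, D)
    for (p in seq_len(nrow(orig)))
      cov[orig[p, 1] + seq_len(P), orig[p, 2] + seq_len(P)] <- TRUE
    !any(mask & !cov)
  }
  # entities: pair columns (ix 0/2) per row iy: shared dx (mirrored) and dy;
  # center column (ix 1) per row iy: dy only (x stays centered)
  rng <- 0:(axpos[2])
  best <- -1L
  bestOrig <- NULL
  for (dx0 in rng) for (dx1 in rng) for (dx2 in rng) {
    for (dyp0 in rng) for (dyc0 in rng) for (dyp2 in rng) for (dyc2 in rng) {
      orig <- cbind(axpos[base[, 1] + 1L], axpos[base[, 2] + 1L])
      dxs <- c(dx0, dx1, dx2)
      for (p in seq_len(nrow(base))) {
        ix <- base[p, 1]; iy <- base[p, 2]
        dx <- if (ix == 0) dxs[iy + 1L] else if (ix == 2) -dxs[iy + 1L] else 0L
        isPair <- ix != 1L
        dy <- if (iy == 0) (if (isPair) dyp0 else dyc0) else
              if (iy == 2) -(if (isPair) dyp2 else dyc2) else 0L
        orig[p, ] <- orig[p, ] + c(dx, dy)
      }
      if (any(orig < 0) || any(orig > D - P)) next
      if (!covers(orig)) next
      tot <- dx0 + dx1 + dx2 + dyp0 + dyc0 + dyp2 + dyc2
      if (tot > best) { best <- tot; bestOrig <- orig }
    }
  }
  greedyTotal <- sum(abs(greedy - cbind(axpos[base[, 1] + 1L],
                                        axpos[base[, 2] + 1L]))) / 2
  expect_true(covers(greedy))
  # greedy moves as far inward in total as the exhaustive optimum
  expect_equal(sum(abs(greedy - cbind(axpos[base[, 1] + 1L],
                                      axpos[base[, 2] + 1L]))),
               sum(abs(bestOrig - cbind(axpos[base[, 1] + 1L],
                                        axpos[base[, 2] + 1L]))))
  # and no single further inward move preserves coverage (tightness)
  center <- (D - 1) / 2
  for (p in seq_len(nrow(base))) {
    ix <- base[p, 1]
    for (a in 1:2) {
      pc <- greedy[p, a] + (P - 1) / 2
      step <- sign(center - pc)
      if (a == 1 && ix == 1) next
      if (step == 0) next
      trial <- greedy
      trial[p, a] <- trial[p, a] + step
      if (ix != 1) {   # mirrored partner moves in lockstep
        q <- which(base[, 1] == 2 - ix & base[, 2] == base[p, 2])
        trial[q, a] <- trial[q, a] + if (a == 1) -step else step
      }
      expect_false(covers(trial),
                   label = sprintf("patch %d axis %d can still move", p, a))
    }
  }
})

test_that("small central blob stays covered after optimization", {
  mask <- array(FALSE, c(24L, 24L, 24L))
  mask[11:14, 10:15, 11:14] <- TRUE
  g <- optimizePatchPositions(list(mask), 8L)
  cov <- array(FALSE, c(24L, 24L, 24L))
  for (p in seq_len(nrow(g@origins))) {
    o <- g@origins[p, ]
    cov[o[1] + 1:8, o[2] + 1:8, o[3] + 1:8] <- TRUE
  }
  expect_true(all(cov[mask]))
})

test_that("uncoverable masks raise an error naming the voxel", {
  # 3 patches of 8 on a 30-wide axis leave gaps (voxels 9-11 and 20-22,
  # 1-based); tissue inside a gap cannot be covered by the starting grid
  mask <- array(FALSE, c(30L, 30L, 30L))
  mask[10, 10, 10] <- TRUE
  expect_error(optimizePatchPositions(list(mask), 8L), "not coverable")
  expect_error(optimizePatchPositions(list(mask), 40L), "exceeds")
})

test_that("gaussian importance peaks centrally and decreases to the faces", {
  w <- gaussianImportance(c(16L, 16L, 16L))
  expect_equal(which.max(w), which(abs(w - max(w)) < 1e-12)[1])
  mid <- w[, 8, 8]
  expect_true(all(diff(mid[1:8]) > 0))
  expect_true(all(diff(mid[9:16]) < 0))
  expect_true(all(w > 0))
})

test_that("patchwise accumulation averages constants and respects weights", {
  shape <- c(24L, 24L, 24L)
  v <- Volume(array(0.5, shape), spacing = c(1, 1, 1))
  grid <- buildPatchGrid(shape, c(8L, 8L, 8L))
  nEff <- max(grid@modelIndex)
  constModels <- replicate(nEff, function(x) array(1.7, dim(x)[1:3]),
                           simplify = FALSE)
  out <- runPatchwise(constModels, v, NULL, grid)
  expect_max_abs(out@data - 1.7, 1e-12)
  # model bank size mismatch errors
  expect_error(runPatchwise(constModels[1:3], v, NULL, grid), "effective")
  # two overlapping 1D-style patches: output between values, nearer patch wins
  w <- gaussianImportance(c(8L, 8L, 8L))
  o1 <- 0L; o2 <- 4L  # overlap region x in 5..8 (1-based)
  a <- 1; b <- 2
  for (x in 5:8) {
    wa <- w[x - o1, 4, 4]; wb <- w[x - o2, 4, 4]
    val <- (a * wa + b * wb) / (wa + wb)
    expect_gt(val, min(a, b)); expect_lt(val, max(a, b))
    nearer <- if (abs(x - (o1 + 4.5)) < abs(x - (o2 + 4.5))) a else b
    expect_lt(abs(val - nearer), abs(val - if (nearer == a) b else a))
  }
})

test_that("sagittal flip weight sharing is exactly mirror-equivariant", {
  shape <- c(24L, 24L, 24L)
  set.seed(9)
  arr <- array(stats::runif(prod(shape)), shape)
  v <- Volume(arr, spacing = c(1, 1, 1))
  vFlip <- Volume(vbmnet:::flipAxis(arr, 1L), spacing = c(1, 1, 1))
  grid <- buildPatchGrid(shape, c(8L, 8L, 8L))
  nEff <- max(grid@modelIndex)
  # arbitrary content-dependent (non-symmetric) patch models
  models <- lapply(seq_len(nEff), function(m)
    function(x) {
      img <- x[, , , 1]
      img * m / nEff + vbmnet:::flipAxis(img, 1L) * 0.3 + m / 10
    })
  predOrig <- runPatchwise(models, v, NULL, grid)
  predFlip <- runPatchwise(models, vFlip, NULL, grid)
  expect_max_abs(vbmnet:::flipAxis(predFlip@data, 1L) - predOrig@data, 1e-12)
})
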