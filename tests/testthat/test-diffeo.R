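# Scaling and squaring, composition, warping, Jacobians, elasticity and
# the registration losses, against closed-form oracles.

test_that("scaling and squaring of zero and constant fields is exact", {
  sh <- c(16L, 16L, 16L)
  phi0 <- scalingSquaring(array(0, c(sh, 3L)))
  expect_true(all(phi0@disp == 0))
  v <- array(0, c(sh, 3L))
  v[, , , 1] <- 0.08; v[, , , 3] <- -0.05
  phi <- scalingSquaring(v, 7)
  expect_max_abs(phi@disp[, , , 1] - 0.08, 1e-4)
  expect_max_abs(phi@disp[, , , 2], 1e-4)
  expect_max_abs(phi@disp[, , , 3] + 0.05, 1e-4)
  expect_error(scalingSquaring(array(NA_real_, c(sh, 3L))), "finite")
  expect_error(scalingSquaring(v, 0), "tau")
})

test_that("SS(v) o SS(-v) is the identity within half a voxel", {
  sh <- c(24L, 24L, 24L)
  v <- randomSmoothField(sh, ampVox = 2, smoothVox = 3, seed = 3)
  res <- composeDeformation(scalingSquaring(v), scalingSquaring(-v))
  voxErr <- max(abs(res@disp)) * (sh[1] - 1) / 2
  expect_lt(voxErr, 0.5)
  # and the Jacobian stays positive (diffeomorphism)
  jd <- jacobianDeterminant(scalingSquaring(v))
  expect_gt(min(jd@data), 0)
})

test_that("composition adds translations and is associative", {
  sh <- c(12L, 12L, 12L)
  tr <- function(t) DeformationField(array(rep(t, each = prod(sh)), c(sh, 3L)))
  idp <- identityDeformation(sh)
  b <- tr(c(-0.01, 0.04, 0.02))
  expect_equal(composeDeformation(idp, b)@disp, b@disp, tolerance = 1e-12)
  a <- tr(c(0.05, 0.02, -0.03))
  ab <- composeDeformation(a, b)
  expect_max_abs(sweep(matrix(ab@disp, ncol = 3), 2,
                       c(0.04, 0.06, -0.01)), 1e-12)
  # associativity on random smooth fields within interpolation tolerance
  sh2 <- c(16L, 16L, 16L)
  f1 <- DeformationField(randomSmoothField(sh2, 0.3, 3, seed = 4))
  f2 <- DeformationField(randomSmoothField(sh2, 0.3, 3, seed = 5))
  f3 <- DeformationField(randomSmoothField(sh2, 0.3, 3, seed = 6))
  lhs <- composeDeformation(composeDeformation(f1, f2), f3)
  rhs <- composeDeformation(f1, composeDeformation(f2, f3))
  expect_max_abs(lhs@disp - rhs@disp, 1e-3)
  expect_error(composeDeformation(f1, identityDeformation(c(8L, 8L, 8L))),
               "mismatch")
})

test_that("warping honors identity, translation and constancy oracles", {
  ph <- smallPhantom()
  img <- ph$image
  sh <- dim(img@data)
  idp <- identityDeformation(sh)
  expect_equal(warpVolume(img, idp)@data, img@data, tolerance = 1e-12)
  # translation moves a blob's centroid by the translation
  blob <- withVolData(img, array(0, sh))
  blob@data[14:18, 14:18, 14:18] <- 1
  shiftVox <- 3
  t1 <- shiftVox * 2 / (sh[1] - 1)
  phiT <- DeformationField(array(rep(c(t1, 0, 0), each = prod(sh)),
                                 c(sh, 3L)))
  moved <- warpVolume(blob, phiT)
  cg <- function(a) {
    i <- vbmnet:::voxelIndexGrid(dim(a)); colSums(i * as.vector(a)) / sum(a)
  }
  expect_equal(cg(moved@data)[1] - cg(blob@data)[1], -shiftVox,
               tolerance = 1e-6)
  # constant image stays constant inside the field of view
  const <- withVolData(img, array(3.2, sh))
  phiS <- DeformationField(randomSmoothField(sh, 1, 2, seed = 8) * 0.5)
  w <- warpVolume(const, phiS)
  expect_max_abs(w@data[5:28, 5:28, 5:28] - 3.2, 1e-9)
})

test_that("jacobian determinant matches zoom and volume-conservation oracles", {
  sh <- c(16L, 16L, 16L)
  expect_max_abs(jacobianDeterminant(identityDeformation(sh))@data - 1, 1e-12)
  eps <- 0.1
  g <- vbmnet:::normCoordGrid(sh)
  zoom <- DeformationField(array(g * eps, c(sh, 3L)))
  jd <- jacobianDeterminant(zoom)
  expect_max_abs(jd@data - (1 + eps)^3, 1e-9)
  # divergence-free periodic field: mean Jacobian stays ~1
  idx <- vbmnet:::voxelIndexGrid(sh)
  u <- array(0, c(sh, 3L))
  u[, , , 1] <- array(0.02 * sin(2 * pi * idx[, 2] / sh[2]), sh)
  u[, , , 2] <- array(0.02 * sin(2 * pi * idx[, 3] / sh[3]), sh)
  jd2 <- jacobianDeterminant(DeformationField(u))
  expect_lt(abs(mean(jd2@data) - 1), 1e-2)
})

test_that("linear elasticity matches the uniform-zoom closed form", {
  sh <- c(16L, 16L, 16L)
  expect_equal(linearElasticity(identityDeformation(sh)), 0)
  # rigid translation has zero strain
  tr <- DeformationField(array(0.07, c(sh, 3L)))
  expect_equal(linearElasticity(tr), 0)
  eps <- 0.1
  g <- vbmnet:::normCoordGrid(sh)
  zoom <- DeformationField(array(g * eps, c(sh, 3L)))
  for (prm in list(elasticityParams(), elasticityParams(mu = 1.3, lam = 0.7))) {
    expect_equal(linearElasticity(zoom, prm),
                 (3 * prm$mu + 4.5 * prm$lam) * eps^2, tolerance = 1e-9)
  }
  # quadratic under field scaling
  u <- DeformationField(randomSmoothField(sh, 1, 2, seed = 9))
  u2 <- DeformationField(u@disp * 2)
  expect_equal(linearElasticity(u2), 4 * linearElasticity(u),
               tolerance = 1e-9)
  expect_error(elasticityParams(mu = -1), ">= 0")
})

test_that("syn loss vanishes iff images match and velocities are zero", {
  ph <- smallPhantom()
  I <- ph$image
  sh <- dim(I@data)
  zeroPair <- VelocityPair(array(0, c(sh, 3L)))
  expect_equal(synLoss(I, I, zeroPair)$loss, 0)
  vp <- VelocityPair(randomSmoothField(sh, 1, 2, seed = 10))
  l <- synLoss(I, I, vp)
  expect_gt(l$loss, 0)
  expect_true(all(l$terms >= 0))
  J <- withVolData(I, I@data[c(2:sh[1], sh[1]), , ])
  expect_gt(synLoss(I, J, zeroPair)$loss, 0)
})

test_that("supervised losses satisfy their algebraic identities", {
  sh <- c(12L, 12L, 12L)
  v <- randomSmoothField(sh, 1, 2, seed = 11)
  pair <- VelocityPair(v)
  expect_equal(supervisedVelocityLoss(pair, pair), 0)
  cshift <- 0.03
  shifted <- VelocityPair(v + cshift, pair@vBwd)
  expect_equal(supervisedVelocityLoss(shifted, pair), cshift^2,
               tolerance = 1e-12)
  expect_equal(supervisedVelocityLoss(shifted, pair),
               supervisedVelocityLoss(pair, shifted))
  # full loss: beta = 0 reduces to L_v + Jacobian term; doubling beta
  # doubles the SyN contribution
  ph <- smallPhantom()
  I <- resampleToGrid(ph$image, gridSpec(sh, rep(10, 3)))
  tgt <- supervisedTarget(pair)
  pred <- VelocityPair(v * 0.9, pair@vBwd * 1.1)
  l0 <- supervisedFullLoss(pred, tgt, I, I, beta = 0)
  lb <- supervisedFullLoss(pred, tgt, I, I, beta = 2e-5)
  l2b <- supervisedFullLoss(pred, tgt, I, I, beta = 4e-5)
  expect_equal(l0$loss, l0$terms[["lv"]] + l0$terms[["jdet"]])
  expect_equal(l2b$loss - l0$loss, 2 * (lb$loss - l0$loss),
               tolerance = 1e-10)
  # self-consistent prediction: L_v and Jacobian terms vanish
  lself <- supervisedFullLoss(pair, tgt, I, I)
  expect_equal(lself$terms[["lv"]], 0)
  expect_equal(lself$terms[["jdet"]], 0)
  expect_gte(lself$loss, 0)
})

test_that("direct optimization of the syn loss decreases it", {
  # numerical-gradient smoke test on a coarse pair: the loss is a usable
  # objective (decreases over the first steps)
  sh <- c(8L, 8L, 8L)
  ph <- smallPhantom()
  I <- resampleToGrid(ph$image, gridSpec(sh, rep(16, 3)))
  J <- withVolData(I, vbmnet:::flipAxis(I@data, 2L))
  v <- array(0, c(sh, 3L))
  lossOf <- function(vv) synLoss(I, J, VelocityPair(array(vv, c(sh, 3L))),
                                 tau = 4L)$loss
  l0 <- lossOf(v)
  set.seed(12)
  lr <- 0.05
  cur <- v
  for (i in 1:10) {
    # stochastic coordinate descent with numerical directional derivative
    dir <- array(stats::rnorm(length(cur)), dim(cur))
    dir <- dir / sqrt(sum(dir^2))
    e <- 1e-4
    slope <- (lossOf(cur + e * dir) - lossOf(cur - e * dir)) / (2 * e)
    cand <- cur - lr * slope * dir
    if (lossOf(cand) < lossOf(cur)) cur <- cand
  }
  expect_lt(lossOf(cur), l0)
})

test_that("velocity distillation reproduces its generating deformation", {
  gt <- makeDeformationTruth(c(16L, 16L, 16L), amplitudeVox = 1.2,
                             smoothVox = 2.5, seed = 13)
  res <- velocityFromDeformation(gt$phiFwd, gt$phiBwd, iters = 200,
                                 lr = 0.5, tol = 1e-12)
  ph <- vbmnet:::deformationsFromPair(res$vpair)
  errVox <- max(abs(ph$fwd@disp - gt$phiFwd@disp)) * (16 - 1) / 2
  expect_lt(errVox, 0.1)
  # identity target -> near-zero velocities
  idp <- identityDeformation(c(12L, 12L, 12L))
  r0 <- velocityFromDeformation(idp, idp, iters = 50, lr = 0.1, tol = 1e-10)
  expect_lt(r0$residual, 1e-6)
  expect_max_abs(r0$vpair@vFwd, 1e-6)
  # loss against the generating velocity is small but may be nonzero
  expect_lt(supervisedVelocityLoss(res$vpair, gt$vpair), 1e-4)
})
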