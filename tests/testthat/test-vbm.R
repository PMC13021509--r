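# GM masking, modulation, smoothing and the voxel-wise GLM machinery.

test_that("gm masking zeroes exactly the resource region", {
  ph <- smallPhantom()
  prob <- decodeLabels(ph$labels)
  gm <- withVolData(ph$image, prob[, , , 3])
  empty <- array(0, dim(gm@data))
  expect_equal(gmMask(gm, empty)@data, gm@data)
  full <- array(1, dim(gm@data))
  expect_true(all(gmMask(gm, full)@data == 0))
  # conservation: the GM sum drops by exactly the masked-in GM sum
  vm <- ph$ventricleMask@data
  masked <- gmMask(gm, vm)
  expect_equal(sum(gm@data) - sum(masked@data), sum(gm@data[vm > 0]))
  expect_error(gmMask(gm, array(0, c(3, 3, 3))), "mismatch")
})

test_that("modulation multiplies by the Jacobian and conserves mass", {
  ph <- smallPhantom()
  gm <- withVolData(ph$image, decodeLabels(ph$labels)[, , , 3])
  ones <- withVolData(gm, array(1, dim(gm@data)))
  expect_equal(modulate(gm, ones)@data, gm@data)
  # uniform zoom: warped+modulated tissue mass approximately conserved
  sh <- dim(gm@data)
  eps <- 0.06
  zoom <- DeformationField(array(vbmnet:::normCoordGrid(sh) * eps, c(sh, 3L)))
  warped <- warpVolume(gm, zoom)
  jd <- jacobianDeterminant(zoom, spacing = gm@spacing)
  mod <- modulate(warped, jd)
  expect_lt(abs(sum(mod@data) - sum(gm@data)) / sum(gm@data), 0.02)
  # negative determinant triggers the fold warning
  neg <- withVolData(gm, array(-0.5, sh))
  expect_warning(modulate(gm, neg), "folds")
})

test_that("fwhm smoothing preserves mass and realizes the requested width", {
  d <- c(31L, 31L, 31L)
  v <- Volume(array(0, d), spacing = c(2, 2, 2))
  v@data[16, 16, 16] <- 1
  sm <- smoothFwhm(v, fwhmMm = 6)
  expect_equal(sum(sm@data), 1, tolerance = 1e-6)   # kernel normalized
  prof <- sm@data[, 16, 16]
  half <- max(prof) / 2
  # sub-voxel half-crossings by linear interpolation of the profile
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  fLo <- lo - (prof[lo] - half) / (prof[lo] - prof[lo - 1])
  fHi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  widthMm <- (fHi - fLo) * v@spacing[1]
  expect_lt(abs(widthMm - 6), v@spacing[1] / 2)      # FWHM within half voxel
  # constant image stays constant away from the zero-padded boundary
  cv <- Volume(array(2, d), spacing = c(2, 2, 2))
  smc <- smoothFwhm(cv, 6)
  expect_max_abs(smc@data[8:24, 8:24, 8:24] - 2, 1e-9)
  expect_error(smoothFwhm(v, 0), "positive")
})

test_that("voxel-wise t matches the closed-form OLS t exactly", {
  # 6-subject toy, single voxel, design ~ x with intercept
  x <- c(1.2, 0.7, 2.5, 3.1, 1.9, 2.2)
  yv <- c(0.5, 0.9, 1.8, 2.4, 1.2, 2.0)
  tab <- data.frame(id = 1:6, x = x)
  maps <- lapply(yv, function(val) Volume(array(val, c(1, 1, 1))))
  tm <- glmTmap(tab, maps, ~ x, coef = "x", mask = array(TRUE, c(1, 1, 1)))
  # hand-computed OLS t-statistic
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  res <- yv - X %*% beta
  s2 <- sum(res^2) / (6 - 2)
  tHand <- beta[2] / sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(tm@t@data[1, 1, 1], as.numeric(tHand), tolerance = 1e-10)
  expect_equal(tm@df, 4)
  # independent oracle: lm()
  tLm <- summary(stats::lm(yv ~ x))$coefficients["x", "t value"]
  expect_equal(tm@t@data[1, 1, 1], tLm, tolerance = 1e-10)
})

test_that("perfect fits are flagged as effectively infinite", {
  x <- seq_len(8)
  tab <- data.frame(x = x)
  maps <- lapply(x, function(val) Volume(array(2 * val, c(1, 1, 1))))
  tm <- glmTmap(tab, maps, ~ x, coef = "x", mask = array(TRUE, c(1, 1, 1)))
  expect_gt(abs(tm@t@data[1, 1, 1]), 1e6)
})

test_that("rank-deficient designs are rejected naming the columns", {
  tab <- data.frame(a = 1:8, b = 2 * (1:8))
  maps <- lapply(1:8, function(i) Volume(array(i, c(1, 1, 1))))
  expect_error(glmTmap(tab, maps, ~ a + b, coef = "a",
                       mask = array(TRUE, c(1, 1, 1))), "collinear")
  expect_error(cohortTable(data.frame(a = c(1, NA, 3, 4, 5)), ~ a), "missing")
})

test_that("permuted covariates yield a null t distribution", {
  co <- makeCohort(50, seed = 31)
  perm <- co$table
  perm$age <- withr::with_seed(17, sample(perm$age))
  tm <- glmTmap(perm, co$gm, ~ age + sex, coef = "age")
  tin <- abs(tm@t@data[tm@mask])
  expect_gte(mean(tin < 5), 0.99)
})

test_that("the injected regional effect is recovered by the median t-map", {
  co <- makeCohort(60, effect = list(center = c(15, 10, 5), radius = 12,
                                     size = 0.15, covariate = "age"),
                   seed = 32)
  tm <- resampledMedianTmap(co$table, co$gm, ~ age + sex, coef = "age",
                            reps = 20L, frac = 0.8, seed = 5)
  inside <- tm@t@data[co$effectMask & tm@mask]
  outside <- tm@t@data[!co$effectMask & tm@mask]
  expect_gt(stats::median(inside),
            stats::quantile(outside, 0.99, names = FALSE))
  peak <- which(tm@t@data == max(tm@t@data), arr.ind = TRUE)[1, ]
  expect_true(co$effectMask[peak[1], peak[2], peak[3]])
})

test_that("resampled median reduces to the plain t-map at reps=1, frac=1", {
  co <- makeCohort(20, seed = 33)
  plain <- glmTmap(co$table, co$gm, ~ age, coef = "age")
  med <- resampledMedianTmap(co$table, co$gm, ~ age, coef = "age",
                             reps = 1L, frac = 1.0, seed = 2)
  expect_equal(med@t@data, plain@t@data, tolerance = 1e-10)
  # determinism under a fixed seed
  med2 <- resampledMedianTmap(co$table, co$gm, ~ age, coef = "age",
                              reps = 5L, frac = 0.8, seed = 9)
  med3 <- resampledMedianTmap(co$table, co$gm, ~ age, coef = "age",
                              reps = 5L, frac = 0.8, seed = 9)
  expect_identical(med2@t@data, med3@t@data)
})

test_that("t-map correlation behaves at its fixed points", {
  co <- makeCohort(20, seed = 34)
  tm <- glmTmap(co$table, co$gm, ~ age, coef = "age")
  expect_equal(tmapCorrelation(tm, tm), 1)
  neg <- tm; neg@t@data <- -neg@t@data
  expect_equal(tmapCorrelation(tm, neg), -1)
  # independent noise maps decorrelate
  d <- c(22L, 22L, 22L)
  mk <- function(seed) {
    arr <- withr::with_seed(seed, array(stats::rnorm(prod(d)), d))
    new("TMap", t = Volume(arr), df = 10, mask = array(TRUE, d))
  }
  expect_lt(abs(tmapCorrelation(mk(1), mk(2))), 0.05)
})
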