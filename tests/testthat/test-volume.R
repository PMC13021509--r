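# Volume container, NIfTI round trips, resampling and crop conventions.

test_that("NIfTI write/read round-trips data and affine", {
  ph <- smallPhantom()
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$image, f)
  v2 <- readVolume(f)
  expect_max_abs(v2@data - ph$image@data, 1e-6)
  expect_equal(v2@affine, ph$image@affine, tolerance = 1e-6)
  expect_equal(v2@spacing, ph$image@spacing, tolerance = 1e-6)
  unlink(f)
})

test_that("4D input is rejected with a format error", {
  f <- tempfile(fileext = ".nii")
  arr <- array(0, c(4, 4, 4, 2))
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  expect_error(readVolume(f), "4D")
  unlink(f)
})

test_that("phantom volumes carry the desk preset geometry", {
  ph <- deskPhantom()
  expect_equal(dim(ph$image@data), c(48L, 48L, 48L))
  expect_equal(ph$image@spacing, rep(3, 3))
})

test_that("Volume validity rejects broken geometry", {
  expect_error(Volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)))
  expect_error(Volume(array(0, c(2, 2, 2)), affine = matrix(0, 4, 4)))
  expect_error(new("Volume", data = array(0, c(2, 2)), spacing = rep(1, 3),
                   affine = diag(4), spaceTag = "native"))
})

test_that("resampling honors identity, translation and constancy oracles", {
  ph <- smallPhantom()
  v <- ph$image
  spec <- list(shape = dim(v@data), spacing = v@spacing, affine = v@affine)
  # identity transform, same grid
  same <- resampleToGrid(v, spec, interpolation = "trilinear")
  expect_max_abs(same@data - v@data, 1e-10)
  # integer-voxel translation with nearest interpolation: shifted copy
  shiftMm <- c(2, 0, 0) * v@spacing          # 2 voxels along x
  A <- diag(4); A[1:3, 4] <- shiftMm
  sh <- resampleToGrid(v, spec, transform = A, interpolation = "nearest")
  d <- dim(v@data)
  expect_equal(sh@data[1:(d[1] - 2), , ], v@data[3:d[1], , ])
  expect_true(all(sh@data[(d[1] - 1):d[1], , ] == 0))
  # constant volume under an arbitrary affine stays constant in-field
  cv <- withVolData(v, array(2.5, d))
  B <- diag(4); B[1:3, 1:3] <- diag(c(1.05, 0.97, 1.02)); B[1:3, 4] <- c(3, -2, 1)
  rs <- resampleToGrid(cv, spec, transform = B, interpolation = "trilinear")
  interior <- rs@data[8:25, 8:25, 8:25]
  expect_max_abs(interior - 2.5, 1e-9)
})

test_that("b-spline resampling reproduces smooth fields accurately", {
  d <- c(20L, 20L, 20L)
  idx <- vbmnet:::voxelIndexGrid(d)
  f <- function(x, y, z) sin(x / 5) * cos(y / 6) + 0.1 * z / 19
  arr <- array(f(idx[, 1], idx[, 2], idx[, 3]), d)
  v <- Volume(arr, spacing = c(1, 1, 1))
  spec <- list(shape = d, spacing = c(1, 1, 1), affine = v@affine)
  A <- diag(4); A[1:3, 4] <- c(0.4, -0.3, 0.2)
  rs <- resampleToGrid(v, spec, transform = A, interpolation = "bspline")
  # exact reproduction at the grid points (interpolating spline property)
  atGrid <- vbmnet:::sampleBspline(vbmnet:::bsplinePrefilter(arr),
                                   matrix(as.numeric(idx), ncol = 3))
  expect_max_abs(atGrid - as.vector(arr), 1e-9)
  # analytic agreement at shifted positions, deep interior (boundary
  # conditions decay with the spline pole |z|^k toward the inside)
  expected <- array(f(idx[, 1] + 0.4, idx[, 2] - 0.3, idx[, 3] + 0.2), d)
  expect_max_abs((rs@data - expected)[7:14, 7:14, 7:14], 5e-4)
})

test_that("round-trip resampling is accurate away from the boundary", {
  # trilinear round-trip error scales with the field curvature, so the
  # smooth test object is a broad Gaussian blob
  d <- c(48L, 48L, 48L)
  idx <- vbmnet:::voxelIndexGrid(d)
  r2 <- rowSums(sweep(idx, 2, (d - 1) / 2)^2)
  v <- Volume(array(exp(-r2 / (2 * 28^2)), d), spacing = c(3, 3, 3))
  spec <- list(shape = d, spacing = v@spacing, affine = v@affine)
  A <- diag(4); A[1:3, 4] <- c(1.6, -1.2, 0.8)
  fwd <- resampleToGrid(v, spec, transform = A)
  back <- resampleToGrid(fwd, spec, transform = solve(A))
  interior <- as.vector((back@data - v@data)[8:41, 8:41, 8:41])
  expect_max_abs(interior, 1e-3)
})

test_that("grid presets match the published shapes and are 16-divisible", {
  p05 <- gridPreset("0.5mm")
  expect_equal(p05$shape, c(339L, 411L, 339L))
  expect_equal(p05$cropShape, c(336L, 384L, 336L))
  expect_equal(gridPreset("0.75mm")$shape, c(224L, 256L, 224L))
  expect_equal(gridPreset("1.5mm")$shape, c(113L, 137L, 113L))
  for (nm in c("0.5mm", "0.75mm", "desk")) {
    expect_true(all(gridPreset(nm)$cropShape %% 16 == 0), info = nm)
  }
})

test_that("analysis crop and uncrop invert each other", {
  spec <- gridSpec(c(20L, 24L, 20L), rep(1, 3), cropOrigin = c(2L, 4L, 2L),
                   cropShape = c(16L, 16L, 16L))
  arr <- array(0, spec$shape)
  arr[5:15, 7:17, 5:15] <- 1
  v <- Volume(arr, spacing = spec$spacing)
  cr <- cropToAnalysisGrid(v, spec)
  expect_equal(dim(cr@data), c(16L, 16L, 16L))
  un <- uncropFromAnalysisGrid(cr, spec)
  expect_equal(dim(un@data), spec$shape)
  expect_equal(un@data[5:15, 7:17, 5:15], arr[5:15, 7:17, 5:15])
  expect_true(all(un@data[1:2, , ] == 0))
  # wrong grid errors; full-coverage data warns
  expect_error(cropToAnalysisGrid(Volume(array(0, c(4, 4, 4))), spec), "grid")
  full <- Volume(array(1, spec$shape), spacing = spec$spacing)
  expect_warning(cropToAnalysisGrid(full, spec), "boundary")
})

test_that("0.5mm preset crops 339x411x339 to 336x384x336", {
  spec <- gridPreset("0.5mm")
  expect_equal(spec$shape - spec$cropShape >= spec$cropOrigin,
               rep(TRUE, 3), ignore_attr = TRUE)
  v <- Volume(array(0L, spec$shape), spacing = spec$spacing)
  cr <- cropToAnalysisGrid(v, "0.5mm")
  expect_equal(dim(cr@data), c(336L, 384L, 336L))
  rm(v, cr)
})
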