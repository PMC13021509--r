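# Interpolation primitives shared by resampling, warping and the
# deformation machinery. Coordinates are 0-based voxel indices unless noted.

# Gather arr[i,j,k] for index matrix idx (V x 3, 0-based, assumed in bounds).
gather3 <- function(arr, idx) {
  d <- dim(arr)
  arr[1L + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])]
}

#' Trilinear sampling of a 3D array at fractional voxel coordinates
#'
#' @param arr 3D array.
#' @param coords V x 3 matrix of 0-based voxel coordinates.
#' @param fill value returned outside the grid (`"clamp"` for edge-clamped
#'   sampling, used when sampling displacement fields).
#' @return numeric vector of length V.
#' @keywords internal
sampleTrilinear <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  clamp <- identical(fill, "clamp")
  if (clamp) {
    for (a in 1:3) coords[, a] <- pmin(pmax(coords[, a], 0), d[a] - 1)
  }
  i0 <- floor(coords)
  fr <- coords - i0
  out <- numeric(nrow(coords))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    inb <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
           iz >= 0 & iz <= d[3] - 1
    cx <- pmin(pmax(ix, 0), d[1] - 1)
    cy <- pmin(pmax(iy, 0), d[2] - 1)
    cz <- pmin(pmax(iz, 0), d[3] - 1)
    v <- arr[1L + cx + d[1] * (cy + d[2] * cz)]
    out <- out + w * ifelse(inb, v, 0)
  }
  out
}

# Nearest-neighbor sampling; zero outside the grid.
sampleNearest <- function(arr, coords) {
  d <- dim(arr)
  i <- round(coords)
  inb <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
         i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
         i[, 3] >= 0 & i[, 3] <= d[3] - 1
  out <- numeric(nrow(coords))
  ii <- i[inb, , drop = FALSE]
  out[inb] <- gather3(arr, ii)
  out
}

# --- cubic B-spline interpolation (Unser-style prefilter + kernel) --------

# Recursive prefilter along one axis so that B-spline interpolation of the
# filtered coefficients reproduces the original samples at the grid points.
bsplinePrefilterAxis <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  if (n < 2) return(x)
  z <- sqrt(3) - 2          # pole of the cubic B-spline
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(x, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = n)
  m <- m * 6
  # causal init (mirror boundary), truncated sum
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z))))
  c0 <- m[1, ]
  zn <- z
  for (k in 2:horizon) { c0 <- c0 + zn * m[k, ]; zn <- zn * z }
  m[1, ] <- c0
  for (k in 2:n) m[k, ] <- m[k, ] + z * m[k - 1, ]
  # anticausal init + pass
  m[n, ] <- (z / (z * z - 1)) * (m[n, ] + z * m[n - 1, ])
  for (k in (n - 1):1) m[k, ] <- z * (m[k + 1, ] - m[k, ])
  m <- array(m, dm)
  aperm(m, order(perm))
}

bsplinePrefilter <- function(x) {
  for (a in 1:3) x <- bsplinePrefilterAxis(x, a)
  x
}

bspline3Kernel <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

# Cubic B-spline sampling; `coef` must be prefiltered. Mirror boundary for
# the kernel taps (consistent with the prefilter); zero outside the field.
sampleBspline <- function(coef, coords) {
  d <- dim(coef)
  i0 <- floor(coords)
  fr <- coords - i0
  out <- numeric(nrow(coords))
  inField <- coords[, 1] >= 0 & coords[, 1] <= d[1] - 1 &
             coords[, 2] >= 0 & coords[, 2] <= d[2] - 1 &
             coords[, 3] >= 0 & coords[, 3] <= d[3] - 1
  mirror <- function(i, n) {
    i <- abs(i)
    i[i > n - 1] <- 2 * (n - 1) - i[i > n - 1]
    pmin(pmax(i, 0), n - 1)
  }
  for (dx in -1:2) for (dy in -1:2) for (dz in -1:2) {
    w <- bspline3Kernel(dx - fr[, 1]) * bspline3Kernel(dy - fr[, 2]) *
         bspline3Kernel(dz - fr[, 3])
    ix <- mirror(i0[, 1] + dx, d[1])
    iy <- mirror(i0[, 2] + dy, d[2])
    iz <- mirror(i0[, 3] + dz, d[3])
    out <- out + w * coef[1L + ix + d[1] * (iy + d[2] * iz)]
  }
  out * inField
}

# --- normalized coordinate helpers ----------------------------------------

# Voxel index (0-based) -> normalized coordinate in [-1, 1] with the
# endpoints at the centers of the first/last voxels.
voxToNorm <- function(idx, n) {
  ifelse(rep(n, length.out = length(idx)) > 1, -1 + 2 * idx / (n - 1), 0)
}

normToVox <- function(u, n) (u + 1) * (n - 1) / 2

# V x 3 matrix of 0-based voxel indices for a grid, in array order.
voxelIndexGrid <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1L, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  )
}

# V x 3 matrix of normalized coordinates for a grid.
normCoordGrid <- function(shape) {
  idx <- voxelIndexGrid(shape)
  cbind(voxToNorm(idx[, 1], shape[1]),
        voxToNorm(idx[, 2], shape[2]),
        voxToNorm(idx[, 3], shape[3]))
}
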