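# Small shared helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# Derive a per-item seed from a root seed, keeping within 32-bit range.
deriveSeed <- function(root, counter) {
  as.integer((as.numeric(root) * 1000003 + counter * 7919) %% 2147483647)
}

# Gaussian random field: white noise smoothed with a separable Gaussian of
# sd `sigmaVox` voxels, standardized to zero mean / unit sd.
smoothNoiseField <- function(shape, sigmaVox) {
  g <- array(stats::rnorm(prod(shape)), shape)
  g <- gaussianSmooth3(g, rep(sigmaVox, 3))
  (g - mean(g)) / stats::sd(g)
}

# Separable zero-padded Gaussian smoothing of a plain array, sd in voxels.
gaussianSmooth3 <- function(arr, sigmaVox) {
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- convolveAxis(arr, k, axis)
  }
  arr
}

# 1D convolution along one axis with zero padding, via shifted adds.
convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  idxAll <- lapply(d, seq_len)
  for (j in seq_along(kernel)) {
    off <- j - 1L - r
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idxDst <- idxAll; idxDst[[axis]] <- which(keep)
    idxSrc <- idxAll; idxSrc[[axis]] <- src[keep]
    out[idxDst[[1]], idxDst[[2]], idxDst[[3]]] <-
      out[idxDst[[1]], idxDst[[2]], idxDst[[3]]] +
      kernel[j] * arr[idxSrc[[1]], idxSrc[[2]], idxSrc[[3]]]
  }
  out
}

# Reverse an array along one axis (used for sagittal flips).
flipAxis <- function(arr, axis = 1L) {
  nd <- length(dim(arr))
  idx <- lapply(dim(arr), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}
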