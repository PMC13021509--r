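# Training augmentations and the synthetic-artifact test protocol.
#
# Twelve augmentation kinds are supported; the k-space kinds (motion,
# ghosting, spike, Gibbs ringing) operate in the Fourier domain of the
# image, the bias field is built from low-frequency Gaussian noise, and the
# spatial kinds (translation, flipping) use nearest-neighbor resampling so
# no interpolation degradation is introduced. Every kind is a deterministic
# function of (kind, strength, seed) and reduces to the identity at
# strength 0.

AUGMENT_KINDS <- c("bias_field", "motion", "noise", "blur", "ghosting",
                   "spike", "downsample", "translate", "flip", "brightness",
                   "contrast", "gibbs")

# Named strengths for the seven-artifact test protocol; constants chosen
# once (see vignette) so that "strong" visibly exceeds "medium" in artifact
# energy on a normalized [0, 1] image.
AUGMENT_PRESETS <- list(
  noise      = c(medium = 0.05, strong = 0.15),
  bias_field = c(medium = 0.30, strong = 0.60),
  blur       = c(medium = 0.70, strong = 1.50),
  ghosting   = c(medium = 0.30, strong = 0.70),
  motion     = c(medium = 1.00, strong = 3.00),
  gibbs      = c(medium = 0.30, strong = 0.55),
  spike      = c(medium = 0.50, strong = 2.00),
  downsample = c(medium = 0.50, strong = 1.50),
  translate  = c(medium = 2.00, strong = 5.00),
  brightness = c(medium = 0.10, strong = 0.30),
  contrast   = c(medium = 0.20, strong = 0.50),
  flip       = c(medium = 1.00, strong = 1.00))

#' Augmentation specification
#'
#' @param kind one of the 12 supported kinds: bias_field, motion, noise,
#'   blur, ghosting, spike, downsample, translate, flip, brightness,
#'   contrast, gibbs.
#' @param strength numeric strength, or `"medium"`/`"strong"` to use the
#'   recorded preset table.
#' @param seed integer seed making stochastic kinds reproducible.
#' @return an `AugmentSpec` list.
#' @export
augmentSpec <- function(kind, strength = "medium", seed = 1L) {
  if (!kind %in% AUGMENT_KINDS) stop("unknown augmentation kind: ", kind)
  intensity <- if (is.character(strength)) strength else NA_character_
  if (is.character(strength)) {
    strength <- AUGMENT_PRESETS[[kind]][[strength]]
    if (is.null(strength)) stop("no preset for kind ", kind)
  }
  list(kind = kind, strength = as.numeric(strength),
       intensity = intensity, seed = as.integer(seed))
}

#' Apply one augmentation to a volume
#'
#' @param v [Volume-class] with finite values.
#' @param spec an [augmentSpec()].
#' @return same-shape [Volume-class]; identical to `v` when the strength is 0.
#' @export
applyAugmentation <- function(v, spec) {
  if (!all(is.finite(v@data))) stop("volume must be finite-valued")
  if (!spec$kind %in% AUGMENT_KINDS) stop("unknown augmentation kind: ", spec$kind)
  s <- spec$strength
  if (s == 0) return(v)
  x <- v@data
  out <- withSeed(spec$seed, switch(spec$kind,
    bias_field = augBiasField(x, s),
    motion     = augMotion(x, s),
    noise      = augChiNoise(x, s),
    blur       = gaussianSmooth3(x, rep(s, 3)),
    ghosting   = augGhosting(x, s),
    spike      = augSpike(x, s),
    downsample = augDownsample(x, s),
    translate  = augTranslate(x, s),
    flip       = flipAxis(x, 1L),
    brightness = x + s,
    contrast   = augContrast(x, s),
    gibbs      = augGibbs(x, s)))
  withVolData(v, array(out, dim(x)))
}

# inverse FFT of low-frequency Gaussian noise -> smooth log-field -> exp
augBiasField <- function(x, s, cutoff = 4L) {
  d <- dim(x)
  ks <- array(0+0i, d)
  f <- lapply(d, signedFreq)
  keep <- outer(abs(f[[1]]) <= cutoff,
                outer(abs(f[[2]]) <= cutoff, abs(f[[3]]) <= cutoff, "&"), "&")
  nLow <- sum(keep)
  ks[keep] <- complex(real = stats::rnorm(nLow), imaginary = stats::rnorm(nLow))
  g <- Re(stats::fft(ks, inverse = TRUE)) / prod(d)
  g <- (g - mean(g)) / stats::sd(g)
  x * exp(s * g)
}

# chi-distributed magnitude noise: k Gaussian channels in quadrature with
# the signal (dof 2 = Rician-magnitude limit).
augChiNoise <- function(x, sigma, dof = 2L) {
  d <- dim(x)
  ss <- (x + sigma * array(stats::rnorm(prod(d)), d))^2
  for (j in seq_len(dof - 1L))
    ss <- ss + (sigma * array(stats::rnorm(prod(d)), d))^2
  sqrt(ss)
}

# average of the k-space with phase-ramped (translated) copies
augMotion <- function(x, ampVox, nMoves = 3L) {
  d <- dim(x)
  ks <- stats::fft(x)
  acc <- ks
  f <- lapply(seq_along(d), function(a) signedFreq(d[a]) / d[a])
  for (j in seq_len(nMoves)) {
    t <- stats::runif(3, -ampVox, ampVox)
    ramp <- exp(-2i * pi * (outer(f[[1]] * t[1],
              outer(f[[2]] * t[2], f[[3]] * t[3], "+"), "+")))
    acc <- acc + ks * ramp
  }
  Re(stats::fft(acc / (nMoves + 1), inverse = TRUE)) / prod(d)
}

# attenuate every Nth phase-encode line (axis 2), sparing DC
augGhosting <- function(x, s, every = 4L) {
  d <- dim(x)
  ks <- stats::fft(x)
  lines <- which((seq_len(d[2]) - 1L) %% every == 0L)
  lines <- setdiff(lines, 1L)
  ks[, lines, ] <- ks[, lines, ] * (1 - s)
  Re(stats::fft(ks, inverse = TRUE)) / prod(d)
}

# one random high-amplitude k-space point
augSpike <- function(x, s) {
  d <- dim(x)
  ks <- stats::fft(x)
  p <- vapply(d, function(n) sample(2:n, 1L), integer(1))
  ks[p[1], p[2], p[3]] <- ks[p[1], p[2], p[3]] +
    s * max(Mod(ks)) * exp(2i * pi * stats::runif(1))
  Re(stats::fft(ks, inverse = TRUE)) / prod(d)
}

# resample to a coarser grid and back (factor 1 + s)
augDownsample <- function(x, s) {
  d <- dim(x)
  factor <- 1 + s
  coarse <- pmax(2L, round(d / factor))
  # sample coarse grid at fractional positions of the fine grid
  cIdx <- voxelIndexGrid(coarse)
  fine2coarse <- sweep(cIdx, 2, (d - 1) / (coarse - 1), "*")
  cArr <- array(sampleTrilinear(x, fine2coarse), coarse)
  fIdx <- voxelIndexGrid(d)
  coarse2fine <- sweep(fIdx, 2, (coarse - 1) / (d - 1), "*")
  array(sampleTrilinear(cArr, coarse2fine), d)
}

# integer-voxel translation with zero fill (nearest-neighbor by construction)
augTranslate <- function(x, ampVox) {
  d <- dim(x)
  t <- round(stats::runif(3, -ampVox, ampVox))
  if (all(t == 0)) t[1] <- max(1, round(ampVox))
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    dst[[a]] <- seq_len(d[a])[seq_len(d[a]) + t[a] >= 1 &
                              seq_len(d[a]) + t[a] <= d[a]] + t[a]
    src[[a]] <- dst[[a]] - t[a]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# gamma adjustment on the positive part, identity at s = 0
augContrast <- function(x, s) {
  m <- max(x)
  if (m <= 0) return(x)
  xp <- pmax(x, 0) / m
  m * xp^(1 + s) + pmin(x, 0)
}

# radial k-space truncation (ringing); keep radius (1 - s) * Nyquist
augGibbs <- function(x, s) {
  d <- dim(x)
  ks <- stats::fft(x)
  f <- lapply(seq_along(d), function(a) signedFreq(d[a]) / (d[a] / 2))
  rho2 <- outer(f[[1]]^2, outer(f[[2]]^2, f[[3]]^2, "+"), "+")
  ks[rho2 > (1 - s)^2] <- 0
  Re(stats::fft(ks, inverse = TRUE)) / prod(d)
}

# signed DFT frequency indices 0, 1, ..., -1 for length n
signedFreq <- function(n) {
  f <- seq_len(n) - 1L
  f[f > n / 2] <- f[f > n / 2] - n
  f
}

#' The seven-artifact test suite
#'
#' Applies each of the seven artifact kinds of the synthetic-artifact test
#' protocol (chi/Rician-type noise, bias field, blurring, ghosting, motion,
#' Gibbs ringing, spike) at medium and strong intensity to every input
#' volume: 14 corrupted volumes per original.
#'
#' @param originals non-empty list of [Volume-class] objects.
#' @param seed root seed; per-volume seeds are derived deterministically.
#' @return list with one element per corrupted volume: `volume`, `spec`,
#'   `original` (index of the source volume).
#' @export
artifactTestSuite <- function(originals, seed = 1L) {
  if (length(originals) == 0) stop("originals must be non-empty")
  kinds <- c("noise", "bias_field", "blur", "ghosting", "motion", "gibbs",
             "spike")
  out <- list()
  counter <- 0L
  for (i in seq_along(originals)) {
    for (k in kinds) {
      for (lvl in c("medium", "strong")) {
        counter <- counter + 1L
        spec <- augmentSpec(k, lvl, seed = deriveSeed(seed, i * 100L + match(k, kinds)))
        spec$intensity <- lvl
        out[[counter]] <- list(volume = applyAugmentation(originals[[i]], spec),
                               spec = spec, original = i)
      }
    }
  }
  out
}
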