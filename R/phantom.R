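# Synthetic head-phantom generator: skull-stripped heads with nested
# CSF/GM/WM compartments, continuous partial-volume labels, ground-truth
# deformations and VBM cohorts with injected effects. Everything the other
# modules consume at desk scale is produced here.

#' Phantom specification
#'
#' Nested ellipsoidal compartments: WM core of radii `wmRadii` (mm), a GM
#' shell of thickness `gmThickness` and a CSF envelope of thickness
#' `csfThickness` around it, with mirrored ventricles (CSF inside WM) and a
#' brainstem mask region at the inferior center. Intensity means follow a
#' T1w-like contrast.
#'
#' @param grid preset name or [gridSpec()] (default `"desk"`: 48^3, 3 mm).
#' @param wmRadii WM ellipsoid radii in mm.
#' @param gmThickness cortical GM thickness in mm (> 0).
#' @param csfThickness CSF envelope thickness in mm.
#' @param ventRadii,ventOffset ventricle ellipsoid radii and center offset
#'   (+/- along x for the mirrored pair), mm.
#' @param brainstemRadii,brainstemOffset brainstem mask ellipsoid, mm.
#' @param means intensity means for (CSF, GM, WM).
#' @param noiseAmp amplitude of the smooth within-class intensity
#'   variation (0 disables it).
#' @param foldAmp amplitude of the cortical folding (gyral/sulcal surface
#'   undulation) as a fraction of the compartment radii; 0 gives smooth
#'   ellipsoids (used when comparing against analytic shell volumes).
#' @param seed RNG seed.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(grid = "desk", wmRadii = c(40, 46, 38),
                        gmThickness = 12, csfThickness = 8,
                        ventRadii = c(6, 14, 9), ventOffset = c(9, 2, -4),
                        brainstemRadii = c(9, 10, 16),
                        brainstemOffset = c(0, -6, -32),
                        means = c(CSF = 0.2, GM = 0.5, WM = 0.8),
                        noiseAmp = 0.03, foldAmp = 0.06, seed = 1L) {
  if (gmThickness <= 0) stop("gmThickness must be > 0")
  if (csfThickness <= 0) stop("csfThickness must be > 0")
  if (any(wmRadii <= 0)) stop("non-nested radii: WM radii must be positive")
  list(grid = if (is.character(grid)) gridPreset(grid) else grid,
       wmRadii = wmRadii, gmThickness = gmThickness,
       csfThickness = csfThickness, ventRadii = ventRadii,
       ventOffset = ventOffset, brainstemRadii = brainstemRadii,
       brainstemOffset = brainstemOffset, means = means,
       noiseAmp = noiseAmp, foldAmp = foldAmp, seed = as.integer(seed))
}

# Soft (sub-voxel) inside-fraction of an ellipsoid, linear ramp over one
# voxel across the surface. `world` is a V x 3 matrix of mm coordinates.
# `mod` optionally modulates the surface level (bumps at rho = 1 + mod).
ellipsoidFraction <- function(world, center, radii, voxelMm, mod = 0) {
  u <- sweep(world, 2, center)
  rho <- sqrt((u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 +
              (u[, 3] / radii[3])^2)
  gradNorm <- sqrt((u[, 1] / radii[1]^2)^2 + (u[, 2] / radii[2]^2)^2 +
                   (u[, 3] / radii[3]^2)^2) / pmax(rho, 1e-9)
  distMm <- (1 + mod - rho) / pmax(gradNorm, 1e-9)
  frac <- pmin(pmax(0.5 + distMm / voxelMm, 0), 1)
  frac[rho < 0.5] <- 1
  frac
}

# Angular folding pattern emulating gyral/sulcal surface undulation:
# smooth, deterministic, and even in the sagittal direction so the
# phantom's midsagittal mirror symmetry stays exact.
foldPattern <- function(world) {
  r <- sqrt(rowSums(world^2))
  d <- world / pmax(r, 1e-9)
  g <- 0.45 * cos(5.1 * d[, 1]) * cos(3.7 * d[, 2] - 1.2) +
       0.35 * cos(4.3 * d[, 2] + 0.8) * cos(2.9 * d[, 3]) +
       0.20 * cos(6.2 * d[, 3] - 0.5)
  g
}

#' Generate a head phantom
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` ([Volume-class]), `labels`
#'   ([TissueLabelMap-class] with exact partial-volume boundaries),
#'   `brainMask`, `ventricleMask`, `brainstemMask` (binary Volumes).
#' @export
makePhantom <- function(spec) {
  g <- spec$grid
  gmR <- spec$wmRadii + spec$gmThickness
  csfR <- gmR + spec$csfThickness
  fovHalf <- g$shape * g$spacing / 2
  foldAmp <- spec$foldAmp %||% 0
  if (any(csfR * (1 + foldAmp) >= fovHalf))
    stop("non-nested or oversized radii: CSF envelope exceeds the grid")
  aff <- gridAffine(g)
  idx <- voxelIndexGrid(g$shape)
  world <- cbind(idx, 1) %*% t(aff)
  world <- world[, 1:3, drop = FALSE]
  h <- mean(g$spacing)

  # common surface undulation keeps the compartments nested while giving
  # the head the angular structure (gyri/sulci) real brains have
  mod <- if (foldAmp > 0) foldAmp * foldPattern(world) else 0
  fWm <- ellipsoidFraction(world, c(0, 0, 0), spec$wmRadii, h, mod)
  fGm <- ellipsoidFraction(world, c(0, 0, 0), gmR, h, mod)
  fCsf <- ellipsoidFraction(world, c(0, 0, 0), csfR, h, mod)
  fVent <- pmax(
    ellipsoidFraction(world, spec$ventOffset, spec$ventRadii, h),
    ellipsoidFraction(world, spec$ventOffset * c(-1, 1, 1), spec$ventRadii, h))
  fStem <- ellipsoidFraction(world, spec$brainstemOffset,
                             spec$brainstemRadii, h)

  pWm <- pmax(fWm, 0)
  pGm <- pmax(fGm - fWm, 0)
  pCsf <- pmax(fCsf - fGm, 0)
  # carve ventricles: tissue inside the ventricle becomes CSF
  pCsf <- pCsf + fVent * (pWm + pGm)
  pWm <- pWm * (1 - fVent)
  pGm <- pGm * (1 - fVent)
  lab <- pCsf + 2 * pGm + 3 * pWm

  intensity <- spec$means[["CSF"]] * pCsf + spec$means[["GM"]] * pGm +
    spec$means[["WM"]] * pWm
  d <- g$shape
  if (spec$noiseAmp > 0) {
    varField <- withSeed(spec$seed, smoothNoiseField(d, 2))
    intensity <- intensity + spec$noiseAmp * as.vector(varField) * (lab > 0)
  }
  mkVol <- function(x, tag = "template")
    new("Volume", data = array(x, d), spacing = g$spacing, affine = aff,
        spaceTag = tag)
  list(image = mkVol(pmax(intensity, 0)),
       labels = TissueLabelMap(mkVol(pmin(pmax(lab, 0), 3))),
       brainMask = mkVol((lab > 0.5) * 1),
       ventricleMask = mkVol((fVent > 0.5) * 1),
       brainstemMask = mkVol((fStem > 0.5) * 1))
}

#' Synthetic atrophy progression
#'
#' Simulates global cortical thinning: the GM thickness is reduced by
#' `k * maxReductionMm / steps` for k = 1..steps while the outer CSF
#' envelope stays fixed (CSF fills the vacated space). With
#' `includeOriginal`, the unmodified base phantom is prepended, giving
#' steps + 1 volumes per base.
#'
#' @param base a [phantomSpec()].
#' @param steps number of atrophy levels (default 10).
#' @param maxReductionMm largest thickness reduction in mm (default 1).
#' @param includeOriginal prepend the unmodified phantom.
#' @return list of [makePhantom()] outputs, each with a `reductionMm`
#'   element recording the applied thinning.
#' @export
atrophySeries <- function(base, steps = 10L, maxReductionMm = 1.0,
                          includeOriginal = FALSE) {
  if (maxReductionMm >= base$gmThickness)
    stop("thickness reduction must stay below the GM thickness")
  out <- list()
  if (includeOriginal) {
    ph <- makePhantom(base)
    ph$reductionMm <- 0
    out[[1]] <- ph
  }
  for (k in seq_len(steps)) {
    r <- k * maxReductionMm / steps
    sp <- base
    sp$gmThickness <- base$gmThickness - r
    sp$csfThickness <- base$csfThickness + r
    ph <- makePhantom(sp)
    ph$reductionMm <- r
    out[[length(out) + 1L]] <- ph
  }
  out
}

#' Ground-truth deformation and velocity pair
#'
#' Smooth random stationary velocity (Gaussian-filtered noise scaled to a
#' target peak amplitude), antisymmetric half pair (vBwd = -vFwd), and the
#' forward/backward deformations via scaling and squaring. The Jacobian is
#' checked to be positive everywhere; the field is regenerated (new derived
#' seed) up to 5 times before failing.
#'
#' @param shape grid shape (integer(3)).
#' @param amplitudeVox peak displacement of the velocity field in voxels.
#' @param smoothVox Gaussian smoothing sd of the noise, voxels.
#' @param seed RNG seed.
#' @param tau squaring steps.
#' @return list with `vpair` ([VelocityPair-class]), `phiFwd`, `phiBwd`
#'   ([DeformationField-class]) and `minJacobian`.
#' @export
makeDeformationTruth <- function(shape, amplitudeVox = 1.5, smoothVox = 3,
                                 seed = 1L, tau = 7L) {
  shape <- as.integer(shape)
  for (attempt in 1:5) {
    v <- array(0, c(shape, 3L))
    if (amplitudeVox > 0) {
      withSeed(deriveSeed(seed, attempt), {
        for (c in 1:3) v[, , , c] <- smoothNoiseField(shape, smoothVox)
      })
      peak <- max(abs(v))
      for (c in 1:3)
        v[, , , c] <- v[, , , c] / peak * amplitudeVox * 2 / (shape[c] - 1)
    }
    vpair <- VelocityPair(v, -v)
    ph <- deformationsFromPair(vpair, tau)
    mj <- min(jacobianDeterminant(ph$fwd)@data)
    if (mj > 0 || amplitudeVox == 0)
      return(list(vpair = vpair, phiFwd = ph$fwd, phiBwd = ph$bwd,
                  minJacobian = mj))
  }
  stop("could not generate a diffeomorphic field at amplitude ",
       amplitudeVox, " voxels (min Jacobian ", signif(mj, 3), ")")
}

#' Synthetic VBM cohort with an injected regional effect
#'
#' Samples covariates (age uniform in [20, 70], sex Bernoulli(0.5), group
#' Bernoulli(0.5)) for n subjects and builds per-subject "warped" GM/WM
#' probability maps: the template tissue map plus a covariate-scaled effect
#' inside a spherical region plus spatially smooth noise.
#'
#' @param n number of subjects (>= 10).
#' @param effect list: `center` (mm), `radius` (mm), `size` (GM probability
#'   change per SD of the covariate), `covariate` (column name, default
#'   `"age"`).
#' @param grid preset name or [gridSpec()].
#' @param noiseSd sd of the smooth spatial noise added per subject.
#' @param seed RNG seed.
#' @return list with `table` (data.frame id/age/sex/group), `gm`, `wm`
#'   (lists of [Volume-class]), `effectMask` (logical array), `templateGm`,
#'   `templateWm`.
#' @export
makeCohort <- function(n, effect = list(center = c(15, 10, 5), radius = 12,
                                        size = 0.15, covariate = "age"),
                       grid = "desk", noiseSd = 0.04, seed = 1L) {
  if (n < 10) stop("need at least 10 subjects")
  ph <- makePhantom(phantomSpec(grid = grid, seed = deriveSeed(seed, 0)))
  prob <- decodeLabels(ph$labels)
  tGm <- prob[, , , 3]
  tWm <- prob[, , , 4]
  g <- if (is.character(grid)) gridPreset(grid) else grid
  aff <- gridAffine(g)
  world <- cbind(voxelIndexGrid(g$shape), 1) %*% t(aff)
  r2 <- (world[, 1] - effect$center[1])^2 + (world[, 2] - effect$center[2])^2 +
        (world[, 3] - effect$center[3])^2
  effMask <- array(r2 < effect$radius^2, g$shape)
  covName <- effect$covariate %||% "age"
  tab <- withSeed(seed, data.frame(
    id = sprintf("sub-%03d", seq_len(n)),
    age = stats::runif(n, 20, 70),
    sex = stats::rbinom(n, 1, 0.5),
    group = stats::rbinom(n, 1, 0.5)))
  z <- as.numeric(scale(tab[[covName]]))
  mkVol <- function(x) new("Volume", data = array(x, g$shape),
                           spacing = g$spacing, affine = aff,
                           spaceTag = "template")
  gm <- wm <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- withSeed(deriveSeed(seed, i), smoothNoiseField(g$shape, 2))
    gmMap <- tGm + effect$size * z[i] * effMask + noiseSd * noise * (tGm > 0.05)
    wmMap <- tWm + noiseSd * withSeed(deriveSeed(seed, i + n),
                                      smoothNoiseField(g$shape, 2)) * (tWm > 0.05)
    gm[[i]] <- mkVol(pmin(pmax(gmMap, 0), 1))
    wm[[i]] <- mkVol(pmin(pmax(wmMap, 0), 1))
  }
  list(table = tab, gm = gm, wm = wm, effectMask = effMask,
       templateGm = mkVol(tGm), templateWm = mkVol(tWm))
}
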