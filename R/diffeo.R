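# Stationary-velocity-field machinery: scaling and squaring, composition,
# warping, Jacobian determinants, linear elasticity, and the symmetric and
# supervised registration losses.
#
# Velocity and deformation fields live in normalized coordinates: each axis
# spans [-1, 1] with the endpoints at the centers of the first and last
# voxels. Displacement sampling is edge-clamped (stable at boundaries);
# image warping uses zero fill (no information outside the brain).

# Sample a displacement field (X,Y,Z,3) at normalized coordinates `coords`
# (V x 3), edge-clamped trilinear.
sampleDisplacement <- function(disp, coords) {
  d <- dim(disp)[1:3]
  vox <- cbind(normToVox(coords[, 1], d[1]), normToVox(coords[, 2], d[2]),
               normToVox(coords[, 3], d[3]))
  out <- matrix(0, nrow(coords), 3)
  for (c in 1:3) out[, c] <- sampleTrilinear(disp[, , , c], vox, fill = "clamp")
  out
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' The field is scaled by 2^(-tau), converted to a small deformation
#' (identity plus scaled field), and composed with itself tau times,
#' yielding a diffeomorphic deformation for smooth fields of moderate
#' amplitude.
#'
#' @param v X x Y x Z x 3 velocity field in normalized coordinates.
#' @param tau number of squaring steps (default 7).
#' @return a [DeformationField-class].
#' @export
scalingSquaring <- function(v, tau = 7L) {
  if (tau < 1) stop("tau must be >= 1")
  if (!all(is.finite(v))) stop("velocity field must be finite")
  d <- dim(v)[1:3]
  disp <- v / 2^tau
  coords <- normCoordGrid(d)
  for (s in seq_len(tau)) {
    dm <- matrix(disp, prod(d), 3)
    moved <- coords + dm
    disp <- array(sampleDisplacement(disp, moved) + dm, c(d, 3L))
  }
  DeformationField(disp)
}

#' Compose two deformation fields
#'
#' `(a o b)(x) = a(b(x))`, sampled with edge-clamped trilinear
#' interpolation of `a`'s displacement at `b`'s coordinates.
#'
#' @param a,b [DeformationField-class] objects on the same grid.
#' @return [DeformationField-class] of the composition.
#' @export
composeDeformation <- function(a, b) {
  if (!identical(dim(a@disp), dim(b@disp))) stop("grid mismatch")
  d <- dim(a@disp)[1:3]
  coords <- normCoordGrid(d)
  bm <- matrix(b@disp, prod(d), 3)
  DeformationField(array(sampleDisplacement(a@disp, coords + bm) + bm,
                         c(d, 3L)))
}

# Inverse of a deformation expressed as a field: phi^{-1} for SS output is
# obtained by integrating -v; this helper only flips a displacement's sign
# in the small-deformation regime and is intentionally not exported.

#' Warp a volume through a deformation field
#'
#' Trilinear resampling of the image at phi(x); zero outside the field of
#' view.
#'
#' @param img [Volume-class].
#' @param phi [DeformationField-class] on the same grid.
#' @return warped [Volume-class].
#' @export
warpVolume <- function(img, phi) {
  d <- dim(img@data)
  if (!identical(as.integer(d), as.integer(dim(phi@disp)[1:3])))
    stop("grid mismatch between image and deformation")
  coords <- normCoordGrid(d) + matrix(phi@disp, prod(d), 3)
  vox <- cbind(normToVox(coords[, 1], d[1]), normToVox(coords[, 2], d[2]),
               normToVox(coords[, 3], d[3]))
  withVolData(img, array(sampleTrilinear(img@data, vox), d))
}

# Per-component spatial gradient of a (X,Y,Z,3) coordinate/displacement map
# with respect to normalized coordinates: central differences in the
# interior, one-sided at the faces. Returns a list g[[i]][[j]] = d map_i / d x_j.
fieldGradient <- function(f) {
  d <- dim(f)[1:3]
  g <- vector("list", 3)
  for (i in 1:3) {
    g[[i]] <- vector("list", 3)
    fi <- f[, , , i]
    for (j in 1:3) {
      h <- 2 / (d[j] - 1)
      n <- d[j]
      idxP <- pmin(seq_len(n) + 1L, n)
      idxM <- pmax(seq_len(n) - 1L, 1L)
      scale <- 1 / (h * (idxP - idxM))  # central interior, one-sided at faces
      if (j == 1) {
        gi <- (fi[idxP, , , drop = FALSE] - fi[idxM, , , drop = FALSE]) *
          array(rep(scale, prod(d[2:3])), d)
      } else if (j == 2) {
        gi <- (fi[, idxP, , drop = FALSE] - fi[, idxM, , drop = FALSE]) *
          array(rep(rep(scale, each = d[1]), d[3]), d)
      } else {
        gi <- (fi[, , idxP, drop = FALSE] - fi[, , idxM, drop = FALSE]) *
          array(rep(scale, each = d[1] * d[2]), d)
      }
      g[[i]][[j]] <- gi
    }
  }
  g
}

#' Jacobian determinant of a deformation
#'
#' Per-voxel determinant of the spatial gradient of the coordinate map
#' (central differences in the interior, one-sided at the faces). The value
#' is the local volume-change factor: identity gives 1 everywhere, a
#' uniform zoom x -> (1 + eps) x gives (1 + eps)^3.
#'
#' @param phi [DeformationField-class].
#' @param spacing,affine optional geometry for the returned Volume.
#' @return [Volume-class] of determinant values.
#' @export
jacobianDeterminant <- function(phi, spacing = c(1, 1, 1), affine = NULL) {
  d <- dim(phi@disp)[1:3]
  coordMap <- phi@disp
  grid <- array(normCoordGrid(d), c(d, 3L))
  coordMap <- coordMap + grid
  g <- fieldGradient(coordMap)
  det3 <- g[[1]][[1]] * (g[[2]][[2]] * g[[3]][[3]] - g[[2]][[3]] * g[[3]][[2]]) -
          g[[1]][[2]] * (g[[2]][[1]] * g[[3]][[3]] - g[[2]][[3]] * g[[3]][[1]]) +
          g[[1]][[3]] * (g[[2]][[1]] * g[[3]][[2]] - g[[2]][[2]] * g[[3]][[1]])
  Volume(det3, spacing = spacing, affine = affine, spaceTag = "template")
}

#' Linear elasticity of a deformation
#'
#' Elastic energy of the displacement part u = phi - id:
#' `R = mean_x ( mu * ||eps(u)||^2 + lambda / 2 * tr(eps(u))^2 )` with
#' eps(u) the symmetrized gradient (strain tensor). The integral is
#' normalized to unit domain volume, so a uniform zoom u = eps * x yields
#' exactly `(3 mu + 4.5 lambda) eps^2` and any rigid translation yields 0.
#'
#' @param phi [DeformationField-class].
#' @param params list with `mu` (zoom-elasticity weight) and `lam`
#'   (shear-elasticity weight); see [elasticityParams()].
#' @return scalar elastic energy.
#' @export
linearElasticity <- function(phi, params = elasticityParams()) {
  g <- fieldGradient(phi@disp)
  normSq <- 0
  tr <- 0
  for (i in 1:3) {
    tr <- tr + g[[i]][[i]]
    for (j in 1:3) {
      eij <- (g[[i]][[j]] + g[[j]][[i]]) / 2
      normSq <- normSq + eij^2
    }
  }
  mean(params$mu * normSq + params$lam / 2 * tr^2)
}

#' Elasticity / regularization parameters
#'
#' @param mu zoom-elasticity weight (default 1).
#' @param lam shearing-elasticity weight (default 1).
#' @param Lambda similarity-regularity trade-off weight (default 0.01).
#'   None of the three is fixed by the reference registration description;
#'   the defaults are package choices, configurable everywhere.
#' @return parameter list.
#' @export
elasticityParams <- function(mu = 1, lam = 1, Lambda = 0.01) {
  if (mu < 0 || lam < 0 || Lambda < 0) stop("weights must be >= 0")
  list(mu = mu, lam = lam, Lambda = Lambda)
}

#' Full forward/backward deformations from a half-velocity pair
#'
#' `Phi = SS(v_fwd) o SS(-v_bwd)` and `Phi^-1 = SS(v_bwd) o SS(-v_fwd)`:
#' the composition-with-inverse reading of the half-deformation
#' convention, the only one that makes `Phi o Phi^-1 = Id` exact in the
#' continuum.
#'
#' @param vpair a [VelocityPair-class].
#' @param tau squaring steps.
#' @return list with `fwd`, `bwd`, `halfFwd`, `halfBwd`
#'   ([DeformationField-class] each).
#' @export
deformationsFromPair <- function(vpair, tau = 7L) {
  phiHalfF <- scalingSquaring(vpair@vFwd, tau)
  phiHalfB <- scalingSquaring(vpair@vBwd, tau)
  phiFwd <- composeDeformation(phiHalfF, scalingSquaring(-vpair@vBwd, tau))
  phiBwd <- composeDeformation(phiHalfB, scalingSquaring(-vpair@vFwd, tau))
  list(fwd = phiFwd, bwd = phiBwd, halfFwd = phiHalfF, halfBwd = phiHalfB)
}

#' Symmetric (SyN-style) registration loss
#'
#' `L = MSE(I o Phi, J) + MSE(I, J o Phi^-1) +
#'  MSE(I o Phi^(1/2), J o Phi^(-1/2)) + Lambda * R(Phi)` where the full
#' forward and backward deformations are built from the half velocity pair
#' by scaling and squaring and composition, and R is the linear elasticity.
#'
#' @param I moving [Volume-class]; J template [Volume-class].
#' @param vpair [VelocityPair-class].
#' @param params [elasticityParams()].
#' @param tau squaring steps.
#' @return list with `loss` and the individual `terms`.
#' @export
synLoss <- function(I, J, vpair, params = elasticityParams(), tau = 7L) {
  if (!identical(dim(I@data), dim(J@data))) stop("grid mismatch")
  if (!identical(as.integer(dim(I@data)), as.integer(dim(vpair@vFwd)[1:3])))
    stop("velocity grid does not match the images")
  ph <- deformationsFromPair(vpair, tau)
  mse <- function(a, b) mean((a@data - b@data)^2)
  t1 <- mse(warpVolume(I, ph$fwd), J)
  t2 <- mse(I, warpVolume(J, ph$bwd))
  t3 <- mse(warpVolume(I, ph$halfFwd), warpVolume(J, ph$halfBwd))
  reg <- linearElasticity(ph$fwd, params)
  list(loss = t1 + t2 + t3 + params$Lambda * reg,
       terms = c(fwd = t1, bwd = t2, half = t3, elasticity = reg))
}

#' Supervised velocity loss L_v
#'
#' Mean squared disagreement between predicted and target half velocity
#' fields, summed over the forward and backward field.
#'
#' @param pred,target [VelocityPair-class] objects on the same grid.
#' @return scalar loss.
#' @export
supervisedVelocityLoss <- function(pred, target) {
  if (!identical(dim(pred@vFwd), dim(target@vFwd))) stop("grid mismatch")
  mean((pred@vFwd - target@vFwd)^2) + mean((pred@vBwd - target@vBwd)^2)
}

#' Supervised target for registration training
#'
#' @param vTarget [VelocityPair-class] distilled from a reference
#'   deformation.
#' @param jdetTarget [Volume-class] of the reference Jacobian determinant;
#'   computed from `vTarget` when omitted.
#' @param tau squaring steps used for the Jacobian.
#' @return a `SupervisedTarget` list.
#' @export
supervisedTarget <- function(vTarget, jdetTarget = NULL, tau = 7L) {
  if (is.null(jdetTarget))
    jdetTarget <- jacobianDeterminant(deformationsFromPair(vTarget, tau)$fwd)
  list(vTarget = vTarget, jdetTarget = jdetTarget)
}

#' Full supervised registration loss
#'
#' `L_supervised = L_v + MSE(Jdet_pred, Jdet_target) + beta * L_SyN` with
#' beta defaulting to 2e-5. All three sub-losses are returned for logging.
#'
#' @param pred predicted [VelocityPair-class].
#' @param target a [supervisedTarget()].
#' @param I,J moving and template [Volume-class] (for the SyN term).
#' @param params [elasticityParams()].
#' @param beta weight of the SyN term.
#' @param tau squaring steps.
#' @return list with `loss` and `terms` (`lv`, `jdet`, `syn`).
#' @export
supervisedFullLoss <- function(pred, target, I, J,
                               params = elasticityParams(), beta = 2e-5,
                               tau = 7L) {
  lv <- supervisedVelocityLoss(pred, target$vTarget)
  jd <- jacobianDeterminant(deformationsFromPair(pred, tau)$fwd)
  lj <- mean((jd@data - target$jdetTarget@data)^2)
  syn <- synLoss(I, J, pred, params, tau)$loss
  list(loss = lv + lj + beta * syn, terms = c(lv = lv, jdet = lj, syn = syn))
}

#' Distill a velocity pair from a reference deformation
#'
#' Determines the stationary half velocity fields that reproduce a given
#' forward/backward deformation pair under scaling and squaring. Iterates a
#' first-order descent on the reconstruction residuals of the half field w
#' (the pair is antisymmetric, `(w, -w)`): with the package convention
#' `recon = SS(w) o SS(w)` and `recon^-1 = SS(-w) o SS(-w)`, the update
#' adds the symmetrized residual
#' `(Phi_target - recon) - (Phi_target^-1 - recon^-1)` (split over the two
#' half maps) to w, with backtracking on the step size. Both residuals
#' vanish exactly when w equals the generating half field, so targets
#' produced by the same discrete machinery are reproduced to the
#' iteration floor.
#'
#' @param phiTarget,phiTargetInv approximately mutually inverse
#'   [DeformationField-class] targets.
#' @param iters maximum iterations.
#' @param lr initial step size.
#' @param tol stop when the mean squared reconstruction residual falls
#'   below this value.
#' @param tau squaring steps.
#' @return list with `vpair` ([VelocityPair-class]), `residual` (final mean
#'   squared residual) and `iterations`.
#' @export
velocityFromDeformation <- function(phiTarget, phiTargetInv, iters = 500L,
                                    lr = 0.1, tol = 1e-4, tau = 7L) {
  if (!identical(dim(phiTarget@disp), dim(phiTargetInv@disp)))
    stop("grid mismatch")
  d <- dim(phiTarget@disp)[1:3]
  w <- array(0, c(d, 3L))   # half velocity; the pair is (w, -w)
  resid <- function(w) {
    # direct reconstruction residuals under the package convention
    # Phi = SS(w) o SS(w), Phi^-1 = SS(-w) o SS(-w): both vanish exactly
    # when w reproduces the generating half field
    sf <- scalingSquaring(w, tau); sb <- scalingSquaring(-w, tau)
    fwd <- composeDeformation(sf, sf)
    inv <- composeDeformation(sb, sb)
    rf <- phiTarget@disp - fwd@disp
    rb <- phiTargetInv@disp - inv@disp
    list(rf = rf, rb = rb, ms = (mean(rf^2) + mean(rb^2)) / 2)
  }
  r <- resid(w)
  initialMs <- max(r$ms, .Machine$double.eps)
  bad <- 0L
  it <- 0L
  while (it < iters && r$ms > tol) {
    it <- it + 1L
    wNew <- w + lr * (r$rf - r$rb) / 4   # correction split over the two halves
    rNew <- resid(wNew)
    if (rNew$ms <= r$ms) {
      w <- wNew; r <- rNew
      bad <- 0L
    } else {
      lr <- lr / 2   # backtrack; the proposed step is rejected
      bad <- bad + 1L
      if (bad >= 10L) {
        # ten consecutive rejected steps: either true divergence (residual
        # still large) or the numerical floor of the fixed-point iteration
        if (r$ms > 1e-3 * initialMs)
          stop("velocity distillation diverged: residual increased over 10 ",
               "consecutive steps (residual ", signif(r$ms, 4),
               ", initial ", signif(initialMs, 4), ")")
        break
      }
    }
    if (r$ms < 1e-16) break
  }
  list(vpair = VelocityPair(w, -w), residual = r$ms, iterations = it)
}
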