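# Post-registration VBM statistics: GM masking, modulation, smoothing,
# voxel-wise GLM t-maps, resampled median maps and map correlation.

#' Zero the GM probability inside a masking resource
#'
#' Conforms GM probability maps to the convention of zeroing gray matter in
#' the ventricles and around the brain stem before registration/analysis.
#'
#' @param prob GM probability [Volume-class].
#' @param maskResource binary [Volume-class]/array: regions to zero.
#' @return masked [Volume-class]; other tissue classes are untouched by
#'   construction (the function only sees the GM map).
#' @export
gmMask <- function(prob, maskResource) {
  m <- asArr(maskResource)
  if (!identical(dim(m), dim(prob@data))) stop("grid mismatch")
  out <- prob@data
  out[m > 0] <- 0
  withVolData(prob, out)
}

#' Modulate a warped tissue map by the Jacobian determinant
#'
#' Voxel-wise product `warped * jdet`, preserving total tissue volume under
#' the deformation (change of variables). A warning is logged when the
#' determinant is negative anywhere (diffeomorphism violation).
#'
#' @param warped warped tissue probability [Volume-class].
#' @param jdet Jacobian-determinant [Volume-class].
#' @return modulated [Volume-class].
#' @export
modulate <- function(warped, jdet) {
  j <- asArr(jdet)
  if (!identical(dim(j), dim(warped@data))) stop("grid mismatch")
  if (any(j < 0)) warning("negative Jacobian determinant: deformation folds")
  withVolData(warped, warped@data * j)
}

#' Gaussian smoothing with a given FWHM
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis in voxel units, zero-padded at the boundary. The kernel is
#' normalized, so the total image sum is preserved for interior-supported
#' content.
#'
#' @param v [Volume-class].
#' @param fwhmMm full width at half maximum in mm (default 6).
#' @return smoothed [Volume-class].
#' @export
smoothFwhm <- function(v, fwhmMm = 6) {
  if (fwhmMm <= 0) stop("fwhm must be positive")
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / v@spacing
  withVolData(v, gaussianSmooth3(v@data, sigmaVox))
}

#' Cohort table for VBM analyses
#'
#' Validates a per-subject covariate table: no missing values in modeled
#' columns and enough subjects for the design.
#'
#' @param table data.frame with one row per subject (id plus covariates).
#' @param design model formula (right-hand side), e.g. `~ age + sex`.
#' @return the validated data.frame.
#' @export
cohortTable <- function(table, design) {
  vars <- all.vars(design)
  missing <- setdiff(vars, names(table))
  if (length(missing)) stop("missing covariates: ", paste(missing, collapse = ", "))
  if (anyNA(table[, vars])) stop("missing values in modeled columns")
  X <- stats::model.matrix(design, table)
  if (nrow(table) < ncol(X) + 2)
    stop("need at least ", ncol(X) + 2, " subjects for this design")
  table
}

# Stack a list of Volumes (or a 4D array) into an n x V matrix.
mapsToMatrix <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    d <- dim(maps)
    return(list(Y = t(matrix(maps, prod(d[1:3]), d[4])), shape = d[1:3],
                proto = NULL))
  }
  d <- dim(asArr(maps[[1]]))
  Y <- do.call(rbind, lapply(maps, function(m) as.vector(asArr(m))))
  list(Y = Y, shape = d, proto = if (is(maps[[1]], "Volume")) maps[[1]] else NULL)
}

#' Voxel-wise GLM t-map
#'
#' Fits an ordinary-least-squares model per voxel of the smoothed,
#' spatially normalized tissue maps and returns the t-statistic of the
#' covariate of interest. Voxels outside the analysis mask (mean tissue
#' probability <= `maskThreshold` by default) are set to 0.
#'
#' @param cohort data.frame validated by [cohortTable()].
#' @param maps list of smoothed [Volume-class] maps (one per subject, same
#'   order as `cohort`) or a 4D array (V x ... x n).
#' @param design model formula, e.g. `~ age + sex`.
#' @param coef name of the design column of interest (default: first
#'   non-intercept column).
#' @param mask optional logical array; when NULL, built from the mean map.
#' @param maskThreshold analysis-mask threshold on the mean map.
#' @return a [TMap-class].
#' @export
glmTmap <- function(cohort, maps, design, coef = NULL, mask = NULL,
                    maskThreshold = 0.1) {
  cohort <- cohortTable(cohort, design)
  mm <- mapsToMatrix(maps)
  Y <- mm$Y
  if (nrow(Y) != nrow(cohort)) stop("one map per subject required")
  X <- stats::model.matrix(design, cohort)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(coef)) {
    cand <- setdiff(colnames(X), "(Intercept)")
    coef <- cand[1]
  }
  j <- match(coef, colnames(X))
  if (is.na(j)) stop("unknown coefficient: ", coef)
  if (is.null(mask)) mask <- array(colMeans(Y) > maskThreshold, mm$shape)
  df <- nrow(X) - qrX$rank
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXinv[j, j])
  t <- beta[j, ] / se
  nf <- !is.finite(t)
  t[nf] <- sign(beta[j, nf]) * .Machine$double.xmax^0.5  # perfect fits
  t[!as.vector(mask)] <- 0
  proto <- mm$proto %||% Volume(array(0, mm$shape))
  new("TMap", t = withVolData(proto, array(t, mm$shape)), df = df,
      mask = mask)
}

#' Median t-map over resampled subsets
#'
#' Repeats the voxel-wise GLM `reps` times on random subsets (fraction
#' `frac`, drawn without replacement; per-repetition seeds derived from the
#' root seed) and returns the per-voxel median t-map.
#'
#' @inheritParams glmTmap
#' @param reps number of repetitions (default 100).
#' @param frac subset fraction (default 0.8).
#' @param seed root seed.
#' @return a [TMap-class] (df of the subset fits).
#' @export
resampledMedianTmap <- function(cohort, maps, design, coef = NULL,
                                reps = 100L, frac = 0.8, seed = 1L,
                                mask = NULL, maskThreshold = 0.1) {
  cohort <- cohortTable(cohort, design)
  n <- nrow(cohort)
  m <- round(frac * n)
  X <- stats::model.matrix(design, cohort)
  if (m < ncol(X) + 2) stop("frac * n too small for the design")
  mm <- mapsToMatrix(maps)
  if (is.null(mask)) mask <- array(colMeans(mm$Y) > maskThreshold, mm$shape)
  tAcc <- matrix(0, reps, ncol(mm$Y))
  dfSub <- NA_real_
  for (r in seq_len(reps)) {
    idx <- withSeed(deriveSeed(seed, r), sample(n, m))
    sub <- glmTmap(cohort[idx, , drop = FALSE],
                   array(t(mm$Y[idx, , drop = FALSE]), c(mm$shape, m)),
                   design, coef = coef, mask = mask)
    tAcc[r, ] <- as.vector(sub@t@data)
    dfSub <- sub@df
  }
  tMed <- apply(tAcc, 2, stats::median)
  tMed[!as.vector(mask)] <- 0
  proto <- mm$proto %||% Volume(array(0, mm$shape))
  new("TMap", t = withVolData(proto, array(tMed, mm$shape)), df = dfSub,
      mask = mask)
}

#' Pearson correlation of two t-maps
#'
#' Computed over the intersection of both analysis masks.
#'
#' @param a,b [TMap-class] objects on the same grid.
#' @return correlation coefficient.
#' @export
tmapCorrelation <- function(a, b) {
  if (!identical(dim(a@t@data), dim(b@t@data))) stop("grid mismatch")
  sel <- a@mask & b@mask
  stats::cor(a@t@data[sel], b@t@data[sel])
}
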