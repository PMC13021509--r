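# Evaluation metrics for segmentation and registration, and their summary
# statistics.

asArr <- function(x) if (is(x, "Volume")) x@data else x

#' Dice score of two binary masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`; two empty masks score 1.
#'
#' @param a,b binary volumes/arrays of the same shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  a <- asArr(a) > 0; b <- asArr(b) > 0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Jaccard score of two binary masks
#'
#' `JSC = |A intersect B| / |A union B|`; two empty masks score 1.
#'
#' @inheritParams dice
#' @export
jaccard <- function(a, b) {
  a <- asArr(a) > 0; b <- asArr(b) > 0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Probabilistic Dice score of two probability maps
#'
#' Min-overlap form: `pDSC = 2 sum(min(p, q)) / (sum(p) + sum(q))`. On
#' binary inputs this reduces exactly to the Dice score.
#'
#' @param p,q probability volumes/arrays in [0, 1], same shape.
#' @export
probabilisticDice <- function(p, q) {
  p <- asArr(p); q <- asArr(q)
  if (!identical(dim(p), dim(q))) stop("shape mismatch")
  if (min(p, q) < -1e-9 || max(p, q) > 1 + 1e-9)
    stop("inputs must lie in [0, 1]")
  s <- sum(p) + sum(q)
  if (s == 0) return(1)
  2 * sum(pmin(p, q)) / s
}

# Hard class assignment from a continuous label map: argmax over the
# decoded channels (background, CSF, GM, WM); ties resolve toward the
# lower class index.
hardClasses <- function(labels) {
  prob <- decodeLabels(labels)
  d <- dim(prob)[1:3]
  pm <- matrix(prob, prod(d), 4L)
  array(max.col(pm, ties.method = "first") - 1L, d)  # 0 = background
}

#' Per-class and foreground segmentation scores
#'
#' Binarizes each tissue class by argmax over the decoded probability
#' channels and computes DSC, pDSC and JSC per class plus their unweighted
#' mean as the foreground score, on the 0-100 scale.
#'
#' @param pred,ref [TissueLabelMap-class] objects on the same grid.
#' @return data.frame with one row per score type (DSC, pDSC, JSC) and
#'   columns CSF, GM, WM, foreground.
#' @export
tissueScores <- function(pred, ref) {
  if (!identical(dim(asArr(pred)), dim(asArr(ref)))) stop("grid mismatch")
  hp <- hardClasses(pred); hr <- hardClasses(ref)
  pp <- decodeLabels(pred); pr <- decodeLabels(ref)
  classes <- c(CSF = 1L, GM = 2L, WM = 3L)
  out <- data.frame(score = c("DSC", "pDSC", "JSC"))
  for (nm in names(classes)) {
    k <- classes[[nm]]
    out[[nm]] <- 100 * c(dice(hp == k, hr == k),
                         probabilisticDice(pp[, , , k + 1], pr[, , , k + 1]),
                         jaccard(hp == k, hr == k))
  }
  out$foreground <- rowMeans(out[, names(classes)])
  out
}

#' Registration quality scores
#'
#' Dissimilarity as the voxel-wise MSE between the warped map and the
#' template, and regularity as the linear elasticity of the deformation.
#'
#' @param warped,template [Volume-class] objects on the same grid.
#' @param phi [DeformationField-class].
#' @param params [elasticityParams()].
#' @return named numeric `c(MSE = ..., LE = ...)`.
#' @export
registrationScores <- function(warped, template, phi,
                               params = elasticityParams()) {
  if (!identical(dim(warped@data), dim(template@data))) stop("grid mismatch")
  c(MSE = mean((warped@data - template@data)^2),
    LE = linearElasticity(phi, params))
}

#' Summary statistics of a score distribution
#'
#' Median as the measure of central tendency, plus the 95th percentile
#' (linear interpolation), maximum and minimum.
#'
#' @param scores numeric vector.
#' @return named numeric `c(median, p95, max, min)`.
#' @export
summarizeScores <- function(scores) {
  c(median = stats::median(scores),
    p95 = stats::quantile(scores, 0.95, names = FALSE, type = 7),
    max = max(scores), min = min(scores))
}
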