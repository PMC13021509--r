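# Skull-strip masking contract and intensity normalization.
#
# Bias-field correction is an external preprocessing step: these functions
# expect already bias-corrected input and only mask and rescale it.

#' Zero all voxels outside a brain mask
#'
#' @param v [Volume-class].
#' @param tissueMask binary [Volume-class] (or logical/numeric array) of the
#'   same shape; nonzero means tissue.
#' @return [Volume-class] with voxels outside the mask set to exactly 0.
#' @export
applyBrainMask <- function(v, tissueMask) {
  m <- if (is(tissueMask, "Volume")) tissueMask@data else tissueMask
  if (!identical(dim(m), dim(v@data)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match volume shape ", paste(dim(v@data), collapse = "x"))
  out <- v@data
  out[!(m > 0)] <- 0
  withVolData(v, out)
}

#' Min-max intensity scaling with a logarithmic upper tail
#'
#' Intensities are scaled linearly between the 0.5th and 99.5th percentile of
#' the masked voxels. Values whose scaled intensity s exceeds 1 are not
#' clipped but mapped to 1 + log10(s), preserving contrast in extreme-value
#' regions (e.g. blood vessels). Values below the lower percentile clip to 0.
#'
#' @param v [Volume-class] (bias-corrected, skull-stripped).
#' @param mask binary [Volume-class] or array selecting the voxels the
#'   percentiles are computed over; must select more than 100 voxels.
#' @param probs the two percentiles, default `c(0.005, 0.995)`.
#' @return normalized [Volume-class]; the transform is applied to every voxel.
#' @export
minmaxLogScale <- function(v, mask, probs = c(0.005, 0.995)) {
  m <- if (is(mask, "Volume")) mask@data else mask
  if (!identical(dim(m), dim(v@data))) stop("mask/volume shape mismatch")
  sel <- v@data[m > 0]
  if (length(sel) <= 100) stop("mask must select more than 100 voxels")
  q <- stats::quantile(sel, probs = probs, names = FALSE, type = 7)
  lo <- q[1]; hi <- q[2]
  if (hi <= lo) stop("degenerate percentiles: lo == hi")
  s <- (v@data - lo) / (hi - lo)
  out <- pmin(pmax(s, 0), 1)
  tail <- s > 1
  out[tail] <- 1 + log10(s[tail])
  withVolData(v, array(out, dim(v@data)))
}
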