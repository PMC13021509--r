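# Multilevel activation and continuous-label <-> probability conversion.

#' Multilevel activation function
#'
#' Sum of six sigmoids mapping an unbounded network output onto the
#' continuous tissue-label scale with plateaus at 0, 1, 1.5, 2, 2.5 and 3:
#' `f(x) = S(a*x) + sum_{i in {1.5, 2, 2.5, 3}} S(a*(x - i)) / 2` with
#' `S(x) = 1 / (1 + exp(-x))`. Output lies in (0, 3) and is non-decreasing
#' in `x`; the slope parameter `a` (alpha) is trainable in the segmentation
#' head.
#'
#' @param x numeric vector/array (pre-activation values).
#' @param alpha positive slope parameter.
#' @return values in (0, 3), same shape as `x`.
#' @export
multilevelActivation <- function(x, alpha = 4) {
  if (alpha <= 0) stop("alpha must be positive")
  out <- sigmoidStable(alpha * x)
  for (i in MULTILEVEL_LEVELS) out <- out + sigmoidStable(alpha * (x - i)) / 2
  out
}

MULTILEVEL_LEVELS <- c(1.5, 2, 2.5, 3)

sigmoidStable <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derivative pieces used by the network backward pass
multilevelBackward <- function(x, alpha, dOut) {
  sp <- function(z) { s <- sigmoidStable(z); s * (1 - s) }
  dfdx <- alpha * sp(alpha * x)
  dfda <- x * sp(alpha * x)
  for (i in MULTILEVEL_LEVELS) {
    s <- sp(alpha * (x - i))
    dfdx <- dfdx + alpha * s / 2
    dfda <- dfda + (x - i) * s / 2
  }
  list(dx = dOut * dfdx, dalpha = sum(dOut * dfda))
}

#' Decode a continuous label map into per-class probability channels
#'
#' Uses triangular kernels `p_k(x) = max(0, 1 - |x - k|)` for CSF (k = 1),
#' GM (k = 2) and WM (k = 3) plus background `max(0, 1 - x)`: a label of 1.5
#' decodes to half CSF / half GM, matching the partial-volume semantics of
#' the continuous scale.
#'
#' @param labels [TissueLabelMap-class] or array with values in [0, 3].
#' @return X x Y x Z x 4 array, channels (background, CSF, GM, WM).
#' @export
decodeLabels <- function(labels) {
  x <- if (is(labels, "Volume")) labels@data else labels
  if (min(x) < -1e-6 || max(x) > 3 + 1e-6) stop("labels outside [0, 3]")
  d <- dim(x)
  out <- array(0, c(d, 4L))
  out[, , , 1] <- pmax(0, 1 - x)
  for (k in 1:3) out[, , , k + 1] <- pmax(0, 1 - abs(x - k))
  out
}

#' Encode per-class probability channels into a continuous label map
#'
#' Inverse of [decodeLabels()] on single-mixture voxels:
#' `label = 1*CSF + 2*GM + 3*WM`.
#'
#' @param prob X x Y x Z x 4 array (background, CSF, GM, WM), channels
#'   non-negative with tissue channels summing to at most 1 + 1e-6.
#' @param ... geometry arguments passed to [TissueLabelMap()] (spacing etc.).
#' @return [TissueLabelMap-class].
#' @export
encodeLabels <- function(prob, ...) {
  stopifnot(length(dim(prob)) == 4L, dim(prob)[4] == 4L)
  if (min(prob) < -1e-6) stop("channels must be non-negative")
  tissueSum <- prob[, , , 2] + prob[, , , 3] + prob[, , , 4]
  if (max(tissueSum) > 1 + 1e-6) stop("tissue channels must sum to <= 1")
  lab <- prob[, , , 2] + 2 * prob[, , , 3] + 3 * prob[, , , 4]
  TissueLabelMap(array(lab, dim(prob)[1:3]), ...)
}
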