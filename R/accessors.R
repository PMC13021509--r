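# Accessor generics and constructors for the central data objects.

#' @rdname Volume-class
#' @param data 3D numeric array.
#' @param spacing voxel size in mm (numeric of length 3 or scalar).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a centered
#'   RAS-style affine built from `spacing`.
#' @param spaceTag `"native"` (default) or `"template"`.
#' @return A [Volume-class] object.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   spaceTag = "native") {
  data <- as.array(data)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- centeredAffine(dim(data), spacing)
  new("Volume", data = data, spacing = spacing, affine = affine,
      spaceTag = spaceTag)
}

#' @rdname TissueLabelMap-class
#' @param data 3D array of continuous labels in [0, 3] or a [Volume-class].
#' @param ... passed to [Volume()].
#' @export
TissueLabelMap <- function(data, ...) {
  v <- if (is(data, "Volume")) data else Volume(data, ...)
  new("TissueLabelMap", data = pmin(pmax(v@data, 0), 3), spacing = v@spacing,
      affine = v@affine, spaceTag = v@spaceTag)
}

#' @rdname VelocityPair-class
#' @param vFwd,vBwd X x Y x Z x 3 displacement arrays in normalized units.
#' @export
VelocityPair <- function(vFwd, vBwd = -vFwd) {
  new("VelocityPair", vFwd = vFwd, vBwd = vBwd)
}

#' @rdname DeformationField-class
#' @param disp X x Y x Z x 3 displacement array in normalized coordinates.
#' @export
DeformationField <- function(disp) new("DeformationField", disp = disp)

#' Identity deformation on a grid
#' @param shape integer(3) grid shape.
#' @return [DeformationField-class] with zero displacement.
#' @export
identityDeformation <- function(shape) {
  DeformationField(array(0, c(shape, 3L)))
}

#' Extract the data array of a Volume
#' @param x a [Volume-class].
#' @export
volData <- function(x) x@data

#' Voxel spacing in mm
#' @param x a [Volume-class].
#' @export
volSpacing <- function(x) x@spacing

#' Voxel-to-world affine
#' @param x a [Volume-class].
#' @export
volAffine <- function(x) x@affine

#' Space tag ("native" or "template")
#' @param x a [Volume-class].
#' @export
spaceTag <- function(x) x@spaceTag

#' Replace the data array, keeping the geometry
#' @param x a [Volume-class].
#' @param data replacement array of the same shape.
#' @export
withVolData <- function(x, data) {
  stopifnot(identical(dim(data), dim(x@data)))
  initialize(x, data = data)
}

# Centered affine: world origin at the volume center, axes aligned.
centeredAffine <- function(shape, spacing) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -spacing * (shape - 1) / 2
  a
}
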