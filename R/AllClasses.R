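#' @import methods
NULL

#' Volume: a 3D scalar grid with voxel spacing and world affine
#'
#' The container every stage of the pipeline consumes and produces. `data`
#' holds the scalar grid, `spacing` the voxel size in mm along each axis,
#' `affine` the 4x4 voxel-to-world matrix (0-based voxel indices), and
#' `spaceTag` records whether the volume lives in native or template space.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot affine 4x4 voxel-to-world matrix, invertible.
#' @slot spaceTag `"native"` or `"template"`.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric",
                 affine = "matrix", spaceTag = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a 3D array")
    if (!is.null(d) && any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps * 100)
      msg <- c(msg, "affine must be invertible")
    if (!object@spaceTag %in% c("native", "template"))
      msg <- c(msg, "spaceTag must be 'native' or 'template'")
    if (length(msg)) msg else TRUE
  })

#' TissueLabelMap: continuous tissue label volume in [0, 3]
#'
#' Values 1, 2 and 3 correspond to CSF, GM and WM; 0 is background.
#' Intermediate values encode partial volume (1.5 = CSF-GM, 2.5 = GM-WM).
#'
#' @export
setClass("TissueLabelMap", contains = "Volume",
  validity = function(object) {
    rng <- range(object@data)
    if (rng[1] < -1e-6 || rng[2] > 3 + 1e-6)
      "label values must lie in [0, 3]" else TRUE
  })

#' VelocityPair: forward and backward stationary half velocity fields
#'
#' Both fields are stored as X x Y x Z x 3 arrays of displacements in
#' normalized coordinates (the [-1, 1] convention used by the registration
#' network output).
#'
#' @slot vFwd 4D array, the half velocity field v^(1/2).
#' @slot vBwd 4D array, the half velocity field v^(-1/2).
#' @export
setClass("VelocityPair",
  representation(vFwd = "array", vBwd = "array"),
  validity = function(object) {
    msg <- character()
    df <- dim(object@vFwd); db <- dim(object@vBwd)
    if (length(df) != 4L || df[4] != 3L) msg <- c(msg, "vFwd must be X*Y*Z*3")
    if (!identical(df, db)) msg <- c(msg, "vFwd and vBwd must share a grid")
    if (!all(is.finite(object@vFwd)) || !all(is.finite(object@vBwd)))
      msg <- c(msg, "velocity fields must be finite")
    if (length(msg)) msg else TRUE
  })

#' DeformationField: dense coordinate map in normalized coordinates
#'
#' Represented as identity plus displacement; `disp` is an X x Y x Z x 3
#' array so that phi(x) = x + disp(x) with x in [-1, 1]^3 normalized
#' coordinates. Sampling an image through the identity field returns the
#' image unchanged (within interpolation tolerance).
#'
#' @slot disp 4D displacement array.
#' @export
setClass("DeformationField",
  representation(disp = "array"),
  validity = function(object) {
    d <- dim(object@disp)
    if (length(d) != 4L || d[4] != 3L) return("disp must be X*Y*Z*3")
    if (!all(is.finite(object@disp))) return("displacements must be finite")
    TRUE
  })

#' PatchGrid: patch origins over the high-resolution analysis grid
#'
#' Holds the 3x3x3 = 27 patch origins (0-based voxel offsets), the shared
#' patch shape, and for each patch the index of the effective model it is
#' served by together with a sagittal flip flag. Right-hemisphere patches
#' map onto their mirrored left partners, reducing 27 positions to 18
#' effective models.
#'
#' @slot origins integer matrix 27 x 3 (0-based).
#' @slot patchShape integer(3).
#' @slot gridShape integer(3), the analysis grid the patches tile.
#' @slot modelIndex integer(27), effective model per patch.
#' @slot flip logical(27), TRUE where the patch is applied mirrored.
#' @export
setClass("PatchGrid",
  representation(origins = "matrix", patchShape = "integer",
                 gridShape = "integer", modelIndex = "integer",
                 flip = "logical"),
  validity = function(object) {
    msg <- character()
    o <- object@origins; p <- object@patchShape; g <- object@gridShape
    if (ncol(o) != 3L) msg <- c(msg, "origins must have 3 columns")
    if (any(o < 0) || any(sweep(o, 2, g - p, ">")))
      msg <- c(msg, "every patch must lie fully inside the grid")
    if (length(object@modelIndex) != nrow(o) || length(object@flip) != nrow(o))
      msg <- c(msg, "modelIndex/flip must have one entry per patch")
    if (length(msg)) msg else TRUE
  })

#' TMap: a voxel-wise t-statistic map with its analysis mask
#'
#' @slot t Volume of t-statistics (0 outside the mask).
#' @slot df residual degrees of freedom of the underlying fits.
#' @slot mask logical array, the analysis mask.
#' @export
setClass("TMap",
  representation(t = "Volume", df = "numeric", mask = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@t@data), dim(object@mask)))
      msg <- c(msg, "t and mask grids must match")
    if (object@df < 1) msg <- c(msg, "df must be >= 1")
    if (any(!is.finite(object@t@data[object@mask])))
      msg <- c(msg, "t must be finite inside the mask")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, space '%s'\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              object@spaceTag))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VelocityPair", function(object) {
  d <- dim(object@vFwd)
  cat(sprintf("VelocityPair on %dx%dx%d grid, max |v| = %.4g (normalized units)\n",
              d[1], d[2], d[3], max(abs(object@vFwd), abs(object@vBwd))))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  cat(sprintf("DeformationField on %dx%dx%d grid, max |disp| = %.4g (normalized units)\n",
              d[1], d[2], d[3], max(abs(object@disp))))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %s on %s grid, %d effective models\n",
              nrow(object@origins), paste(object@patchShape, collapse = "x"),
              paste(object@gridShape, collapse = "x"),
              length(unique(object@modelIndex))))
})

setMethod("show", "TMap", function(object) {
  cat(sprintf("TMap: df = %g, %d voxels in mask, |t| max = %.3f\n",
              object@df, sum(object@mask),
              max(abs(object@t@data[object@mask]), 0)))
})
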