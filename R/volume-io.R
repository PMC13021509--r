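# NIfTI I/O, grid presets, resampling and the analysis-crop convention.

#' Named grid presets
#'
#' The template-space grids used across the pipeline: `"0.5mm"`
#' (339 x 411 x 339, with the 336 x 384 x 336 analysis crop), `"0.75mm"`
#' (224 x 256 x 224), `"1.5mm"` (113 x 137 x 113), plus the desk-scale
#' grids `"desk"` (48^3 at 3 mm) and `"desk_half"` (24^3 at 6 mm) that the
#' tests and examples run on. All analysis shapes are divisible by 16 as
#' required by the UNet downsampling path.
#'
#' @param name preset name.
#' @return list with `shape`, `spacing`, `cropShape`, `cropOrigin` (0-based).
#' @export
gridPreset <- function(name = c("0.5mm", "0.75mm", "1.5mm", "desk", "desk_half")) {
  name <- match.arg(name)
  switch(name,
    "0.5mm" = list(shape = c(339L, 411L, 339L), spacing = rep(0.5, 3),
                   cropShape = c(336L, 384L, 336L),
                   cropOrigin = c(1L, 13L, 1L)),
    "0.75mm" = list(shape = c(224L, 256L, 224L), spacing = rep(0.75, 3),
                    cropShape = c(224L, 256L, 224L), cropOrigin = c(0L, 0L, 0L)),
    "1.5mm" = list(shape = c(113L, 137L, 113L), spacing = rep(1.5, 3),
                   cropShape = c(112L, 128L, 112L), cropOrigin = c(0L, 4L, 0L)),
    "desk" = list(shape = c(48L, 48L, 48L), spacing = rep(3, 3),
                  cropShape = c(48L, 48L, 48L), cropOrigin = c(0L, 0L, 0L)),
    "desk_half" = list(shape = c(24L, 24L, 24L), spacing = rep(6, 3),
                       cropShape = c(24L, 24L, 24L), cropOrigin = c(0L, 0L, 0L)))
}

#' Grid specification
#'
#' @param shape integer(3) voxel counts.
#' @param spacing numeric(3) mm per voxel.
#' @param cropOrigin integer(3) 0-based offset of the analysis crop.
#' @param cropShape integer(3) shape of the analysis crop.
#' @return a `GridSpec` list.
#' @export
gridSpec <- function(shape, spacing, cropOrigin = c(0L, 0L, 0L),
                     cropShape = shape) {
  stopifnot(length(shape) == 3, all(shape >= 1), all(spacing > 0),
            all(cropOrigin >= 0), all(cropOrigin + cropShape <= shape))
  list(shape = as.integer(shape), spacing = as.numeric(spacing),
       cropOrigin = as.integer(cropOrigin), cropShape = as.integer(cropShape))
}

# Voxel-to-world affine of a grid spec (centered, axis-aligned).
gridAffine <- function(spec) centeredAffine(spec$shape, spec$spacing)

#' Read a 3D NIfTI file into a Volume
#'
#' Data are cast to double (float32-compatible); spacing is derived from the
#' affine column norms. 4D or higher-dimensional images are rejected.
#'
#' @param path path to a NIfTI-1/2 file (.nii or .nii.gz).
#' @param spaceTag space tag to attach.
#' @return a [Volume-class].
#' @export
readVolume <- function(path, spaceTag = "native") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D (dims: ",
         paste(d, collapse = "x"), ")")
  aff <- structure(RNifti::xform(img), class = "matrix")
  aff <- matrix(as.numeric(aff), 4, 4)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  new("Volume", data = array(as.double(img), d), spacing = spacing,
      affine = aff, spaceTag = spaceTag)
}

#' Write a Volume to a NIfTI file
#'
#' Round trip through [readVolume()] preserves the data within float32
#' precision and the affine exactly.
#'
#' @param v a [Volume-class].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype, default `"float"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path, datatype = "float") {
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing   # must precede the xform assignment
  RNifti::qform(img) <- structure(v@affine, code = 2L)
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a Volume onto a target grid through an affine transform
#'
#' For every voxel of the target grid, its world coordinate is mapped
#' through `transform` (target world -> source world) and the source volume
#' is interpolated there. Out-of-field voxels are zero.
#'
#' @param v source [Volume-class].
#' @param target a `GridSpec` (see [gridSpec()]) or another Volume whose grid
#'   is used.
#' @param transform 4x4 world-to-world matrix (identity by default).
#' @param interpolation `"trilinear"`, `"bspline"` (cubic) or `"nearest"`.
#' @param spaceTag tag for the output volume.
#' @return [Volume-class] on the target grid.
#' @export
resampleToGrid <- function(v, target, transform = diag(4),
                           interpolation = c("trilinear", "bspline", "nearest"),
                           spaceTag = "template") {
  interpolation <- match.arg(interpolation)
  if (is(target, "Volume"))
    target <- list(shape = dim(target@data), spacing = target@spacing,
                   affine = target@affine)
  tAff <- if (!is.null(target$affine)) target$affine else gridAffine(target)
  if (abs(det(transform)) < 1e-12) stop("singular transform")
  idx <- voxelIndexGrid(target$shape)
  world <- cbind(idx, 1) %*% t(tAff)          # target voxel -> target world
  srcWorld <- world %*% t(transform)          # -> source world
  srcVox <- srcWorld %*% t(solve(v@affine))   # -> source voxel
  coords <- srcVox[, 1:3, drop = FALSE]
  vals <- switch(interpolation,
    trilinear = sampleTrilinear(v@data, coords),
    nearest = sampleNearest(v@data, coords),
    bspline = sampleBspline(bsplinePrefilter(v@data), coords))
  new("Volume", data = array(vals, target$shape),
      spacing = as.numeric(target$spacing), affine = tAff,
      spaceTag = spaceTag)
}

#' Crop a Volume to the analysis grid of its preset
#'
#' The high-resolution template grid carries a fixed crop (for the 0.5 mm
#' preset: 339 x 411 x 339 down to 336 x 384 x 336 at origin (1, 13, 1)) so
#' that the analysis shape is divisible by 16. A warning is raised when
#' nonzero values touch the crop boundary (tissue coverage at risk).
#'
#' @param v [Volume-class] on the preset's full grid.
#' @param preset preset name or `GridSpec`.
#' @return cropped [Volume-class].
#' @export
cropToAnalysisGrid <- function(v, preset = "0.5mm") {
  spec <- if (is.character(preset)) gridPreset(preset) else preset
  if (!identical(dim(v@data), as.integer(spec$shape)))
    stop("input grid ", paste(dim(v@data), collapse = "x"),
         " does not match preset grid ", paste(spec$shape, collapse = "x"))
  o <- spec$cropOrigin; s <- spec$cropShape
  sub <- v@data[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
                o[3] + seq_len(s[3]), drop = FALSE]
  cropped <- sub
  # coverage warning: nonzero data on any crop face
  faces <- c(sub[1, , ], sub[s[1], , ], sub[, 1, ], sub[, s[2], ],
             sub[, , 1], sub[, , s[3]])
  if (any(faces != 0))
    warning("nonzero values touch the analysis-crop boundary")
  aff <- v@affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% o
  new("Volume", data = cropped, spacing = v@spacing, affine = aff,
      spaceTag = v@spaceTag)
}

#' Undo the analysis crop, padding with zeros
#'
#' @param v cropped [Volume-class].
#' @param preset preset name or `GridSpec`.
#' @return [Volume-class] on the preset's full grid.
#' @export
uncropFromAnalysisGrid <- function(v, preset = "0.5mm") {
  spec <- if (is.character(preset)) gridPreset(preset) else preset
  if (!identical(dim(v@data), as.integer(spec$cropShape)))
    stop("input does not match the preset crop shape")
  full <- array(0, spec$shape)
  o <- spec$cropOrigin; s <- spec$cropShape
  full[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]), o[3] + seq_len(s[3])] <-
    v@data
  aff <- v@affine
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% o
  new("Volume", data = full, spacing = v@spacing, affine = aff,
      spaceTag = v@spaceTag)
}
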