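# End-to-end prediction pipeline and cross-dataset fold assignment.

#' Run the six-step VBM preprocessing pipeline
#'
#' Executes, in order: brain masking (the brain-extraction step itself is an
#' external interface — a mask must be supplied), intensity normalization,
#' affine registration to the template, tissue segmentation, tissue
#' separation with GM masking, nonlinear registration, and
#' modulation + smoothing. Seven NIfTI outputs are written, plus a JSON
#' sidecar with per-step provenance (step list, config hash, seed, output
#' checksums).
#'
#' @param input native T1w [Volume-class] (bias-corrected).
#' @param brainMask binary [Volume-class] from an external brain-extraction
#'   tool; `NULL` raises an error naming the interface.
#' @param models list with `seg` (a [trainCascade()] bank) and `reg`
#'   (a [buildRegNet()] network).
#' @param template list with `image`, `mask`, `gm`, `wm`,
#'   `gmMaskResource` (ventricle/brain-stem masking volume, optional).
#' @param outDir output directory (created if needed).
#' @param config list: `fwhmMm` (default 6), `modulate` (default TRUE),
#'   `seed`, `affine` (config for [affineRegister()]), `tau`.
#' @return invisible list with the outputs, the sidecar path and the
#'   per-file checksums.
#' @export
runPipeline <- function(input, brainMask, models, template, outDir,
                        config = list()) {
  if (is.null(brainMask))
    stop("brain-extraction interface: a brain mask volume is required ",
         "(brain extraction itself is performed by an external tool)")
  cfg <- utils::modifyList(list(fwhmMm = 6, modulate = TRUE, seed = 1L,
                                affine = list(), tau = 7L), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  steps <- character()
  outputs <- list()

  # 1. masking + intensity normalization
  masked <- applyBrainMask(input, brainMask)
  normed <- minmaxLogScale(masked, brainMask)
  steps <- c(steps, "brain_mask", "intensity_normalization")

  # 2. affine registration onto the template grid
  reg <- affineRegister(normed, template$image, brainMask, template$mask,
                        config = cfg$affine)
  tSpec <- list(shape = dim(template$image@data),
                spacing = template$image@spacing,
                affine = template$image@affine)
  affined <- resampleToGrid(normed, tSpec, transform = reg$affine,
                            interpolation = "trilinear")
  outputs$affine <- affined
  steps <- c(steps, "affine_registration")

  # 3. tissue segmentation
  seg <- predictTissue(models$seg, affined)
  outputs$seg <- seg
  steps <- c(steps, "tissue_segmentation")

  # 4. tissue separation + GM masking
  prob <- decodeLabels(seg)
  gm <- withVolData(template$image, prob[, , , 3])
  wm <- withVolData(template$image, prob[, , , 4])
  if (!is.null(template$gmMaskResource))
    gm <- gmMask(gm, template$gmMaskResource)
  outputs$p1 <- gm
  outputs$p2 <- wm
  steps <- c(steps, "tissue_separation")

  # 5. nonlinear registration
  vpair <- predictVelocity(models$reg, gm, wm, template$gm, template$wm)
  ph <- deformationsFromPair(vpair, cfg$tau)
  jdet <- jacobianDeterminant(ph$fwd, spacing = gm@spacing,
                              affine = gm@affine)
  outputs$jdet <- jdet
  wGm <- warpVolume(gm, ph$fwd)
  wWm <- warpVolume(wm, ph$fwd)
  steps <- c(steps, "nonlinear_registration")

  # 6. modulation + smoothing
  if (cfg$modulate) {
    wGm <- modulate(wGm, jdet)
    wWm <- modulate(wWm, jdet)
  }
  outputs$s6mwp1 <- smoothFwhm(wGm, cfg$fwhmMm)
  outputs$s6mwp2 <- smoothFwhm(wWm, cfg$fwhmMm)
  steps <- c(steps, "smoothing")

  files <- character()
  for (nm in names(outputs)) {
    f <- file.path(outDir, paste0(nm, ".nii"))
    writeVolume(outputs[[nm]], f)
    files[nm] <- f
  }
  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(cfg[c("fwhmMm", "modulate", "seed", "tau")], cfgFile,
                       auto_unbox = TRUE, digits = NA)
  checksums <- as.character(tools::md5sum(files))
  names(checksums) <- names(files)
  sidecar <- list(steps = steps,
                  configHash = as.character(tools::md5sum(cfgFile)),
                  seed = cfg$seed, outputs = as.list(checksums))
  sidecarPath <- file.path(outDir, "provenance.json")
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = TRUE)
  invisible(list(outputs = outputs, files = files, sidecar = sidecarPath,
                 checksums = checksums, affine = reg$affine))
}

#' Grouped (cross-dataset) cross-validation folds
#'
#' Assigns every dataset to exactly one of k folds (all scans of a dataset
#' stay together), with fold sizes balanced within one dataset.
#'
#' @param datasetIds character/factor vector, one entry per scan.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return list with `foldOfDataset` (named integer vector) and
#'   `foldOfScan` (integer vector aligned with `datasetIds`).
#' @export
crossvalSplit <- function(datasetIds, k = 5L, seed = 1L) {
  ids <- unique(as.character(datasetIds))
  if (k > length(ids))
    stop("k = ", k, " exceeds the number of datasets (", length(ids), ")")
  shuffled <- withSeed(seed, sample(ids))
  fold <- stats::setNames(rep(seq_len(k), length.out = length(ids)), shuffled)
  list(foldOfDataset = fold[ids],
       foldOfScan = unname(fold[as.character(datasetIds)]))
}
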