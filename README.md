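# vbmnet

Neural-network preprocessing and statistics for voxel-based morphometry
(VBM) of T1-weighted brain MRI, implemented end to end in R at desk scale.

VBM measures local differences in brain tissue concentration across
subjects: each scan is segmented into CSF, gray matter (GM) and white
matter (WM), the tissue probability maps are spatially normalized to a
template, and a general linear model is fit per voxel, giving a t-map of
the association between tissue probability and a covariate of interest
(age, sex, diagnosis, ...). vbmnet provides every stage of that chain:

* **Volumes** — a `Volume` S4 container (3D array + spacing + world
  affine), NIfTI I/O via RNifti, trilinear / nearest / cubic-B-spline
  resampling, and the fixed template-grid presets (0.5 mm: 339x411x339
  with its 336x384x336 analysis crop; 0.75 mm; 1.5 mm; desk grids).
* **Intensity** — brain-mask application and min-max scaling between the
  0.5th/99.5th percentiles with a `1 + log10(s)` upper tail.
* **Augmentation** — 12 seeded artifact generators (bias field, motion,
  chi noise, blur, ghosting, spikes, downsampling, translation, flip,
  brightness, contrast, Gibbs ringing) and the 7-kind x 2-intensity
  synthetic-artifact test protocol.
* **Tissue segmentation** — a cascaded patchwise 3D UNet bank: full-view
  low-resolution stage, 27 patches with 18 effective models via sagittal
  weight sharing, tissue-driven patch-position optimization, Gaussian
  importance blending, and a trainable six-sigmoid multilevel activation
  mapping network output onto the continuous 0-3 tissue label scale
  (1 = CSF, 2 = GM, 3 = WM, mixtures in between).
* **Registration** — stationary-velocity-field diffeomorphisms via
  scaling and squaring (tau = 7), symmetric half-deformation composition
  (`Phi = SS(v^1/2) o SS(-v^-1/2)`), linear-elasticity regularization, the
  SyN-style symmetric loss, supervised velocity/Jacobian losses
  (`beta = 2e-5`), velocity distillation from reference deformations, and
  a tanh-bounded UNet predicting the half-field pair. Affine registration
  minimizes MSE + soft Dice over 12 parameters in a 12 mm -> 6 mm
  two-stage schedule plus a short native-resolution polish.
* **Metrics** — Dice, probabilistic Dice, Jaccard, per-class/foreground
  tissue scores on the 0-100 scale, registration MSE + linear elasticity,
  median/95th-percentile summaries.
* **VBM statistics** — GM masking, Jacobian modulation, 6 mm FWHM
  smoothing, voxel-wise OLS t-maps, the 100 x 80%-resampled median t-map,
  and t-map correlation.
* **Phantoms** — a synthetic head generator (nested CSF/GM/WM ellipsoid
  compartments with exact partial-volume labels, ventricles, brainstem
  mask), atrophy progressions (0.1-1 mm cortical thinning), ground-truth
  diffeomorphic deformations, and VBM cohorts with injected regional
  effects.

The small conv-nets are implemented in pure R (im2col + BLAS, manual
backprop, Adam, one-cycle schedule) and train on a single CPU in minutes;
there is no GPU dependency and no pretrained-weight download. Brain
extraction and N4 bias correction are *interfaces*: supply a mask and
bias-corrected intensities from the external tools of your choice.

## Worked example

Generate a phantom, train a tiny cascade on it, and score the prediction
against the phantom's own ground truth:

```r
library(vbmnet)

ph  <- makePhantom(phantomSpec(seed = 42))      # 48^3 head phantom, 3 mm
img <- minmaxLogScale(ph$image, ph$brainMask)   # normalized intensities

cfg  <- segTrainConfig(stage1Epochs = 150L, foundationEpochs = 30L,
                       finetuneEpochs = 120L, lrMax = 2e-2)
bank <- trainCascade(list(list(image = img, labels = ph$labels)), cfg,
                     seed = 11)
pred <- predictTissue(bank, img)
tissueScores(pred, ph$labels)
```

```
  score      CSF       GM       WM foreground
1   DSC 98.03363 98.68275 99.08020   98.59886
2  pDSC 96.65290 97.81323 98.77313   97.74642
3   JSC 96.14310 97.39975 98.17716   97.24000
```

The `foreground` column is the unweighted mean of the CSF/GM/WM scores on
the 0-100 scale; an overfit run like this one demonstrates that the full
cascade (patch optimization, weight sharing, importance blending,
multilevel head) can reproduce a known segmentation. The registration side
has the same flavor:

```r
gt  <- makeDeformationTruth(c(24L, 24L, 24L), amplitudeVox = 1.5,
                            smoothVox = 3, seed = 7)
res <- velocityFromDeformation(gt$phiFwd, gt$phiBwd, iters = 300,
                               lr = 0.5, tol = 1e-12)
max(abs(deformationsFromPair(res$vpair)$fwd@disp - gt$phiFwd@disp)) * 23 / 2
#> [1] 0.026  # voxels: the distilled pair reproduces the deformation
```

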