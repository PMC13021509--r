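---
title: "vbmnet: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vbmnet: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

vbmnet implements a complete neural-network preprocessing chain for
voxel-based morphometry (VBM) of T1-weighted brain MRI at desk scale:
intensity normalization, k-space/spatial data augmentation, cascaded
patchwise tissue segmentation, symmetric diffeomorphic registration driven
by stationary velocity fields, gradient-based affine registration,
evaluation metrics, and the downstream voxel-wise GLM statistics. Brain
extraction and bias-field correction are interfaces, not implementations:
every entry point expects a brain mask and bias-corrected intensities from
external tools. All networks are small and trainable on a single CPU using
the built-in head-phantom generator; nothing in the package depends on
pretrained weights.

# Data model and coordinate conventions

A `Volume` is a 3D scalar array with voxel spacing (mm) and a 4x4
voxel-to-world affine; voxel indexing is 0-based. Tissue is represented as
a continuous label in [0, 3] (`TissueLabelMap`): 1 = CSF, 2 = GM, 3 = WM,
0 = background, with intermediate values encoding partial volume (1.5 is
the CSF-GM mixture, 2.5 GM-WM). Decoding to per-class probabilities uses
triangular kernels `p_k(x) = max(0, 1 - |x - k|)`; this is one of several
possible conventions for a continuous label scale and is flagged as a
package choice — its defining property, exact invertibility of
encode(decode(x)) over the whole range, is what the tests pin down.

Registration quantities (velocity fields, deformations) live in normalized
coordinates: each axis spans [-1, 1] with the endpoints at the *centers*
of the first and last voxels, matching the output range of a tanh network
head. Deformations are stored as identity-plus-displacement. Displacement
sampling is edge-clamped trilinear (stable at the boundary); image warping
uses zero fill (after skull stripping there is no information outside the
head). Grid presets record the reference shapes (0.5 mm: 339x411x339 with
a 336x384x336 analysis crop; 0.75 mm: 224x256x224; 1.5 mm: 113x137x113)
plus the desk grids (48^3 at 3 mm, 24^3 at 6 mm) that tests and examples
use. The crop origin within the 0.5 mm grid is not prescribed anywhere, so
the centered offset (1, 13, 1) is recorded as a package constant.

# Intensity normalization

Min-max scaling between the 0.5th and 99.5th percentile of the masked
voxels, with the upper tail mapped through `1 + log10(s)` instead of
clipping, preserving contrast in extreme-intensity structures such as
vessels. Values below the lower percentile clip to 0; only the upper clip
is overridden by the log tail. Percentiles use the linear-interpolation
definition (R type 7) over masked voxels only.

# Augmentation

Twelve kinds: bias field, motion, chi noise, blur, ghosting, spike,
downsampling, translation, flip, brightness, contrast, Gibbs ringing. The
k-space kinds modify the FFT of the image; bias fields are the
exponential of an inverse FFT of Gaussian noise restricted to frequencies
of at most 4 cycles per field of view; chi noise adds k Gaussian channels
in quadrature with the signal (k = 2 is the Rician magnitude limit);
motion averages the k-space with phase-ramped (translated) copies —
translations are exact in k-space and reduce to the identity at zero
amplitude, whereas rotations would not, so the desk implementation uses
translations only. Spatial kinds use nearest-neighbor resampling
(integer-voxel translation, sagittal flip) to avoid interpolation
degradation. Every kind is a deterministic function of (kind, strength,
seed) and reduces to the identity at strength 0.

The published protocol does not state numeric artifact strengths, so the
medium/strong preset table is a set of recorded constants (see
`vbmnet:::AUGMENT_PRESETS`), chosen once so that "strong" visibly exceeds
"medium" in artifact energy on a [0, 1]-normalized image. The seven-kind
test suite (noise, bias field, blur, ghosting, motion, ringing, spike at
two intensities) yields 14 corrupted volumes per original.

# Tissue segmentation

A cascade of two UNet stages. Stage 1 sees the whole image at reduced
resolution; stage 2 tiles the analysis grid with 3x3x3 = 27 patches and
trains one network per *effective* patch position. Right-hemisphere
patches are flipped along the sagittal axis, passed through the mirrored
left-hemisphere model, and flipped back, reducing 27 positions to 18
models. Patch positions start on the regular grid and are moved one voxel
at a time toward the image center for as long as every tissue voxel of
every training mask stays covered; mirrored pairs move in lockstep
(sagittal moves mirrored, other axes shared) so flip equivalence stays
exact, and the sweep order is axis 1, 2, 3 within each pass until a pass
makes no move. Patch predictions are blended with Gaussian importance
weights (sigma = patch size / 8 per axis, the patch-based segmentation
convention), normalized to sum to one per voxel; voxels outside every
patch are background by construction of the position optimizer.

The output head is a trainable multilevel activation, the sum of six
sigmoids `S(a x) + sum_i S(a (x - i)) / 2` over i in {1.5, 2, 2.5, 3},
with plateaus at 0, 1, 1.5, 2, 2.5, 3 — an inductive bias toward the
empirical label histogram. The slope a (alpha) is a network parameter,
initialized at 4.0 so the plateaus are visible from the start. Training
minimizes the mean absolute error against the continuous labels under a
one-cycle learning-rate schedule; both UNet stages use ReLU, instance
normalization, depth 4 and channel doubling from 8 at reference scale.

**Desk profile.** The test suite exercises the full structure at reduced
size: 48^3 phantoms at 3 mm, 16^3 patches, depth-2 UNets with 4 base
channels. The reference one-cycle peak rate is 0.001; the desk-scale
overfit runs use a peak rate of 0.02 because the tiny networks and tiny
problem sizes are far from the reference regime and converge an order of
magnitude faster there (the schedule shape, single peak at the configured
value, is unchanged and is what the tests assert). Epoch counts at
reference scale (60 stage-1 epochs, 2 foundation epochs, 20 fine-tuning
epochs per position) are configuration defaults; desk runs scale them to
CPU budgets.

# Diffeomorphic registration

The stationary-velocity framework: a velocity field v is integrated by
scaling and squaring (`tau = 7` halvings, then `tau` self-compositions) to
a deformation `Phi`. Symmetry follows the half-deformation construction:
the network predicts both half fields `v^(1/2)` and `v^(-1/2)`, and

* `Phi = SS(v^(1/2)) o SS(-v^(-1/2))`,
* `Phi^(-1) = SS(v^(-1/2)) o SS(-v^(1/2))`,

the only reading of the half-composition convention that makes
`Phi o Phi^(-1) = Id` exact in the continuum. Whether the two half fields
should be tied antisymmetrically (`v^(-1/2)` = `-v^(1/2)`) is left open by
the reference description; the network predicts them independently by
default, with an `antisymmetric` config flag for the tied variant. The
phantom ground-truth generator uses the antisymmetric construction.

The symmetric (SyN-style) loss is
`MSE(I o Phi, J) + MSE(I, J o Phi^-1) + MSE(I o Phi^1/2, J o Phi^-1/2) +
Lambda R(Phi)` with R the linear elasticity
`mean( mu ||eps(u)||^2 + lambda/2 tr(eps(u))^2 )` of the displacement's
symmetrized gradient. The elastic integral is normalized to unit domain
volume so a uniform zoom `u = eps x` gives exactly
`(3 mu + 4.5 lambda) eps^2`, the oracle the tests use; none of mu, lambda,
Lambda is prescribed by the reference description, so the defaults
(1, 1, 0.01) are package choices, configurable everywhere. The supervised
objectives are `L_v` (mean squared half-field disagreement), `L_v` plus
the Jacobian-determinant MSE, and the full
`L_supervised = L_(v,J) + beta L_SyN` with `beta = 2e-5`; network
training descends on `L_v` (the distillation-matching term), while the
richer objectives are computed for evaluation and logging — their
gradients would require differentiating through scaling and squaring,
which the pure-R framework deliberately does not implement.

**Velocity distillation.** Reference deformations are converted to
velocity targets by an iterative first-order descent on the half field w
(pair `(w, -w)`): the update adds the symmetrized reconstruction residual
`(Phi_t - SS(w) o SS(w)) - (Phi_t^-1 - SS(-w) o SS(-w))`, split over the
two half maps, with step-size backtracking (halving on any residual
increase; ten consecutive rejections far from convergence raise a
divergence error with diagnostics). Because the residual compares against
the same discrete reconstruction used everywhere else, a deformation
generated by this machinery is a true zero of the iteration and is
recovered to well below 0.1 voxel. Defaults: 500 iterations, step 0.1,
tolerance 1e-4 on the mean squared residual.

Jacobian determinants and elasticity gradients use central differences in
the interior and one-sided differences at the faces, making the
uniform-zoom oracles exact including the boundary.

# Affine registration

Twelve parameters — translation (in half-field-of-view units so all
parameters share a scale), axis-angle rotation, log-scale, shear — are
optimized by Adam on central-finite-difference gradients of
`MSE(image, template) + soft-Dice loss(masks)`, in the two-stage schedule
of 500 iterations at 12 mm and 100 at 6 mm working resolution with zero
padding, followed by a 50-iteration polish at the template's native
resolution. Three numerical choices matter and are deliberate:

* both images and masks are smoothed to the working resolution before
  downsampling (anti-aliasing): without it the coarse loss surface has its
  minimum displaced by interpolation aliasing, by several degrees in
  rotation on smooth phantoms;
* the learning rate decays cosine-wise within each stage, because Adam's
  scale-free steps otherwise keep wandering in nearly flat directions
  (rotation of a near-ellipsoidal head) instead of settling;
* the polish stage exists because the mm-valued working resolutions were
  designed for ~1 mm acquisitions; on coarser grids (3 mm desk phantoms)
  the 6 mm working grid alone leaves the rotation component
  under-determined (a shallow, rugged loss surface), while the
  native-resolution surface is clean and centered on the true transform.
  The polish loss is evaluated on a fixed, seeded subsample of 20,000
  voxels, which keeps its cost independent of grid size and removes the
  systematic aliasing a regular decimation would reintroduce.

# VBM statistics

GM probability can be zeroed inside a masking resource (ventricles and
brain stem); warped maps are modulated by the Jacobian determinant by
default (volume preservation; switchable), then smoothed with a separable
Gaussian of 6 mm FWHM (`sigma = FWHM / (2 sqrt(2 ln 2))` per axis, zero
padded). Voxel-wise OLS fits give the t-statistic of the covariate of
interest; the analysis mask defaults to mean map intensity > 0.1
(standard practice, configurable). Perfect fits (zero residual) are
reported as sign-preserving effectively-infinite values. The resampled
median map repeats the fit on random 80% subsets (without replacement,
per-repetition seeds derived from a root seed by a counter) and takes the
voxel-wise median; map agreement uses Pearson correlation over the mask
intersection.

# The phantom generator

Phantoms emulate skull-stripped heads as nested ellipsoids: a WM core, a
GM shell of configurable cortical thickness, a CSF envelope, mirrored
ventricles (CSF carved out of deep tissue) and a brainstem mask region.
The compartment surfaces carry a deterministic angular undulation
(`foldAmp`, default 0.06 of the radii) emulating gyral/sulcal folding;
it is even in the sagittal direction, so the midsagittal mirror symmetry
stays exact. The folding matters beyond appearance: a smooth ellipsoid
head is nearly rotation-symmetric, which leaves affine registration
under-determined — a deficiency of the emulation, not of the method.
With `foldAmp = 0` the boundaries are exact ellipsoids, which is what the
analytic shell-volume checks use. Boundaries carry exact partial-volume
labels via a linear sub-voxel ramp on the signed distance to each
interface, so class volumes match the analytic ellipsoid-shell volumes
and every label map round-trips through encode/decode. Intensities are class means (CSF 0.2, GM 0.5, WM 0.8 —
T1w-like contrast) plus a smooth within-class variation field (amplitude
0.03). Cohorts add a covariate-scaled effect inside a spherical region
plus smooth spatial noise to template tissue maps; ages are uniform in
[20, 70], sex and group Bernoulli(0.5). Atrophy series thin the GM shell
in steps of 0.1 mm while the outer CSF envelope stays fixed (CSF fills the
vacated space), so 20 bases with ten progressions plus originals give 220
volumes.

What the phantoms do *not* emulate: gyrification and cortical geometry,
heterogeneous tissue texture, acquisition physics (beyond the augmentation
module), and real covariate-morphology coupling. Tests passing on
phantoms therefore establish that the machinery is correct — not that the
desk-scale networks would segment or register real brains at published
accuracy; that claim would need real cohorts, reference tissue maps and
production-scale training, all outside this package's scope.

# Problem sizes and numerical tolerances

The test and acceptance runs use: 48^3 phantoms (3 mm), 32^3 grids for the
diffeomorphism oracle suite, 24^3 for velocity distillation, 16^3 patches,
and cohorts of 50-60 subjects, chosen as the smallest sizes at which every
structural property of the full-scale method is still exercised.
Interpolation-limited checks use tolerances of 1e-3 to 1e-4; analytic
identities (OLS t-statistics, elasticity closed forms, Jacobians of affine
maps) are asserted at 1e-9 or tighter; the scaling-and-squaring group
inverse is asserted at half a voxel for 2-voxel-amplitude fields, which is
what trilinear composition supports at these grid sizes.

# Known limitations

* Pure-R networks: minutes, not seconds, for desk-scale training; no GPU
  path.
* Trilinear composition limits deformation accuracy at coarse grids; the
  distillation residual floor reflects it.
* The affine optimizer is local; it assumes initialization within the
  capture range typical after brain extraction (tens of mm, tens of
  degrees).
* The B-spline resampler evaluates 64 taps per voxel in R; at the full
  0.5 mm grid it is usable but slow.
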