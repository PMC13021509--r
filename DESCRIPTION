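Package: vbmnet
Title: Neural-Network Preprocessing and Statistics for Voxel-Based Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a neural-network based
    preprocessing pipeline for voxel-based morphometry (VBM) of T1-weighted brain
    MRI. Provides volume handling and NIfTI input/output, intensity normalization,
    k-space and spatial data augmentation, cascaded patchwise tissue segmentation
    with a multilevel activation head, stationary-velocity-field diffeomorphic
    registration with symmetric (SyN-style) and supervised losses, gradient-based
    affine registration, segmentation and registration evaluation metrics,
    voxel-wise GLM t-maps with resampled median maps, and a synthetic head-phantom
    generator supplying ground-truth tissue maps, deformations and cohorts. The
    small 3D convolutional networks are trained with a built-in pure-R framework
    so the whole pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
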