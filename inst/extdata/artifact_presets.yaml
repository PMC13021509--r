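# Named strengths for the seven-artifact synthetic test protocol and the
# remaining training augmentations. These mirror the recorded constants in
# the package (vbmnet:::AUGMENT_PRESETS); strengths are dimensionless
# except where noted (voxels for motion/translate, voxel-sd for blur).
noise:      {medium: 0.05, strong: 0.15}
bias_field: {medium: 0.30, strong: 0.60}
blur:       {medium: 0.70, strong: 1.50}
ghosting:   {medium: 0.30, strong: 0.70}
motion:     {medium: 1.00, strong: 3.00}
gibbs:      {medium: 0.30, strong: 0.55}
spike:      {medium: 0.50, strong: 2.00}
downsample: {medium: 0.50, strong: 1.50}
translate:  {medium: 2.00, strong: 5.00}
brightness: {medium: 0.10, strong: 0.30}
contrast:   {medium: 0.20, strong: 0.50}
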