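# Desk-scale training configuration for the segmentation cascade
# (arguments of vbmnet::segTrainConfig). The reference-scale protocol uses
# 60 / 2 / 20 epochs with a one-cycle peak rate of 0.001; these values are
# the single-CPU desk profile used by the tests and examples.
patchShape: [16, 16, 16]
stage1Scale: 2
stage1Epochs: 150
foundationEpochs: 30
finetuneEpochs: 120
depth: 2
baseChannels: 4
lrMax: 0.02
finetuneLrMax: 0.005
alphaInit: 4.0
flipAugment: false
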