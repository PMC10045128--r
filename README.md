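# ratunet

Skull stripping (brain extraction) for coronal rat brain MR slices with a
residual U-Net. The package is aimed at preclinical stroke imaging, where
DWI/T2WI rat acquisitions must be reduced to a binary brain mask before any
lesion or volumetric analysis, and where strong-field inhomogeneity,
brain-like scalp intensities and ischemic hyperintensities defeat simple
thresholding.

## The method

The segmentation network is a U-shaped encoder–decoder over single-channel
`N × N` slices whose building unit is a pre-activation block
(batch normalization → activation → same-padded 3×3 convolution) at constant
channel width *C*:

* **Encoder** — an initial 3×3 convolution to *C* channels, then five
  2×2/stride-2 max-pooling levels with 2, 2, 3, 3, 3 blocks and a residual
  addition per level; every pooling layer stores its argmax indices.
  14 convolutions, 5 pooling layers.
* **Decoder** — five max-*unpooling* layers driven by the stored indices
  (deepest pool ↔ first unpool), each followed by concatenation with the
  matching encoder output (2*C* channels), a channel-reducing block and —
  at the four inner levels — three more blocks plus a residual addition.
  A sigmoid-activated block and a final 1×1 convolution produce the
  probability map. 19 convolutions, 5 unpooling layers.

33 convolutions in total. Training minimizes the soft Dice loss
Λ = 1 − κ_D, κ_D = (2·Σpg + ε)/(Σp + Σg + ε), with Adam (batch 8, 100
epochs, learning rate 5·10⁻⁴ decaying to 10⁻⁴ after epoch 20), subject-level
6:2:2 splits, five-fold cross-validation, and on-the-fly paired
augmentation (shear ≤ 0.3 rad, rotation ≤ 30°, zoom ≤ 20 %, horizontal
flips). Evaluation reports Dice κ_D, sensitivity κ_st = TP/(TP+FN),
sensibility κ_sb = 1 − FP/(TP+FN), and Hausdorff / average Hausdorff contour
distances in millimetres, plus paired t-tests between methods.

Because the reference rat datasets are in-house and not deposited, the
package includes a synthetic phantom generator (elliptical brain, dark
skull gap, brain-like scalp ring, hyperintense lesion, polynomial bias
field, Rician noise) with exact ground-truth masks, so the entire pipeline
is testable end to end. The network/training kernels (blocked im2col
convolution, batch norm, index-preserving pooling, backprop, Adam) are
implemented in RcppArmadillo and verified against explicit-loop oracles and
numerical differentiation in the test suite.

## Worked example

Generate a phantom cohort, train a desk-scale network, and evaluate
held-out subjects:

```r
library(ratunet)

subs <- generate_phantom_dataset(50, "DWI", seed = 42, matrix_size = 64)
train_ids <- names(subs)[1:40]
test_ids  <- names(subs)[41:50]

stats <- compute_dataset_stats(lapply(subs[train_ids], `[[`, "volume"))
norm  <- lapply(subs, function(s) { s$volume <- zscore_normalize(s$volume, stats); s })

cfg   <- train_config(batch_size = 8, epochs = 10, seed = 42, per_epoch_factor = 1)
model <- build_runet(input_size = 64, base_channels = 16, seed = 42)
fit   <- train_runet(model, subjects_to_slices(norm[train_ids]), cfg = cfg)

res <- sapply(test_ids, function(id) {
  pred <- predict_volume(fit$model, norm[[id]]$volume, threshold = 0.5)
  r <- evaluate_pair(pred$mask, subs[[id]]$mask)
  c(dice = r$dice, avg_hausdorff_mm = r$avg_hausdorff_mm)
})
rowMeans(res)
```

On the fixed seed above the run prints per-epoch training curves ending at

```
epoch  10  lr 5.00e-04  train loss 0.0102 dice 0.9927
```

and held-out means of

```
            dice avg_hausdorff_mm
    0.9999227332     0.0005126347
```

i.e. near-perfect overlap (Dice ≈ 1) and sub-voxel average contour error
(the phantom's in-plane spacing is 0.4 mm), which is the expected ceiling
behaviour on a geometric phantom with exact ground truth. `print(model)`
shows the structural signature:

```
<runet> N=64, width 16: 33 conv (14 encoder + 19 decoder), 5 pool, 5 unpool, 31 BN
```

A command-line front end wrapping the same functions is installed at
`inst/cli/ratunet.R` (subcommands `phantom`, `train`, `crossval`, `predict`,
`evaluate`).

## Package layout

* `R/io.R` — NIfTI I/O, `mr_volume` / `binary_mask` containers, dataset
  statistics and z-score normalization, manifests.
* `R/metrics.R` — confusion counts, Dice / sensitivity / sensibility,
  contours, Hausdorff distances, cohort evaluation, paired t-test.
* `R/augment.R` — paired affine augmentation and deterministic streams.
* `R/network.R` — graph builder, forward/backward executors, pooling with
  indices, unpooling, prediction, checkpoints.
* `R/train.R` — Dice loss, learning-rate schedule, splits and folds,
  Adam training loop, cross-validation.
* `R/phantom.R` — synthetic stroke-rat phantom generator.
* `R/config.R` — YAML configuration and the pipeline smoke run.
* `src/kernels.cpp` — numerical kernels (RcppArmadillo).
* `vignettes/ratunet-methods.Rmd` — model, conventions and design notes.
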