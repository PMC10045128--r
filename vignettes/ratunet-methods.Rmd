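---
title: "Skull stripping rat brain MR slices with a residual U-Net: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull stripping rat brain MR slices with a residual U-Net: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Preclinical stroke studies in rats lean on MRI — diffusion-weighted (DWI)
and T2-weighted (T2WI) coronal acquisitions — and nearly every downstream
analysis (lesion segmentation, hemisphere comparison, volumetry) starts from
a binary brain mask. Skull stripping, the extraction of that mask, is
harder in rats than in humans: stronger fields (7 T and up) bring larger
radio-frequency inhomogeneity, the brain–scalp geometry differs, and
ischemic lesions introduce large intensity variation inside the brain
itself. `ratunet` implements a complete, tested skull-stripping toolkit
around a residual U-Net ("RU-Net") for single-channel coronal MR slices,
together with preprocessing, augmentation, Dice-loss training, evaluation
metrics and a synthetic phantom generator.

## The network

The model is a U-shaped encoder–decoder operating on one `N × N` slice at a
time (`N` divisible by 32). Its building unit is a *block*: batch
normalization, then an activation (ReLU except at the very end), then a
same-padded `3 × 3` convolution; channel width is constant at `C`
(`base_channels`, 64 at published fidelity) everywhere except immediately
after concatenations.

* **Encoder.** A `3 × 3` convolution lifts the input to `C` channels. Two
  blocks follow, and a *residual addition* joins the initial convolution
  output with the second block output. Four pooled levels follow: each
  applies non-overlapping `2 × 2` stride-2 max pooling (storing the argmax
  index of every window), then two blocks at the first pooled level and
  three blocks at the deeper levels, then a residual addition of the pool
  output with the last block output. A fifth pooling reaches `N/32`. The
  encoder holds 14 convolutions and 5 pooling layers.
* **Index transmission.** Every pooling layer's argmax indices are kept.
  The decoder upsamples by *max-unpooling*: values are scattered back to
  exactly the positions the paired pooling layer selected, zeros elsewhere.
  Pairing is innermost-first: the fifth (deepest) pool drives the first
  unpool, the first pool drives the last. This preserves the encoder's
  salient feature locations instead of inventing them by interpolation.
* **Decoder.** At each of the four mirrored levels: unpool, concatenate
  with the corresponding encoder addition output (giving `2C` channels,
  decoder features first), one block reducing back to `C`, three more
  blocks, and a residual addition of the reducing block's output with the
  third block's output. At full resolution: unpool, concatenate with the
  encoder's level-0 addition, one reducing block, one block whose
  activation is a sigmoid, and a final `1 × 1` convolution consolidating
  the channels into a single map — 19 decoder convolutions and 5 unpooling
  layers, 33 convolutions in total.

Two structural choices deserve a note because the architecture's printed
layer inventory pins them down. First, the encoder block counts are
2, 2, 3, 3, 3 from the full-resolution level inward: this is the only
assignment consistent with 14 encoder convolutions alongside the stated
two-block first levels. Second, the final decoder level has two blocks and
no residual addition: 4 levels × 4 convolutions + 2 blocks + the `1 × 1`
head is the only decomposition reaching exactly 19.

One deliberate deviation from a literal reading: the sigmoid sits in the
activation slot of the last block, *before* the final `1 × 1` convolution —
but a linear `1 × 1` layer cannot guarantee outputs in `[0, 1]`. Since the
network must emit a probability map (and the Dice loss assumes one), we
keep the sigmoid-activated block and also pass the `1 × 1` output through a
sigmoid. This adds no convolution and leaves the layer inventory untouched.

Everything the architecture leaves open is fixed conventionally and
recorded in the configuration: same-padded biased convolutions,
He-style weight initialization, batch-norm momentum 0.1 and epsilon 1e-5
with population (divide-by-n) variances, pooling ties broken to the first
window position in row-major order, unpooled non-max positions zero-filled,
concatenation order decoder-then-encoder, binarization threshold 0.5.
An optional largest-connected-component cleanup exists but is off by
default — the raw network output is the method.

### Why the kernels are local

No deep-learning framework is a dependency: the computational graph here
*is* the package's subject matter, and its needs are narrow (2-D
convolution, batch norm, pooling with indices, unpooling, backprop, Adam).
The kernels live in `src/kernels.cpp` (RcppArmadillo). Convolutions are
evaluated as blocked im2col + GEMM: patch matrices are built over small
column ranges so they stay cache-resident and the BLAS call is
compute-bound. Gradients of every kernel are verified against numerical
differentiation in the test suite, and the convolution itself against an
explicit-loop oracle.

## Preprocessing

The only preprocessing is standard-score (z-score) normalization with
*dataset-level* statistics: `(I − μ) / σ`, where `μ` and `σ` are the
population mean and standard deviation pooled over **every voxel of every
training volume**, background included, computed separately per modality
and frozen for validation, test and inference. Whether background air
should be excluded is genuinely open; pooling everything is the simplest
reproducible convention and is what the package does. No bias-field
correction, registration or resampling is applied.

## Augmentation

Training slices are expanded on the fly with one random affine per draw:
shear uniform in ±0.3 rad, rotation uniform in ±30°, isotropic zoom uniform
in ±20 %, composed in the fixed order shear → rotate → zoom about the image
centre, then a horizontal reflection with probability ½. Images are
interpolated bilinearly, masks by nearest neighbour (binariness is
asserted), out-of-frame regions are zero-filled, and identity parameters
are a strict no-op. The reflection is an exact column reversal, so it is an
involution. Warps go through `EBImage::affine()`. The protocol's
thousand-fold expansion "through all epochs" is realized as
`per_epoch_factor` fresh variants per original slice per epoch (10 per
epoch × 100 epochs by default) rather than materializing a thousand copies.
Validation and test data are never augmented. Whether the zoom should be
anchored on the brain region rather than the image centre is unstated in
the protocol; image-centred is implemented.

## Training

The loss is soft Dice over all pixels of a batch jointly:
`1 − (2·Σpg + ε) / (Σp + Σg + ε)` with `ε = 1e-6` — the differentiable
surrogate of the Dice metric (which is defined on masks, but
backpropagation needs probabilities). `ε` also makes the both-empty case a
zero loss. Optimization is Adam (β₁ 0.9, β₂ 0.999) with mini-batches of 8,
100 epochs, learning rate 5e-4 held through epoch 20 and then decayed to
1e-4; "gradually decreased" is read as linear decay to the final epoch,
with a step schedule available behind a config switch. Splits are always at
the *subject* level (never slices), 6:2:2 with largest-remainder rounding,
and five-fold cross-validation assigns every subject to exactly one
validation fold. The checkpoint with the best validation Dice is returned;
training curves (loss, hard Dice, pixel accuracy — "accuracy" is ambiguous
in training-curve figures, so both are recorded) are kept per epoch. One
master seed drives splits, initialization, shuffling and augmentation, so
runs are bitwise reproducible.

## Evaluation metrics

With `TP/FP/FN` voxel counts between prediction and ground truth:

* Dice `κ_D = 2·TP / (2·TP + FN + FP)`;
* sensitivity `κ_st = TP / (TP + FN)` (under-segmentation);
* sensibility `κ_sb = 1 − FP / (TP + FN)` (over-segmentation penalty) —
  deliberately **unclamped**, so gross over-segmentation can push it below
  zero;
* Hausdorff distance `δ_h`: the larger of the two directed
  farthest-nearest-neighbour distances between contour point sets, in mm;
* average Hausdorff `δ_ah`: the symmetric mean of the two directed average
  nearest-neighbour distances, `(mean_a min_b + mean_b min_a) / 2`. "The
  average instead of the maximum" admits several readings; this symmetric
  one is the common convention and preserves `δ_ah ≤ δ_h`.

Contours are per-slice 2-D boundaries (a foreground voxel with a background
or out-of-image 4-neighbour), unioned across slices into a 3-D point set at
voxel centres `index × spacing` (0-based), with distances taken as 3-D
Euclidean under the anisotropic spacing — distance metrics are reported in
physical mm on anisotropic volumes, and whether they should instead be
computed per slice is left open by the protocol; the 3-D reading is
implemented. Both masks empty gives Dice 1 by convention; empty ground
truth or empty contours raise errors rather than inventing a value. Method
comparisons use the classical paired two-tailed t-test
(`stats::t.test(paired = TRUE)`), with degenerate difference vectors
rejected explicitly.

## The phantom generator

The in-vivo datasets this pipeline targets (55 stroke-rat subjects per
modality, 15 coronal slices of 1 mm over a 2.56 cm field of view, 128²
DWI / 256² T2WI matrices) are not publicly deposited, so the package ships
a synthetic phantom that emulates their geometry and the failure modes that
make thresholding insufficient:

* an elliptical "brain" (mid-slice semi-axes ≈ 7.75 × 5.75 mm, jittered per
  subject, shrinking toward the end slices) of unit intensity;
* a thin dark skull-gap ring (0.4 mm, intensity 0.15) and a bright scalp
  ring (1 mm, intensity 0.75) outside it — the scalp is deliberately
  brain-like so that intensity alone cannot separate it;
* a hyperintense lesion (gain 1.3–1.8, radius 1.2–2.0 mm) inside one
  hemisphere on a contiguous band of middle slices, emulating DWI-bright
  ischemia (the same mechanism is reused for T2WI-like phantoms; no
  modality physics is modelled);
* a multiplicative bias field, the exponential of a random low-order 2-D
  polynomial with log-amplitude capped at 0.3, emulating RF inhomogeneity;
* Rician noise — the magnitude of signal plus complex Gaussian — with σ
  defaulting to 1/15 (brain SNR ≈ 15).

The ground-truth mask is the ellipse interior *by construction* (lesion
included, rings excluded), so a perfect segmentation scores Dice 1 and the
generator supports exact end-to-end checks. Lesion placement is validated
against the per-slice ellipse; infeasible parameter combinations are
errors, and the default ranges are chosen so every seed is feasible. What
the phantom does **not** capture: real rat anatomy, k-space/sequence
physics, partial-volume effects, motion, and inter-site variability —
passing phantom tests demonstrates that the pipeline's machinery works and
learns, not that it reaches in-vivo accuracy.

## Problem sizes used in the checks

The structural properties (layer inventory, channel/spatial arithmetic,
unpooling round trips) are width- and size-independent and are checked at
several `N` and widths including the published `N = 128`, width 64. The
learning check trains a width-16 network at `N = 64` (0.4 mm pixels) for 10
epochs, batch 8, one augmented variant per slice per epoch, on 40 phantom
subjects (600 slices), and evaluates 10 held-out subjects; with the fixed
seed this reaches mean Dice above 0.999 and mean average Hausdorff below
10⁻³ mm on held-out phantoms — far above the 0.90 / 1 mm acceptance floor,
as expected for a geometric phantom. The pipeline smoke run exercises
phantom → train → predict → evaluate at `N = 64`, width 8, 2 epochs, 6
subjects.

## Known limitations

* The kernels are CPU-only, double-precision and single-threaded apart
  from BLAS; they are sized for desk-scale experiments and inference, not
  for large-scale GPU training.
* Checkpoints are JSON (portable and diffable, but large for width-64
  networks).
* Phantom realism is geometric, not physical (see above).
* Multimodal fusion (joint DWI + T2WI input), 3-D convolutions and
  competitor architectures are out of scope.
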