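---
title: "Methods: the duralseg segmentation and classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the duralseg segmentation and classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Subdural (SDH) and epidural (EDH) hemorrhages are the two *dural* bleed
types seen on emergency head CT. They sit against the inner table of the
skull and are easily confused with each other: both are peripheral,
hyperdense (fresh blood attenuates more than brain parenchyma), and
variable in size. Their classical radiological signatures differ in shape —
SDH forms a thin *crescent* that follows the inner skull curvature, EDH a
*biconvex (lentiform) lens* bounded by dural attachments. `duralseg`
implements an end-to-end pipeline that segments the lesion pixel-wise and
classifies the slice as SDH or EDH, together with a synthetic phantom
generator so every stage can be trained and verified at desk scale on a
single CPU.

## The model

The network is a U-shaped encoder–decoder with three attention/refinement
mechanisms layered onto the standard U-Net skeleton:

* **Encoder**: four stages of double Conv(3×3, stride 1)–BatchNorm–ReLU
  with 2×2 max pooling between stages; channel widths double per stage
  (`base_filters` × 1, 2, 4, 8; 64/128/256/512 at the published scale) into
  a bottleneck of 16× `base_filters`.
* **CSR blocks** (Convolution + Squeeze-Excitation + Residual skip) process
  each encoder stage's output before it is handed to the decoder:
  a Conv-BN-ReLU block, channel recalibration by squeeze-and-excitation
  (global average pool → bottleneck FC `C → C/r` with ReLU → expansion
  `C/r → C` with sigmoid → per-channel gates in (0,1)), plus a direct
  additive skip from block input to output (1×1 projection when channel
  counts differ).
* **Bottleneck**: Conv-BN-ReLU followed by a full pre-activation residual
  unit (BN → ReLU → conv → BN → ReLU → conv, identity shortcut), so an
  identity path with intact gradient flow spans the deepest part of the
  network.
* **Decoder**: four stages; each upsamples by a learned 2×2 transposed
  convolution (halving channels), concatenates the CSR-processed skip
  features of the matching scale, applies a **spatial attention gate** —
  channel-wise max and mean maps stacked into a 2-channel descriptor, a
  single 7×7 convolution, a sigmoid, and elementwise multiplication
  (broadcast over channels) — and refines with a double Conv-BN-ReLU.
* **Heads**: a 1×1 convolution + sigmoid yields the per-pixel hemorrhage
  probability at full input resolution; a classification branch taps the
  bottleneck with a CBL unit (Conv-BN-LeakyReLU, slope 0.001), a second
  convolution, global average pooling, a fully connected layer, and a
  numerically stabilized softmax over {SDH, EDH}.

Training minimizes the multi-task objective

$$ M \;=\; M_{\text{focal}}(\hat{y}, y) \;+\; \delta\, M_{\text{dice}}(\hat{S}, S), $$

the canonical focal loss $-\alpha (1-p_t)^\gamma \log p_t$ on the class
probabilities plus $\delta$ times the soft dice loss
$1 - (2\sum \hat{S}S + \varepsilon)/(\sum \hat{S} + \sum S + \varepsilon)$
on the segmentation probabilities, with Adam, seeded shuffling, plateau
learning-rate decay and best-checkpoint selection on validation dice. All
forward/backward passes are implemented in the package (R with
RcppArmadillo convolution kernels) and are verified against numerical
differentiation in the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `target_size` | 256×256 px | network input size (/16-divisible) |
| `clahe_clip_limit` | 2.0 | CLAHE histogram clip factor (× mean bin count) |
| `clahe_tile_grid` | 8×8 | CLAHE tile grid |
| `gamma` | 0.8 | gamma-correction exponent (mild shadow brightening) |
| `k_neighbors` | 5 | SMOTE neighbor count |
| `base_filters` | 64 | encoder stage-1 channels (8 at desk scale) |
| `se_reduction` | 16 | squeeze-excitation bottleneck ratio |
| `leaky_slope` | 0.001 | CBL LeakyReLU slope |
| `attention_kernel` | 7 | spatial-attention convolution size |
| `learning_rate` | 1e-4 | Adam initial rate |
| `lr_decay_factor` | 0.5 | multiplicative decay on plateau |
| `lr_patience` | 10 epochs | plateau length before decay |
| `epochs` / `batch_size` | 60 / 16 | training length / batch |
| `balance_delta` | 1.0 | weight of the dice term in the objective |
| `focal_gamma`, `focal_alpha` | 2, 0.25 | focal-loss parameters |

## Design choices where the design was open

Several architectural details are not pinned down by the textual
description this package follows; the choices below are the package's own,
made once:

* **Stage-1 width and bottleneck**: only stages 2–4 (128/256/512) are
  stated; `E1 = 64` and a 1024-channel bottleneck preserve the stated
  doubling pattern.
* **Descriptor fusion in spatial attention**: the channel-wise max and mean
  maps are *concatenated* into a 2-channel descriptor (the standard
  CBAM construction), not multiplied elementwise.
* **Upsampling**: learned 2×2 transposed convolution, halving channels.
* **Attention placement**: the gate acts on the fused
  (upsampled ⊕ skip) features at every decoder level, before the decoder
  convolutions.
* **Classifier tap point**: the bottleneck — the deepest, most semantic
  features; ReLU is used inside encoder/decoder convolutions and LeakyReLU
  only in the CBL classifier branch.
* **Segmentation head**: a single-channel lesion-vs-background probability;
  the lesion *type* comes from the classification head. Per-class dice is
  reported by grouping test slices by their true class.
* **Precision formula**: the standard `TP / (TP + FP)` is used; a source
  formula with `TP + TN` in the numerator is inconsistent with its own
  accuracy definition and is treated as a misprint.
* **δ reading**: the balance coefficient multiplies the segmentation term;
  default 1.0 (no value is stated anywhere).
* **Batch size**: 16 by default (one source passage says 32; both are
  config options).
* **Plateau trigger**: the decay factor (0.5) is stated but not its
  trigger; validation-loss stagnation for `lr_patience = 10` epochs is
  used, and a 10% stratified validation carve-out is taken when no
  validation set is supplied.
* **SMOTE scope**: both classes are raised to a *common* per-class target
  (matching the published 414+414 = 828 training table), not classic
  minority-only oversampling; distances are Euclidean on flattened pixel
  vectors (cosine selectable); each synthetic mask is interpolated with the
  same `u` as its image and re-thresholded at 0.5, which preserves the
  spatial correspondence between image and mask.

## Numerical choices

* **Batch normalization**: ε = 1e-5, momentum 0.1 for running statistics;
  evaluation mode uses running statistics, so repeated evaluation-mode
  forwards are bit-identical.
* **Initialization**: He-normal for convolutions and dense layers; the
  spatial-attention kernel is scaled by 0.1 so initial attention maps sit
  near the neutral 0.5.
* **Dice smoothing**: ε = 1 in the loss (stability on small lesions), ε = 0
  in every reported metric; the *both-masks-empty* case scores 1 (perfect
  agreement on absence), resolving the 0/0 in the overlap formulas.
* **Softmax** subtracts the row maximum before exponentiation; focal loss
  clamps p_t away from 0.
* **ROC**: thresholds sweep the distinct scores; the trapezoidal AUC then
  equals the Mann–Whitney pairwise probability with ties counted ½.
  Zero-denominator classification ratios are reported as `NaN` with a
  warning, never silently as 0.
* **Nearest neighbors** break distance ties toward the lower sample index,
  making SMOTE fully deterministic under a seed.
* **Lesion sizing** in the phantom uses 30-step bisection of a monotone
  pixel-count function; geometry that cannot fit raises a
  degenerate-geometry error rather than silently shrinking.
* **CLAHE neutrality**: the clip limit → 0 direction (not → ∞) flattens
  tile histograms into the identity ramp; the unclipped single-tile setting
  is global histogram equalization. The tests pin both behaviors.

## What the phantom generator emulates — and what it does not

`generate_slice()` draws a bright elliptical skull ring (≈0.95 intensity),
a textured brain interior (≈0.40 with low-frequency texture), a hyperdense
lesion (≈0.70) hugging the inner table — an annular-sector crescent with
cosine-tapered ends for SDH, an intersection-of-two-discs lens for EDH —
plus additive Gaussian noise (σ = 0.03, truncated at 3σ so the tissue
intensity bands cannot cross), on a [0,1] scale that mimics the *ordering*
of CT attenuation without modeling Hounsfield units. Head position, axes,
lesion position, arc span and area are jittered per seed; lesion area
defaults to 5% of the brain interior. Class structure mirrors a published
dural-hemorrhage collection (56 SDH vs 173 EDH slices; default counts in
the pipeline configuration).

The phantoms are *separable by construction*: a trivial classifier on the
convex-hull-to-lesion area ratio already distinguishes the classes. A green
training test therefore establishes that the implementation can learn and
represent the shape distinction — it does **not** establish clinical
performance: real CT adds skull-base artifacts, bilateral and mixed bleeds,
calcifications, partial-volume effects, uneven lesion densities and
inter-scanner variation that the phantom deliberately omits, and published
headline numbers on real data (mean dice ≈ 0.97) are not reproducible at
desk scale without the clinical images and GPU-scale training.

## The train-only enhancement asymmetry

The pipeline this package follows enhances *training* images with CLAHE and
gamma correction while test images are only resized and normalized. That
asymmetry is reproduced faithfully in `run_pipeline()`. It is worth knowing
what it does at desk scale: the two preprocessing paths produce visibly
different intensity distributions, and a small classifier trained on the
enhanced distribution ranks un-enhanced test slices poorly even when it
separates its own training distribution perfectly. The package's
classification sanity test therefore preprocesses both sides with the same
resize+normalize path — it is a check of the model's ability to learn the
crescent-vs-lens shape distinction, not of robustness to an intentional
distribution shift. Users evaluating on real data should weigh whether the
asymmetric protocol is what they want.

## Known limitations

* CPU-only: the published 256×256 / 60-epoch configuration trains in hours,
  not minutes; desk-scale settings (64×64, `base_filters = 8`) are provided
  throughout the examples and tests.
* 2-D slices only; no DICOM/NIfTI reader in the core package.
* Two classes only (SDH/EDH); the other intracranial hemorrhage subtypes
  are out of scope.
* No flip/rotation augmentation — class balance is addressed exclusively by
  SMOTE, mirroring the pipeline this package implements.
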