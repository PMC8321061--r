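---
title: "Dilated ResFCN for polyp segmentation: model, design choices and desk-scale evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilated ResFCN for polyp segmentation: model, design choices and desk-scale evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Colonoscopy frames show polyps at widely varying sizes, under specular
highlights, vignetting, blur and colour shifts. `polypseg` implements a
fully convolutional segmentation network built from three parts:

1. **Feature extraction**: a residual bottleneck backbone partitioned into
   stages Res1–Res5. Res1 is the 7×7/stride-2 stem convolution plus a
   3×3/stride-2 max pooling; Res2–Res5 are bottleneck stages operating at
   strides 4, 8, 16 and 32. For the depth-50 partition the stages contain
   9, 12, 18 and 9 residual-branch convolutions and emit 256, 512, 1024
   and 2048 channels; at a 250×287 input their maps are 62×72, 31×36,
   16×18 and 8×9.
2. **Multi-resolution classification**: four parallel paths tap the
   Res2–Res5 outputs. Each path is a 3×3 *dilated* convolution, a dropout
   layer, and a 1×1 per-pixel classifier. The dilation rates are 16, 8, 4
   and 2 from the finest to the coarsest path, giving effective kernel
   spans of (k−1)·r+1 = 33, 17, 9 and 5 pixels per side, so each path
   covers a comparable extent of the *input* image while reading features
   at its own resolution.
3. **Fusion**: each path's 2-class score map is upsampled to the input
   size with fixed (non-learned) bilinear interpolation and the four maps
   are summed; a per-pixel softmax yields the polyp probability map.

The `use_dilation = FALSE` ablation variant replaces every path's dilation
rate with 1 while keeping shapes and parameter counts identical; it exists
to quantify what the enlarged receptive fields contribute.

### Receptive-field diagnostics

`valid_weight_histogram()` counts, for every output position of a
same-padded dilated convolution on a small feature map, how many kernel
taps fall inside the map. On an 8×9 map a 3×3 kernel at rate ≥ 9 has
exactly one valid tap everywhere — the kernel has degenerated to 1×1 —
while very small rates waste the map's extent. `receptive_field_report()`
tabulates spans, histograms and the fraction of positions retaining at
least 4 of 9 weights for all four paths; `coverage_fraction()` computes
the design statistic used to choose the coarsest rate: the share of
polyps whose extent, divided by the path's stride, fits within the span.

### Size arithmetic

Stage output sizes follow the convolution arithmetic of the framework the
architecture family originates from: convolutions use floor division with
explicit symmetric padding, pooling uses ceiling division with windows
clipped to the valid region. This is the only convention that yields
62×72 → 31×36 → 16×18 → 8×9 from a 250×287 input (note 250/4 = 62.5 is
*floored* at stride 4 but 16×18 arises from ceiling-style pooling
upstream), and 56/28/14/7 from 224×224.

## A self-contained network implementation

No deep-learning framework is available to R in this package's dependency
set, and the network itself is the package's subject, so the layers are
implemented here directly: im2col/GEMM convolutions (with stride and
dilation), ceil-mode max pooling, fixed bilinear up/down-sampling with an
exact adjoint, dropout, per-pixel softmax cross-entropy, hand-derived
backward passes for every layer, and Adam. The C++ kernels (Rcpp/
RcppArmadillo) handle the memory-bound loops; BLAS does the matrix
products. Gradient correctness is pinned by finite-difference tests at
every layer and through the whole network.

**Normalization.** Where this backbone family would use batch
normalization, `polypseg` uses per-sample channel (instance)
normalization with learned scale and shift. At the batch sizes a CPU
permits (1–4), batch statistics are noise; instance normalization is
deterministic, batch-size independent, and trains stably. This is a
deliberate substitution, stated here because it changes what "Res-k"
means in fine detail while leaving every shape, stride, channel and
layer-count property intact.

**Backbone profiles.** Depths 50, 101 and 152 follow the standard
bottleneck partitions (block counts 3/4/6/3, 3/4/23/3, 3/8/36/3). A
fourth profile, depth 14 (one bottleneck per stage, widths divided by 8),
exists for CPU-scale experiments: it preserves the four-stage stride
structure and the four-path dilated head exactly, so the full pipeline is
exercised end to end in minutes. All structural acceptance checks
(shapes, channels, layer counts, parameter-count ordering) run on the
faithful profiles.

**Initialization.** Backbone convolutions use He initialization; the
classification paths use Xavier, and the upsampling is fixed bilinear
rather than learned. Loading externally pretrained backbone weights is
possible through the checkpoint mechanism but nothing in the package
requires it.

## Training

Training uses Adam on per-pixel 2-class cross-entropy over the fused
score map, with the stepped schedule: initial learning rate 1e-4 decayed
by 0.1 every 10 epochs over 30 epochs (all configurable in
`training_spec()`; the schedule law `lr(e) = lr0 · f^⌊e/decay_every⌋` is
tested exactly). The loss is unweighted by default; inverse-frequency
class weighting is exposed (`class_weighting = "balanced"`) and is used
by the desk-scale configurations, where the polyp occupies 5–15% of the
frame and 1–2 epoch runs would otherwise sit in the all-background
regime. Input frames are standardized per channel with training-corpus
statistics.

Cross-validation is grouped by video: `make_fold_plan()` assigns whole
sequences to folds (greedy balancing of frame counts), so frames of one
polyp never appear on both sides of a fold. The training side is
augmented; the validation side is never augmented.

## Augmentation

All transforms act once on the geometry and are shared between image
(bilinear sampling, reflected border) and mask (nearest-neighbour, zero
border), so masks remain binary and paired:

* **Rescale + crop** — isotropic scaling by the smallest factor reaching
  the target in both dimensions, residual removed by a random crop
  (translation augmentation); centered crop at validation time.
* **Rotation** — uniform in [0°, 360°).
* **Scale** — uniform in [0.8, 1.2].
* **Thin-plate-spline deformation** — a 10×10 control grid, each point
  displaced uniformly within ±4 px per axis, interpolated by an exact TPS
  solve and evaluated at every pixel.
* **HSV jitter** — per-image mean hue/saturation/value deviations are
  collected from the training corpus and resampled as shifts (hue wraps,
  saturation/value clamp). Shifts therefore never leave the support
  observed in the corpus, and a corpus of identical images yields a
  degenerate (zero-shift) distribution. The source describes jitter
  "drawn from the distributions derived from the original training
  images" without a formula; resampling observed deviations is this
  package's concrete reading.

Composition order, when several transforms are enabled, is rescale+crop →
rotation → scale → TPS → jitter; the order is a package choice (the
transforms are listed but not ordered in the source description). Each
output sample draws all transform parameters independently of which
transforms are enabled, so disabling one never perturbs the draws of the
others — the property the augmentation ablation design relies on. The
per-subset augmented count is exposed directly
(`augmented_count_per_subset`, default twice the originals); the
source's printed per-fold corpus sizes arise from an unstated per-image
multiplicity policy that we do not try to reverse-engineer.

## Inference

`predict_probability()` runs the fully convolutional forward pass at the
frame's own size. Rotation test-time augmentation (`predict_tta()`)
rotates the frame in `angle_step` increments (default 15°, hence 24
views), segments each view, rotates each output back, and averages. Two
aggregation modes exist: `binary_mean` (threshold each view, then
average — the default, matching the source's description of averaging
binary outputs) and `probability_mean`. Non-square frames are padded to
the enclosing square with reflected image content; per-pixel aggregation
divides by the number of views whose valid (unpadded) region covers the
pixel. Right-angle rotations of square frames use exact index
permutations, which makes the single-view identity and the
equivariant-predictor checks exact rather than approximate.

Binarization (`postprocess()`) is threshold (default 0.5) → morphological
opening with a disc of radius 2 px (sized for 250×287; scale it with the
frame) → hole filling. The operation is idempotent, which the tests
assert directly.

## Evaluation

Per-frame records carry TP/FP/FN/TN, Dice, precision, recall, Jaccard
(with the identity J = D/(2−D) tested to 1e-12), and the boundary
Hausdorff distance (Euclidean, between 4-adjacency boundary pixel sets;
`Inf` sentinel when a mask is empty, excluded from means with the
exclusion count reported). When both masks are empty the overlap metrics
are 1, when exactly one is empty they are 0; the raw counts are always
reported so other conventions can be recomputed.

Circularity is 4πA/P² with the perimeter measured on the traced boundary
polygon subsampled at every 4th contour point. Raw 8-connected chain
length overestimates a circle's perimeter by ~5%, which would push ideal
discs to ≈0.90; subsampling removes the staircase bias so discs score
near 1 while an axis-aligned square still scores ≈π/4. Strata
(Small/Normal/Large, for size and circularity independently) are cut at
the 25th/75th percentiles (linear interpolation, type-7) of the
*training-side* distributions of each fold. "Size" is mask area in
pixels; area is recorded per frame so a linear-extent reading can be
recomputed.

## What the phantoms emulate — and what they do not

The generator produces corpora with the structure of the standard-
definition training set this line of work uses: 15 sequences × 20 frames
(300 frames) by default, one polyp per frame, rendered at 250×287.
Sequences model videos: one polyp identity (log-uniform radius in 18–60
px, area-preserving eccentricity up to 0.6, band-limited boundary
roughness, colour) shared by all frames, with per-frame pose and
illumination jitter. Frames include the confounders that motivate the
method — specular highlights, vignetting, low-frequency background
texture, sensor noise — and the corpus is bit-reproducible from (spec,
seed).

Phantoms are deliberately *not* photorealistic: no folds and wrinkles, no
instrument occlusion, no motion blur, a single polyp per frame, and far
higher foreground/background colour separability than real mucosa.
Passing the pipeline-recovery tests therefore demonstrates that the
machinery (grouped folds, augmentation, optimization, inference,
metrics) is correct and that the network can learn, not that the method
reaches any particular accuracy on clinical data.

## Desk-scale problem sizes and numerical choices

The package's own evaluation runs, chosen once as CPU-scale conditions:

* Pipeline recovery: 60 phantoms (6 sequences × 10 frames) at 250×287,
  2-fold grouped CV, 2 epochs, batch size 1, learning rate 1e-3,
  balanced class weights, depth-14 profile with 32-channel paths;
  single-phantom overfit: 200 iterations, same profile. These run in
  minutes on one CPU and reach mean validation Dice ≈ 0.7 and overfit
  Dice > 0.95.
* Structural checks (shapes, channels, layer counts, spans, valid-weight
  histograms) always use the faithful depth-50 partition at 250×287.
* Tolerances: Jaccard–Dice identity at 1e-12; Hausdorff equals an
  all-pairs oracle exactly; square circularity within 5% of π/4;
  TTA single-view and equivariance identities exact (right-angle index
  rotations); rotation-TTA non-inferiority within 2% of the plain median.
* Ties and degenerate inputs: max-pool ties resolve to the first tap in
  column-major order; empty masks yield the Inf Hausdorff sentinel and
  the 0/1 conventions above; grey pixels (undefined hue) pass through
  jitter unchanged except for value shifts.

## Known limitations

* Instance rather than batch normalization (see above); with externally
  pretrained weights the running-statistics semantics of batch
  normalization would not be reproduced.
* The TPS warp uses the forward displacement field as the backward
  sampling field; for ≤4 px displacements on a 10×10 grid the difference
  from a true inverse is far below a pixel.
* Offline augmentation only (a fixed augmented corpus per fold), matching
  the printed corpus description; per-epoch resampling is not
  implemented.
* CPU double-precision throughput bounds practical training to the
  depth-14 profile; the faithful depths build and run forward passes but
  are not trained in the test suite.
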