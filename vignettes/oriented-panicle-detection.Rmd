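---
title: "Oriented panicle detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oriented panicle detection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the box representation and overlap measures, the detector and its loss, the
synthetic-scene generator that stands in for field imagery, and the design
choices that were genuinely open.

## Why oriented boxes

Rice panicles photographed from a UAV are slender (aspect ratios of 5-12),
densely packed, and oriented arbitrarily in the image plane. An
axis-aligned box around a diagonal panicle is mostly background, and
neighboring panicles' boxes overlap heavily even when the plants do not.
An oriented box `(cx, cy, w, h, θ)` — center, side lengths, and rotation —
fits the plant tightly. Throughout the package boxes are canonical:
`w ≥ h` (so `θ` is the main-stem direction) and `θ ∈ [-π/2, π/2)`, using
the π-periodicity of rectangles. Coordinates are 0-based continuous image
coordinates, origin top-left, x right, y down, with pixel `(i, j)` covering
the unit square whose center is `(j + 0.5, i + 0.5)`.

## Overlap measures

Two different overlap notions serve two different purposes.

**Probabilistic IoU (the loss).** Each box is replaced by the Gaussian
with its center as mean and covariance
`Σ = R(θ) diag(w²/12, h²/12) R(θ)ᵀ` — the second moments of a uniform
density over the rectangle, so the determinant `(w²/12)(h²/12)` is
rotation-invariant. The Bhattacharyya coefficient
`BC = ∫√(p q) dx` has a closed form for Gaussians, and

    ProbIoU(a, b) = 1 − HD(a, b),   HD = √(1 − BC).

This measure is 1 exactly for identical boxes, symmetric, invariant under a
common rigid motion, smooth in all five parameters, and — crucially for
training — it keeps a usable gradient when boxes do not intersect at all,
where a polygon IoU is flat zero. Two conventions deserve a note: the
linear form `HD = 1 − BC` (without the radical) appears in some
presentations; it is not a metric and `prob_iou(..., hellinger_sqrt =
FALSE)` exposes it only for comparison. Likewise `∫ p·q dx` (without the
square root) is not the Bhattacharyya coefficient — it would not equal 1
for identical densities, destroying the identity `ProbIoU(a, a) = 1` — so
the package implements the standard `√(p q)` form, which the test suite
verifies against direct 2-D grid quadrature of the integral.

**Polygon IoU (the evaluator).** Matching detections to ground truth, and
non-maximum suppression, use the exact area-of-intersection over
area-of-union, computed by Sutherland–Hodgman clipping of one rectangle by
the other. A deliberately naive cross-check — classifying up to 10⁷ grid
points against both rectangles — agrees within 0.005 on random pairs. The
Gaussian surrogate is *not* used for evaluation: it is intentionally
forgiving (a square's Gaussian is isotropic, so ProbIoU of a square with
its own 45° rotation is 1), which is a virtue in a loss and a flaw in a
metric.

## Annotation formats and tiling

Field annotation tools and trainers disagree on formats, so the package
implements the conversion chain used in practice: rolabelImg XML
(`cx, cy, w, h, angle` in radians) → DOTA text (eight vertex coordinates,
class, difficulty) → normalized YOLO-OBB text (class index plus vertices
scaled to [0, 1]). Round-tripping 500 random boxes through the whole chain
moves no vertex by more than half a pixel.

UAV frames (5472 × 3648) are tiled into 608 × 608 patches — exactly 54 per
frame — because full frames would be downscaled into oblivion by the
detector's fixed input resolution. Boxes crossing tile borders are clipped
against the tile, re-fit by the minimum-area enclosing rectangle (rotating
calipers over the convex hull), and kept only if the clipped piece retains
at least `min_area_frac = 0.30` of the original box area. The 30% default
mirrors the manual annotation protocol for partially occluded panicles
(annotate if more than 30% visible); how the original pipeline handled
border-crossing boxes is not recorded anywhere, so this explicit mechanical
rule is the package's own, and it is reported per dropped box.

## The synthetic-scene generator

The real UAV dataset is not publicly archived, so the package ships a
seeded generator whose scenes stand in for it. Each scene renders 15-40
textured capsules (optionally bent at 15-35° to mimic curved panicles) over
low-frequency green-brown clutter with per-pixel speckle. Ground truth is
defined mechanically: the minimum-area rectangle of the rendered mask.
Rejection sampling enforces a maximum pairwise polygon IoU between objects.
Presets encode the study conditions: `heading` scenes are sparser (15-25
objects, overlap ≤ 0.05, yellow-green) and `filling` denser and more
occluded (25-40 objects, overlap ≤ 0.15, golden); the `10m` flight-height
preset scales object size by 3/10 relative to `3m`, whose panicles are
60-120 px long and 8-16 px wide at 608 px tile resolution. These sizes and
colors were chosen once as field-plausible values and are not tuned.

What the generator does *not* emulate: perspective, canopy 3-D structure,
specular highlights, motion blur, other organs (leaves crossing panicles
are only approximated by clutter), and radiometric variation between
flights. Passing tests on synthetic scenes therefore demonstrate that the
pipeline's machinery — geometry, assignment, loss, optimization,
evaluation — is correct and that the detector can learn slender oriented
objects from realistic layouts; they do not certify field accuracy.

## The detector

The backbone follows the EfficientNetV2-S stage table: a stride-2 stem,
three Fused-MBConv stages (a single 3 × 3 standard convolution replacing
the depthwise/expansion pair in shallow layers, plus a 1 × 1 projection
when the expansion ratio exceeds 1), and three MBConv stages
(1 × 1 expand → 3 × 3 depthwise → squeeze-and-excitation at ratio 0.25 of
the block input → 1 × 1 project) with stochastic depth available on
residual blocks. Feature maps are tapped after stages 3, 5 and 6, at
strides 8/16/32 (76 × 76, 38 × 38 and 19 × 19 on a 608 input). The
classification stage of the original table exists only for reference
construction; detection never instantiates it.

The neck is PAN-style: SPPF (three chained 5 × 5 max-pools) and a
position-sensitive attention block on the deepest tap, a top-down path with
nearest upsampling and concatenation, then a bottom-up path; C3k2 blocks
(split/aggregate pairs of small convolutions) fuse each junction. In the
three blocks feeding the detection branches, the bottleneck's second
convolution is replaced by a *dynamic convolution*: K = 4 parallel kernels
fused by input-dependent weights `π(x) = softmax(z/τ)`, where `z` comes
from a two-layer perceptron over the globally average-pooled feature
vector. The weights are a probability vector by construction, and by
linearity the fused-kernel convolution equals the π-weighted sum of the K
individual convolutions — both facts are tested, the latter against an
explicit convolve-then-aggregate oracle. The gate temperature starts at 30
and anneals linearly to 1 over the first 10 epochs, following the
dynamic-convolution literature's recipe for avoiding early gate collapse;
the hidden width is `max(C/4, 4)`. None of these three values is dictated
by the architecture itself; they are stated here as the package's
defaults.

Each detection branch is decoupled: a box stack, a class stack and an
angular branch producing one angle channel mapped by a sigmoid to
`[-π/2, π/2)`. Box geometry is regressed either as discretized side
distributions (`reg_max = 16` bins decoded by expectation; the default,
matching the reference head) or as direct offsets
(`box_mode = "direct"`: sigmoid center offsets within ±1.5 cells and
log-scale side lengths), selectable in `model_config()`.

**Calibration of the default scale.** The reference publication states the
assembled detector's budget — about 2.45 M parameters — but not the
width/depth multipliers that produce it. The package's default
`width_mult = 0.35`, `depth_mult = 0.625` (channels rounded to multiples
of 8, layer counts rounded up) was calibrated once so that
`model_complexity(build_oe_yolo(model_config()))` reports 2.45 M to two
decimals (2.4526 M, with 4.93 GFLOPs at a 608 input counting one
multiply-accumulate as two operations).

## Training

The package trains on CPU through a small reverse-mode autodiff tape with
C++ kernels (im2col/col2im convolution, pooling, fused batch
normalization and SiLU). Batch normalization uses per-image spatial
statistics during training and exponential running statistics (momentum
0.1) at inference; every tape gradient is verified against finite
differences in the test suite.

The loss is the composite used for rotated detection:
`w_box · mean(1 − ProbIoU)` over positive locations plus
`w_cls · BCE` over all locations (normalized by the positive count), with
default weights 7.5 and 0.5. The gradient of the ProbIoU term with respect
to the five decoded box parameters is computed by central finite
differences of the closed form (the function is smooth and cheap, so ten
vectorized evaluations per batch of positives are exact enough at step
sizes of 0.05 px / 1% side length / 0.002 rad) and then chained
analytically through the decoding map onto the raw head outputs.

**Assignment.** The stated rule — a candidate is positive when its IoU
with a ground truth reaches 0.7 — is implemented verbatim in
`assign_targets()` and exposed as the module's contract. The training loop
itself, however, is anchor-free: with grid-cell candidate boxes, slender
ground truths (aspect ratio ≫ 1) essentially never reach IoU 0.7, so the
literal rule alone would yield no positives at all. The trainer therefore
uses a center-prior assigner: grid cells whose center falls inside the
ground-truth rectangle *and* within 1.25 strides of its center (at most 6
cells, nearest first; conflicts to the nearer object) are positive. The
proximity restriction matters specifically for slender boxes: the head's
center offset reaches at most 1.5 cells, so a cell far along the main axis
could never regress the true center and would only learn to emit
duplicates. Objects are routed to the stride-8 level below 128 px long
side and stride-16 below 256 px, biased fine because the *thin* dimension
(8-16 px) is what limits localization.

**Schedule.** SGD with momentum 0.937, initial learning rate 0.01, cosine
annealing to `lr0/100` with exact endpoints, L2 weight decay 0.001 on
convolution and linear weights (not on normalization parameters or
biases), batch size 16 by gradient accumulation, 110 epochs and 608 px
inputs by default. One integer seed drives weight initialization, data
order, augmentation and cropping. `train_config(crop_size =)` optionally
trains on random square crops: object scale is preserved while
per-iteration cost drops with the crop area, which is how the CPU smoke
benchmark stays tractable.

**Validation.** mAP is computed from detections kept at a low score cut
(0.01): average precision integrates the whole precision-recall curve, and
truncating it at the deployment threshold (0.25) would understate AP.
Counting, by contrast, uses the deployment threshold, since a count is a
point decision, and applies NMS at IoU 0.35 — loose enough to keep
genuinely neighboring panicles.

## Evaluation and counting

Matching is greedy in descending score with one-to-one ground-truth
consumption; AP uses all-point interpolation (the precision envelope
summed over distinct recall steps); mAP50-95 averages thresholds 0.50 to
0.95 in steps of 0.05 and can never exceed mAP50 (the matching set shrinks
with the threshold — a property the tests assert). Degenerate images
follow the conventions P = 1 with no detections and R = 1 with no ground
truths. For the single panicle class the macro-average over classes
degenerates to the plain values but the implementation averages per class
so that multi-class extensions behave as documented. Counting metrics are
the standard regression quartet over per-image (predicted, manual) pairs:
R² about the mean manual count, MAE, RMSE (≥ MAE always) and MAPE, which
requires strictly positive manual counts.

## Numerical choices and degenerate inputs

- Canonicalization wraps θ by subtracting multiples of π and guards the
  upper boundary against floating-point spill so θ < π/2 strictly.
- `min_area_rect()` rejects collinear point sets; vertex fitting of
  near-rectangles recovers them to 1e−4 px, and arbitrary convex quads get
  their true minimum-area enclosing rectangle (verified against a dense
  angle-sweep oracle).
- `bhattacharyya_coefficient()` raises a degeneracy error on singular
  covariances rather than returning NaN.
- Decoded box sides are clamped below (1e−2 stride units) so the Gaussian
  surrogate stays positive-definite; the clamp's gradient is zero.
- BCE probabilities are clipped to [1e−12, 1−1e−12]; exact 0/1 predictions
  at correct labels contribute exactly zero loss.
- NMS breaks score ties by lower class id, then input order, making the
  survivor set deterministic.
- Training aborts with a diagnostic on a non-finite loss instead of
  continuing silently.

## Problem sizes

The shipped verification uses desk-scale problem sizes chosen to exercise
every code path: oracle comparisons on 50-500 random geometry instances;
quadrature grids of roughly 1-2 million points per Gaussian pair; and a
smoke training benchmark of 200 synthetic heading-stage 608 px scenes
(seed 0) with 30 validation scenes, a tiny-width detector
(`width_mult = 0.125`, `depth_mult = 0.07`, direct box regression), 30
epochs on 192 px random crops with batch size 4 — on short schedules the
doubled number of optimizer updates from the smaller batch converges
substantially better than larger batches. The benchmark asserts that
validation mAP50 reaches 0.5 (from an untrained baseline of essentially 0)
and that per-image counting MAPE stays under 20% — thresholds that are the
package's own definition of "the pipeline learns", not field-accuracy
claims.

## Known limitations

- Training is single-image (gradient accumulation, not true batching);
  batch normalization statistics are per-image, which is closer to
  instance normalization and degrades slightly for very small feature
  maps.
- The dynamic-convolution gate is shared per block, not per spatial
  location; spatially adaptive variants are out of scope.
- The synthetic generator's realism limits (above) mean reported
  accuracies do not transfer to field imagery without retraining.
- The CPU trainer is practical for tiny-width models and crops; the
  default 2.45 M-parameter configuration at 608 px is buildable and
  runnable but training it to convergence on CPU is not a supported
  workflow.
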