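---
title: "citrusRL: models, accounting and synthetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{citrusRL: models, accounting and synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`citrusRL` packages a lightweight citrus detector family together with the
count-to-yield regression stage that turns single-view fruit counts into
whole-tree estimates. This vignette documents the models, the accounting
conventions, the synthetic data the package evaluates itself on, and the
numerical choices a user should know about.

## The detector family

Four variants of a nano-scale one-stage detector are assembled by
`build_model()`:

* `yolov8n` — the stock baseline: CBS units (conv + batch norm + SiLU), C2f
  split-bottleneck blocks, an SPPF pooling block, a PAN-style neck, and a
  decoupled anchor-free head with distribution-focal box regression
  (`reg_max = 16` distance bins per box side).
* `rgcspelan_only` — every C2f replaced by an RGCSPELAN block.
* `lscd_only` — the stock head replaced by the LSCD head.
* `yolov8_rl` — both replacements; the model of interest.

**RGCSPELAN.** A 1×1 stem projects the input to a hidden width `c`; the
channels split into a pass-through half and a gradient branch that runs
through `n` RepConv units of width `m` and a 3×3 tail conv. The pass-through
half and every branch stage are concatenated and projected by a final 1×1
conv. Discarding the residual bottlenecks removes parameters; the RepConv
units compensate for the lost gradient paths during training and fuse to
single 3×3 convolutions for inference (`repconv_fuse()` folds each branch's
batch-norm statistics into its kernel, zero-pads the 1×1 kernel to the centre
of a 3×3 kernel, and sums kernels and biases). Fusion uses the running
variance and is intended for evaluation mode; the train-mode and fused
forward agree to well below 1e-4 (a property test checks 1000 random
instantiations).

**LSCD.** The three pyramid levels (strides 8/16/32) have different widths,
so a per-level 1×1 group-normalized conv first unifies them; two 3×3
group-normalized convs and the final 1×1 projections (4·`reg_max` box
channels, `nc` class channels) are then *shared* across levels, and a
learnable per-level scalar multiplies the regression output to re-express the
shared regressor in each level's scale. Group normalization is used
throughout the head because its statistics are batch-size independent:
`GN(x_i) = γ (x_i − μ_g)/sqrt(σ_g² + ε) + β` with per-sample, per-group
moments, `ε = 1e-5`, and 16 groups by default, reduced to the largest divisor
of the channel count not exceeding 16 when 16 does not divide it (the
calibrated head widths 65 and 55 are not multiples of 16).

## Parameter and FLOP accounting

`count_parameters()` counts conv kernels, conv biases and affine norm
parameters, plus the 16 fixed weights of the distance-expectation projection
in the head — the convention under which the published baseline total
(3,157,200 at 80 classes) is reproduced exactly. Running statistics and fused
deploy kernels are excluded. `count_flops()` counts convolutions only, one
multiply-accumulate as two FLOPs, with RepConv in its fused single-conv
deploy form.

The published block diagrams do not pin down the RGCSPELAN hidden widths or
the LSCD trunk widths, and the four published whole-model totals are not
mutually consistent with a single width configuration composed naively
(the parameter savings of the two modifications do not add up to the
combined model's saving). The package therefore fixes the widths by a
calibrated per-variant channel manifest
(`inst/extdata/channel_manifest.yaml`), solved by exact integer search so
that all four published totals are reproduced exactly **and** the deploy-mode
FLOP ratio of the combined model lands on the published reduction
(4.420/8.743 ≈ 0.506 at 640 px). Most blocks sit at the natural defaults
(hidden width = half the output width, branch width = half of that); the
calibration concentrates the combined model's extra width in the 40²- and
20²-resolution blocks, where parameters are FLOP-cheap. All accounting
comparisons use the 80-class head, the configuration under which the baseline
total matches the stock summary; citrus training uses `num_classes = 3`.

## Training objective and loop

`train()` is plain SGD with momentum, linear learning-rate decay, optional
weight decay on conv kernels, and a ramped exponential moving average of the
weights (the EMA, not the raw iterate, is validated and returned — with only
a few hundred optimization steps the averaged weights are substantially more
stable). Defaults follow the published field recipe: `lr0 = 0.001`,
momentum 0.937, weight decay 5e-4, batch 16, 640-pixel inputs, checkpoints
every 10 epochs, best checkpoint by validation mAP at IoU 0.5.

The objective is the standard anchor-free composite: binary cross-entropy on
class scores, complete-IoU loss on decoded boxes, and distribution-focal
cross-entropy on the two distance bins bracketing each target distance,
weighted 0.5 / 7.5 / 1.5. Targets come from task-aligned assignment
(top-10 candidate cells per object inside its box, alignment metric
`score^0.5 · IoU^6`, conflicts resolved by IoU, per-object normalized
alignment as the soft class target). Assignment targets are constants to the
gradient, as is standard; all backward passes through the network
(convolution, batch/group norm, SiLU, pooling, upsampling, the split/concat
blocks, the shared head) are analytic and were verified against central
finite differences with the assignment frozen. The complete-IoU gradient
treats the aspect-ratio trade-off coefficient as a constant, the convention
of the reference implementations.

Determinism: all stochasticity flows through R's RNG under the hyperparameter
seed, computation is single-threaded, so two runs with the same seed produce
identical histories.

## Synthetic orchard scenes

The generator (`generate_scene()`) emulates the statistics of close-range
orchard imagery rather than its appearance: a layered foliage background;
three object classes styled as white petal rosettes (flowers), green discs
hue-offset from the foliage (green fruit — deliberately the hardest class)
and orange discs with highlights (ripe fruit); center-biased cluster
placement with near-square boxes (median aspect ratio within [0.95, 1.05]);
foreground leaves that occlude up to a configurable fraction of each object;
and gamma/backlight lighting variation. Labels cover the visible extent after
leaf occlusion, with a minimum surviving area of 8 px²; objects are labelled
whole when overlapped only by other fruit, as a human annotator would.
Augmentations follow the published pipeline: gamma mapping, luminance-channel
histogram equalization (chroma preserved), mixup (labels concatenated) and
four-image mosaic with a junction point in the central half of the canvas.
`split_dataset()` uses a seeded shuffle with largest-remainder apportionment,
so 3250 items split 7:1:2 into exactly 2275/325/650.

What passing tests on these scenes show — and what they do not: the pipeline
(assignment, loss, gradients, decoding, NMS, metrics) demonstrably learns to
localize and classify clustered, partially occluded objects from scratch on a
CPU; the scenes do not reproduce real foliage texture, specular fruit
surfaces, or true lighting statistics, so accuracy figures on them say
nothing quantitative about field performance.

**Smoke configuration.** The self-check training run uses 200 scenes of
320×320 px (4 flowers, 5 green and 5 orange fruit each, occlusion fraction
0.1, object radius 4.5% of the canvas side — about 29 px, so an object spans
roughly a dozen stride-8 cells and the top-10 aligned-assignment budget
covers most of its anchors consistently), a thin-width (0.0625) combined
model, batch 8, 30 epochs at `lr0 = 0.01`. These are the smoke choices, made
for learnability at desk scale: with larger objects most in-box anchors fall
outside the positive budget and receive background targets on fruit pixels,
which a thin network cannot spatially disambiguate; with batch 16 the run is
only ~375 SGD steps and whether all three classes converge depends on the
initialization, while batch 8 doubles the step count at identical total
compute and converges reliably; and the default 0.001 learning rate barely
moves a randomly initialized model in so few steps (it belongs to the
300-epoch field recipe). The run is expected to more than halve its initial
loss and exceed 0.5 validation mAP at IoU 0.5 — a pipeline sanity bound, not
a field accuracy claim.

## Count-to-yield regression

`fit_polynomial()` regresses whole-tree true counts on single-view detected
counts by ordinary least squares (degree 1 or 2) and reports both the plain
determination coefficient `1 − SS_res/SS_tot` and the adjusted variant
`1 − (SS_res/(n−p−1))/(SS_tot/(n−1))`. On the packaged ten-tree fitting
tables, the green-fruit stage is linear (slope 1.43885, intercept 0.89779)
and its published determination coefficient matches the **plain** R²
(0.91992); the ripening stage is quadratic (0.01100·x² + 0.04029·x +
39.22014) and its published coefficient matches the **adjusted** R²
(0.95639). Both variants are therefore always reported. The quadratic's
leading coefficient is the refit value; the printed rendering of that
coefficient is typographically damaged in the source tables.

`predict_count()` evaluates the polynomial and rounds half away from zero,
flooring at zero — the rule consistent with every self-consistent published
row. `evaluate_predictions()` computes E1 = |actual − detect|,
E2 = |actual − predicted| and the per-tree error rate 100·E2/actual
**truncated** (not rounded) to one decimal, with the mean of the per-tree
rates truncated to two decimals; truncation, not rounding, is the arithmetic
that reproduces the published per-tree rates and both published means (6.96%
and 3.71%). One published green-stage rate cell is inconsistent with its own
row; the packaged table carries the printed rate column so the published mean
can be reproduced verbatim, and the recomputed rates are always available.

`generate_tree_views()` simulates the paired records for self-tests: visible
counts uniform over the observed 40–90 range and true counts from the linear
relation plus Gaussian noise, floored at the visible count. Noise is placed
on the response rather than the regressor deliberately — regressor noise
would attenuate the recovered slope (regression dilution) and make the
parameter-recovery check test the wrong thing.

## Numerical choices and limitations

* Convolutions run through im2col and BLAS in single precision inside the
  compiled kernels; parameters, norms and losses stay in double precision.
  The training-mode forward caches the im2col buffer for the backward pass.
* AP uses all-point interpolation (precision envelope over recall); matching
  is per class, greedy by score, ties broken lexicographically by box
  coordinates; NMS suppresses strictly above the IoU threshold, so a tie at
  exactly the threshold keeps both boxes. 0/0 precision or recall is 0.
* Decoding thresholds default to 0.25 confidence and 0.45 NMS IoU for
  counting; evaluation decodes at 0.001 for a faithful precision-recall
  curve.
* Checkpoints are R serializations of the full weight tree; the optional
  half-precision form (IEEE binary16) halves storage for size accounting and
  quantizes weights by at most ~1e-3 relative — the full-precision form
  round-trips bit-exactly.
* Known limitations: no letterboxing (square inputs only), no test-time
  augmentation, no identity-branch RepConv variants, no quantization, and
  CPU-scale training only — the published field accuracies (mAP ≈ 0.95 on
  3250 real images after 300 GPU epochs) are out of desk-scale reach by
  design and are not asserted anywhere in the package.
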