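---
title: "Lightweight shuffle-block posture detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight shuffle-block posture detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shuffledet)
```

## The problem

Continuous monitoring of group-housed pigs relies on recognising, frame by
frame, where each animal is and which of five postures it holds: standing
(STD), lying on the belly (LOB), lying on the side (LOS), sitting (SIT) and
mounting (MOT). The lying/not-lying balance over a day is a practical
welfare signal (resting pigs lie 70–80% of the day; deviations flag
lameness, disease or tail-biting onset), so the detector must run
continuously on modest hardware near the pen. That pushes the design toward
a very small convolutional detector: a few hundred thousand parameters and
about one GFLOP per frame, rather than the tens of millions of parameters
of general-purpose detectors.

`shuffledet` implements such a detector as a complete, tested R library:
the network and its building blocks, training, evaluation, model
profiling, annotation I/O, and a synthetic scene generator that stands in
for farm footage (which is not publicly available) so that every component
can be exercised end to end.

## Architecture

The detector is a one-stage anchor-based YOLO-style network with three
parts.

**Backbone.** A 3x3 stride-2 convolution to 24 channels followed by a 2x2
max pool (stride 4 total), then three stages of *compression blocks* at 48,
96 and 192 channels with 3, 7 and 3 basic units respectively. Each stage
opens with a symmetric downsampling unit and closes with an efficient
channel attention (ECA) module. The pyramid taps P3/P4/P5 sit at strides
8/16/32.

The basic compression unit splits its channels in half; the first half
passes through untouched while the second traverses 1x1 conv, 5x5
depthwise conv and 1x1 conv; the halves are concatenated and
channel-shuffled (two groups) so information crosses the split on the next
block. The downsampling unit drops the split and runs *two identical*
1x1 -> 5x5 depthwise (stride 2) -> 1x1 branches over all input channels —
the symmetric structure that doubles width while halving resolution. The
5x5 depthwise kernel (rather than the usual 3x3) is the blocks' deliberate
trade: a modest parameter increase for a larger receptive field at very low
cost, since depthwise parameters scale only linearly in channel count.

The depthwise kernel size is configurable (`dw_kernel`), but 5 is the
design point used everywhere, in both unit types.

**ECA.** Channel attention without dimensionality reduction: the map is
globally average pooled to a length-`C` vector, convolved with a 1-D kernel
of adaptive odd size `k = floor(|log2(C)/gamma + b/gamma|)` (gamma = 2,
b = 1; bumped to odd; clamped to at least 3 so the interaction never
degenerates to a per-channel gate), and a sigmoid yields per-channel
weights in (0, 1). At the default widths the kernels are k = 3, 3, 5 for
C = 48, 96, 192.

**Neck and heads.** A path-aggregation network fuses the pyramid: lateral
1x1 convolutions bring P3/P4/P5 to a unified width of 48, a top-down pass
upsamples (nearest-neighbour 2x) and fuses, and a bottom-up pass
downsamples (3x3 stride-2 convolutions) and fuses again, shortening the
path from localisation-rich shallow features to the heads. Each head is a
single 1x1 convolution to `K x (5 + C) = 3 x 10 = 30` channels per grid
cell.

### Calibrating the parameter/FLOP budget

The published figures for this architecture are 0.358 M parameters and
1.2 GFLOPs at 640x640. The backbone above is fully determined (0.172 M
parameters), but a neck built purely from depthwise compression blocks at
width 48 cannot reach that budget — it saturates near 0.25 M parameters
and 0.46 GFLOPs. The neck therefore uses dense 3x3 fusion convolutions
(the standard choice in the YOLOv5 family this detector derives from),
with the fusion depth concentrated at the stride-8 level where small and
partially occluded animals live: the N3 fusion stacks five 3x3
convolutions; the other fusions are plain 1x1 reductions. With that
layout the default model lands at 357,557 parameters (0.3576 M, 0.1%
under the published count) and 1.103 GFLOPs.

The remaining 8% gap on GFLOPs is structural, not a tuning failure: every
operation available at stride 8 contributes exactly `80^2 = 6400` MACs per
parameter at 640 input, so adding the ~0.7 GFLOPs the budget asks for
within the remaining ~0.10 M parameter allowance is only possible at
stride 8, and `0.10 M x 6400 = 0.67 G` is the ceiling. The profiler
(`profile_model()`) reports both totals analytically and is cross-checked
in the tests against a brute-force enumeration of every allocated weight.

## Decoding, score and suppression

Each head cell emits, per anchor, `(t_x, t_y, t_w, t_h, t_o,
t_1..t_5)`. The box decode is the sigmoid parameterisation of the base
detector family:

* centre: `(2 sigma(t_xy) - 0.5 + cell) * stride` — spans 1.5 cells around
  the cell so neighbouring cells can also claim a box;
* size: `anchor * (2 sigma(t_wh))^2` — bounded in (0, 4x anchor), which is
  why anchor assignment uses a ratio gate of 4.

Objectness and class logits pass through sigmoids, and a detection's score
is the product of objectness confidence and its best class probability —
the train-time IoU factor in the confidence definition has target 1, so at
inference the product reduces to `Pr(class) x Pr(object)`. Greedy
per-class NMS (IoU threshold 0.45, ties broken by lower index for
determinism) removes redundant boxes. Anchors default to seeded k-means
(k = 9) over the training boxes, split 3/3/3 by area across the scales; the
shipped defaults were fitted once to the synthetic generator's box
distribution at 640 px.

## Training

Targets: each ground-truth box is assigned, per scale, to anchors passing
the ratio gate, at the centre cell plus its nearest horizontal and
vertical neighbours. Objectness targets are 1 at assigned slots and 0
elsewhere; a slot claimed twice keeps its first box, so no slot carries
two classes.

The loss is `5.0 * mean(1 - CIoU)` over assigned slots `+ 1.0 *`
balanced BCE over all objectness logits (scale weights 4/1/0.4)
`+ 5.0 *` BCE over assigned class logits. Two engine-specific choices
deserve a note:

* **Gain calibration.** Because box and class terms are normalised by the
  assigned-slot count, their per-logit gradients are one to two orders of
  magnitude smaller than the objectness term's. The default gains
  (box = 5, cls = 5 instead of the 0.05/0.5 common in large-batch GPU
  training) rebalance the terms for this package's one-image-per-step,
  few-hundred-step regime; without them the box and class heads saturate
  under feature drift before they can learn.
* **Box gradients** flow through the decode + CIoU chain by central finite
  differences on the four raw values (step 1e-3). CIoU is piecewise smooth
  and the assigned-slot count is small, so this is exact to well below the
  optimisation noise floor and keeps the CIoU code single-sourced.
* **Normalisation** layers use per-sample spatial statistics in training
  *and* inference. The engine trains one image at a time, so there is no
  batch axis to average over; using the same statistics in both modes
  removes the train/test mismatch that running averages would introduce
  (and which measurably depressed held-out mAP in development). The cost
  is that a map's normalisation depends on its own image — acceptable for
  detection, and standard for instance-style normalisation.

Head biases initialise to a low-objectness prior (`sigmoid(-4.6) ~ 0.01`)
so the background-dominated objectness loss starts near its optimum.
Optimisation is SGD with momentum 0.937, weight decay 5e-4 on convolution
weights, linear warmup for 3 epochs and cosine decay to `lrf * lr0`.
Augmentation: horizontal flips (p = 0.5), random quarter-turn rotations
(p = 0.75 on square canvases — postures are rotation-invariant in
top-view imagery, so this quadruples orientation coverage at zero cost),
mild log-normal brightness jitter, and an optional 4-scene mosaic (off by
default — synthetic pen scenes are already multi-instance, which is what
mosaic is meant to supply).

### Hyperparameter evolution

`evolve_hyperparameters()` implements elitist (1+1) evolution: each
generation mutates the best-so-far parent field-wise with log-normal
multiplicative noise (per-field probability 0.9, sigma 0.2, clamped to
sane bounds), scores the child, and keeps the better of the two; the
best-ever fitness trace is non-decreasing by construction. Fitness is the
weighted metric combination `0.1 * mAP@0.5 + 0.9 * mAP@0.5:0.95`, with
precision and recall deliberately absent. The search mechanism is
exercised against an analytic mock objective in the tests and against
short training runs via `make_train_fitness()`; reproducing a
45,000-iteration search is a compute exercise, not a correctness question,
and is out of scope. Whether such a search should score candidates on a
validation or training split is not fixed by the procedure; this package
uses a validation split.

## Evaluation

Matching is greedy within class and image: predictions in descending score
order claim the highest-IoU unmatched ground truth at IoU >= 0.5.
Precision `TP/(TP+FP)` and recall `TP/(TP+FN)` accumulate over score cuts;
AP is the area under the precision-envelope–recall curve on the standard
101-point recall grid (the annotations are COCO-dialect, so the COCO
interpolation is the natural choice; the tests bound the grid's
discretisation error against an exact stepwise integrator at 0.01). mAP
averages AP over the classes, and mAP@0.5:0.95 averages over the IoU
ladder 0.50:0.05:0.95.

Detector ROC curves need true negatives, which pure detection does not
define; the package makes the convention explicit: the negative pool is
the set of decoded candidates with IoU < 0.1 against every ground truth,
and TPR/FPR are swept over the score axis per class. AUC is trapezoidal.

The profiler counts conv parameters as `k^2 Cin Cout / groups` (+ bias,
+ 2 per channel for normalisation scale/offset) and conv MACs as weight
count x output area, excluding normalisation and activation. GFLOPs are
reported under the 1 MAC = 1 FLOP convention used by the common framework
profilers; a 2x field is also provided because both conventions circulate.

Posture statistics follow the lying dichotomy: lying = {LOB, LOS},
not-lying = {STD, SIT, MOT}. `posture_proportions()` emits per-frame (or
windowed) fractions, with frames containing no detections reported as
missing rather than zero, and serialises to a plain-text table.

## The synthetic scene generator

Real barn footage is not deposited, so the generator emulates its
structure: a textured floor under variable illumination (optionally
grayscale, infrared-like), 5–50 elliptical animals per pen at the farm
geometry (2304x1296; the default canvas is 640x640), overlap and rail
occlusion, and configurable class imbalance. Each posture's silhouette
recipe keys on the anatomical cue that defines the class: STD a narrow
3.2:1 body with four detached leg dots; LOB a plain wide ellipse (legs
folded under); LOS an ellipse with four leg strokes on one flank (legs
visible); SIT a wedge tapering from hindquarters to front; MOT a body
crossed by a second, roughly perpendicular animal. A hand-coded geometric
classifier (component count, width ratio, lateral skewness, taper
correlation, elongation) separates the five recipes at >= 95% on clean
silhouettes — the generator's guarantee that the detection task it poses
is learnable.

What the generator does *not* emulate: pig texture and anatomy beyond
silhouettes, perspective and lens distortion, motion blur, and temporal
continuity between frames. Passing the end-to-end tests therefore
demonstrates that the architecture, loss, assignment and evaluation
machinery are self-consistent and can learn a multi-class silhouette
detection task — not that the shipped defaults would reach any particular
accuracy on real farm video.

## Desk-scale experiment sizes

The package's experiments are sized for a single CPU:

* *Overfit check*: 8 scenes at 96x96 (2–5 animals of 28–48 px), 150
  epochs without augmentation; training mAP@0.5 should approach 1, which
  certifies the assignment/loss/decode loop end to end.
* *Generalisation check*: 200 training + 50 held-out scenes at 96x96, 50
  epochs (batch 2, lr 0.02 with cosine decay, flip + quarter-turn
  augmentation, best-fitness checkpoint); held-out mAP@0.5 is the
  learnability property under test.
* *Posture time series*: a simulated 24-hour schedule with a known
  lying/not-lying profile, aggregated hourly.

The 96 px canvas keeps one forward+backward pass under 0.1 s while
remaining divisible by 32; silhouettes are drawn relatively larger than at
640 px so that class cues survive the coarser raster. In the
generalisation experiment the engine localises essentially every animal
(~95% of ground truth covered at IoU 0.5) well before the epoch budget
runs out; the 5-way posture classification converges more slowly and its
loss is still falling when training stops, so held-out mAP@0.5 is
optimisation-bound rather than architecture- or data-bound at this
problem size.

## Numerical choices and degenerate inputs

* Normalisation epsilon 1e-5; BCE computed in the numerically stable
  max/log1p form; sigmoid never clamped.
* Zero-area boxes have IoU 0 by convention; empty detection sets pass
  through NMS and evaluation unchanged; classes without ground truth are
  skipped with a warning rather than polluting mAP.
* Downsampling on odd spatial dims uses ceiling division (pad k %/% 2);
  letterboxing keeps boxes within half a pixel over a round trip.
* All randomness (scene generation, initialisation, sample order,
  augmentation, k-means, evolution) flows from explicit integer seeds;
  per-image sub-seeds are derived by a fixed affine counter so any scene
  can be regenerated independently. R's default Mersenne-Twister is the
  pinned generator.

## Known limitations

* The engine is single-image SGD on CPU; it is meant for desk-scale
  experiments and method study, not for training on real farm-scale
  datasets.
* mAP on synthetic scenes is not comparable to published farm-data
  accuracy; no claim is made about real-data performance.
* ECA placement after neck fusions is available behind a flag
  (`neck$eca_after_fusion`) but off by default: the reference design
  attaches ECA to backbone stage ends only.
* Temporal modelling (tracking, posture transitions) is out of scope; the
  time-series module aggregates independent per-frame detections.
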