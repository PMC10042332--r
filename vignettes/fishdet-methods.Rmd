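---
title: "Detecting and counting tank fish: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting tank fish: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In recirculating-aquaculture tanks, feeding is dosed per head, so the
operator needs a running count of the fish visible in an overhead camera
frame. Counting by detection is hard in this setting for one dominant
reason: fish school, so the image is full of partially overlapping,
near-parallel or crossing bodies, and a conventional detector first merges
their boxes into one and then deletes the duplicates — which deletes real
fish.

`fishdet` implements a single-stage anchor-based detector specialized for
this task: a CSP (cross-stage-partial) backbone with a pixel-slicing stem
and SPPF pyramid pooling, an FPN+PAN neck, and three prediction heads at
strides 8/16/32 — augmented with *coordinate attention* in the backbone and
neck, trained with a composite CIoU / binary-cross-entropy objective, with
prior boxes re-clustered from the data, and post-processed with *linear
Soft-NMS* so that heavily overlapped fish are kept rather than suppressed.
Everything, including reverse-mode gradients and the Adam optimizer, is
implemented in R; there is no external deep-learning runtime.

## The model

`build_model()` assembles the compound-scaled architecture from a
`model_config()`. With depth multiple 0.33, width multiple 0.50 and one
class, the unmodified network has exactly **7,012,822** trainable
parameters. Two representational choices matter here:

* **Bias-carrying convolutions, no separate normalization layers.** Every
  convolution is stored in its inference (batch-norm-folded) form:
  `k x k x C_in x C_out` weights plus one bias per output channel. This is
  the parameterization whose counts detection toolchains print in their
  fused summaries, and it is the simplest form to train from scratch at
  desk scale. The cost is that training has no normalization safety net —
  see *Numerical choices* below.
* **Coordinate attention (CA).** A CA block pools its feature map twice —
  along width (giving a per-row profile) and along height (a per-column
  profile) — passes both through a shared bottleneck transform
  (`C -> max(8, C/r)` channels, SiLU), and emits two sigmoid gate fields,
  one per direction, that rescale the input:
  `out[h, w, c] = x[h, w, c] * g_h[h, c] * g_w[w, c]`. Unlike plain channel
  attention this keeps positional information along each axis, which is
  what distinguishes two parallel fish bodies that identical channel
  statistics would merge. The reduction ratio `r` defaults to 32.

CA enters the network at two sites, both selectable in
`model_config(ca_sites = ...)`:

* **C3CA backbone blocks.** The standard C3 block splits its input through
  two 1x1 convolutions, runs one branch through bottlenecks, and fuses.
  In C3CA the bottleneck branch passes through CA before fusion, and the
  secondary branch's 1x1 conv unit is removed entirely: the first
  `C_out/2` input channels join the fusion concat untouched (a plain
  channel split). Removing that conv saves more parameters than the small
  CA weights add, so C3CA is strictly lighter than C3 at matched widths
  (e.g. 17,384 vs 18,624 at 64 channels), and the improved full-size model
  is lighter than the baseline (6,893,054 vs 7,012,822).
* **Neck CA blocks**, one after each of the four neck fusion C3 blocks.

`tiny_model_config()` is a width-0.125, 160-px preset of the same graph
used for CPU experiments and the test suite; it is not a reduced
architecture, just a narrow one.

## Losses and target assignment

The training objective is the sum of three parts,
`Loss = L_bbox + L_cfd + L_cls`, each carrying a configurable gain
(`loss_config()`):

* **Box regression** is `1 - CIoU` averaged over positive matches, where
  `CIoU = IoU - rho^2/c^2 - alpha * v` penalizes center distance (`rho`,
  normalized by the enclosing-box diagonal `c`) and aspect-ratio mismatch
  (`v = (4/pi^2)(atan(w_gt/h_gt) - atan(w/h))^2`,
  `alpha = v/((1 - IoU) + v)`). `alpha` is treated as a constant during
  differentiation, the usual practice.
* **Confidence** is binary cross-entropy on the objectness logits: the sum
  over object positions plus `lambda_noobj` (default 0.5) times the sum
  over no-object positions, *jointly* normalized by the total number of
  positions. An earlier variant normalized the two terms separately; that
  gives each background position roughly 1/50 of a positive's weight at
  this grid size, background near fish is then never pushed down, and
  held-out AP stalls around 0.65. The joint normalization is also the more
  literal reading of a summed objective.
* **Classification** is per-class BCE at object positions only.

Target assignment is the size-ratio rule: a ground-truth box is positive
for an anchor when `max(w/aw, aw/w, h/ah, ah/h) < 4`, in its containing
grid cell plus the two nearest neighbour cells. Decoding uses the bounded
parameterization `center = (2*sigmoid(t) - 0.5 + cell) * stride`,
`size = anchor * (2*sigmoid(t))^2`.

Two further choices were made after controlled comparisons at the package's
desk-scale budget (64 scenes, 20 epochs), and are defaults rather than
constants:

* **IoU-valued objectness targets** (`iou_obj_target = TRUE`): the target
  at a positive position is the detached IoU of the currently decoded box
  with its ground truth, not the constant 1. Constant targets saturate
  every positive's score at 1.0, so ranking carries no localization
  information and average precision suffers (~0.65 vs ~0.9 under identical
  budgets).
* **Per-scale confidence balance** `(4, 1, 0.4)`: the stride-8 head sees
  16x more positions than the stride-32 head and the coarse head produces
  the least precise boxes; damping the coarse head reduces confident
  mislocalized duplicates.

## Prior boxes

`kmeans_anchors()` clusters ground-truth `(w, h)` pairs under the distance
`1 - IoU` of origin-aligned rectangles — the metric that matches what a
prior box is for — with k-means++ seeding and 10 restarts. The Lloyd update
uses cluster means; because mean updates are not guaranteed monotone under
the IoU objective, the iteration stops (keeping the previous state) the
moment the objective fails to decrease, so the recorded trace is
non-increasing by construction. A Euclidean mode
(`distance = "euclidean"`, delegating to `stats::kmeans`) exists for
comparison. The nine centers are sorted by area and split 3/3/3 across the
heads (ties broken by width, then height). Pairs are interpreted as
(width, height) throughout.

## Suppression

`nms()` is the classical greedy rule: emit the best box, zero every
remaining box overlapping it above `N_j`. `soft_nms()` replaces deletion
with linear decay, `s_k <- s_k * (1 - IoU(M, b_k))` when the overlap
exceeds `N_j`, and discards only below `final_score_min` (default 0.001).
For two true fish whose boxes overlap at 0.6, hard NMS deletes the weaker
one outright; linear decay leaves it at 40% of its score, where it still
counts. Some formulations circulate with both inequalities transposed; the
package implements the standard orientation and keeps the transposed
variant behind `transposed = TRUE` for inspection. Suppression is
per-class, and ties are broken by score, then area, then coordinates, so
output is independent of input order.

## Evaluation

`match_detections()` applies the community greedy protocol: detections in
descending score order each claim the unclaimed ground truth of highest
IoU at or above 0.5. `pr_curve_and_ap()` computes the cumulative PR curve
and the area under its precision envelope (all-point interpolation; an
11-point mode exists behind a flag). The summary precision/recall/F1 are
reported at the ranking prefix that maximizes F1, since a comparison table
printed without an operating point is best matched by the optimum.
`f1_score()` is the harmonic mean and works on fractions or percentages
alike.

## The synthetic scene generator

`generate_scene()` emulates the geometry of overhead tank captures: a
circular tank disc on a darker background, fish as ellipse bodies with
flared triangular tails, uniformly random heading, length 55-100 px at the
640-px scale (28-45 px in the 160-px tiny preset, i.e. the same physical
proportions), aspect ratio 2.8-4.2. Occlusion modes place side-by-side
(`parallel`) or crossing (`cross`) pairs by rejection sampling until the
pair's box IoU reaches `min_pair_iou` (attempt budget 1000), or crowd all
fish into a small region (`dense`). Brightness and Gaussian noise are
applied last; the default base scene has neither, because photometric
variation is the job of the augmentation stage. Every annotation is the
tight bounding box of the rendered silhouette, computed before noise.

What the generator does *not* emulate: water refraction and caustics,
partial submersion and depth blur, motion blur, reflections at the tank
wall, and the texture statistics of real fish. Passing tests on these
scenes therefore demonstrates that the architecture, losses, optimizer,
suppression and metrics interoperate and can learn a nontrivial detection
task end-to-end on a CPU — not that the trained weights transfer to real
imagery, which requires training on real annotated frames at full
resolution.

## Augmentation

`mosaic8()` composites eight labeled images onto one canvas in a 4x2 cell
layout, each cell boundary jittered up to 20% of the cell size, each image
scaled to cover its cell (plus up to 50% extra, `scale_jitter`) and
randomly cropped. Boxes ride the same affine placement, are clipped to
their cell, and dropped below 8 px^2 or 20% of their original area —
slivers make destructive regression targets. Brightness and noise jitter
are applied to the composite. The recorded per-cell transforms are
attached to the output so the label transformation is independently
checkable.

## Numerical choices

* **Gradient clipping.** Without normalization layers, Adam at lr 0.005
  produced activation explosions and NaN within a handful of steps; all
  training clips the global gradient L2 norm at 5.
* **Decoded-size floor.** Inside the loss, decoded widths/heights are
  floored at 0.01 px so the aspect-ratio term stays finite when a sigmoid
  underflows early in training.
* **Stable BCE.** All training-path cross-entropies are computed on logits
  with the softplus identity; probability-space helpers clamp only inside
  the logarithms so exact predictions give exactly zero loss.
* **Initialization.** He-scaled weights for SiLU convolutions; objectness
  biases start at `logit(0.01)` so the untrained detector believes almost
  everything is background.
* **Determinism.** Every stochastic stage (scenes, initialization,
  shuffling, augmentation, clustering) is seeded; per-image seeds derive
  from a master seed through a fixed linear-congruential map kept below
  2^31.

## Training profiles and problem sizes

The `tiny` profile — the default and the tested path — uses the 160-px
model on 64 synthetic scenes, batch 4, 20 epochs, Adam at lr 0.005 with
single-cycle cosine annealing to lr/100, checkpointing the epoch with the
lowest validation loss. Batch 4 rather than a larger batch is deliberate:
with the sample budget fixed, 320 optimizer updates instead of 160 is the
difference between held-out AP ~0.75 and ~0.9. The `reference` profile
is the full-scale recipe (Adam, lr 0.01, batch 32, 200 epochs) for users
scaling up to real data; lr 0.01 with Adam is aggressive and kept only
there. The test suite's training runs complete in a few minutes on one
CPU; evaluation uses 8 held-out scenes from the same generator.

## Known limitations

* Pure-R convolution is ~100x slower than an optimized GPU runtime; the
  full-size 640-px model is practical for parameter accounting and single
  forward passes, not for training.
* The one-to-one greedy matcher and all-point AP are the modern VOC/COCO
  convention; numbers computed under 11-point interpolation differ
  slightly.
* `count_fish()` is thresholded counting of suppressed detections; it
  inherits whatever calibration the score threshold has on the target
  imagery.
* With a single class, per-class suppression and classification are
  degenerate (the class branch trains to 1); the machinery generalizes to
  more classes but is untested beyond `num_classes = 1` at scale.
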