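# fishdet

Detection and counting of fish in top-view images of circular
recirculating-aquaculture tanks. Feeding in tank culture is dosed per
head, so the operator needs an accurate count of the fish visible to an
overhead camera — and the hard part is that fish school: overlapping,
near-parallel and crossing bodies make a conventional detector merge
neighbours into one box and then delete the duplicates, which deletes real
fish.

`fishdet` implements a single-stage anchor-based detector specialized for
this setting, entirely in R (including reverse-mode gradients and the Adam
optimizer — no external deep-learning runtime):

* **Architecture** — CSP backbone with a pixel-slicing Focus stem, SPPF
  pyramid pooling, FPN+PAN neck, three heads at strides 8/16/32;
  **coordinate attention** inserted into the backbone C3 blocks (the C3CA
  block, which also removes the secondary-branch conv and is strictly
  lighter) and after each neck fusion block. The unmodified single-class
  baseline has exactly 7,012,822 trainable parameters; the
  attention-augmented variant has fewer (6,893,054).
* **Training objective** — composite loss
  `L = L_bbox + L_cfd + L_cls` with CIoU box regression

  `CIoU = IoU − ρ²(b, b_gt)/c² − αv`,  `v = (4/π²)(atan(w_gt/h_gt) − atan(w/h))²`,  `α = v/((1 − IoU) + v)`,

  objectness BCE with a no-object penalty weight λ_noobj, and per-class
  BCE at object positions.
* **Prior boxes** — K-means over ground-truth (w, h) pairs under the
  `1 − IoU` distance of origin-aligned rectangles, nine centers split
  3/3/3 across the prediction scales by area.
* **Mosaic-8 augmentation** — eight images scaled, cropped and composited
  per canvas with label-preserving affine placement, plus brightness and
  Gaussian-noise jitter.
* **Soft-NMS re-screening** — linear score decay
  `s_k ← s_k (1 − IoU(M, b_k))` for boxes overlapping the current best
  above N_j, instead of deletion, so overlapped fish survive to be
  counted.
* **Evaluation** — greedy matching at IoU 0.5, precision/recall, AP as the
  area under the precision envelope, F1 = 2PR/(P+R).
* **Synthetic tank scenes** — a built-in generator renders overhead
  circular-tank scenes of ellipse-bodied fish with controllable density,
  occlusion (parallel / crossing / dense), brightness and noise, with
  tight-box annotations, so the whole pipeline is reproducible on a laptop
  CPU with no external data. Pascal VOC XML and YOLO-text annotation I/O
  round-trips through the standard `images/` + `labels/` layout.

## Worked example

Train the tiny CPU preset end-to-end on synthetic scenes (about four
minutes on one core) and count fish on held-out images:

```r
library(fishdet)

cfg <- run_config(profile = "tiny", n_images = 64, seed = 11,
                  out_dir = "runs/demo")
run <- train_run(cfg, verbose = TRUE)
tail(tidy(run), 1)
#> # A tibble: 1 × 7
#>   epoch train_loss val_loss l_bbox l_cfd   l_cls      lr
#>   <int>      <dbl>    <dbl>  <dbl> <dbl>   <dbl>   <dbl>
#> 1    20       3.45     4.37   3.34 0.106 0.00742 0.00005

rep <- evaluate_checkpoint(attr(run, "checkpoint"),
                           file.path(attr(run, "data_dir"), "test"))
rep
#> <eval_report> AP@0.5 = 0.8691 | best-F1 point: P = 0.7826, R = 0.8571,
#>   F1 = 0.8182 (TP 18, FP 5, FN 3)
```

`train_loss`/`val_loss` are the composite objective (box + confidence +
class components shown separately, each carrying its gain); the report
line says that on the seven held-out scenes (21 fish), at the best-F1
threshold, 18 fish were found with 5 false alarms, and the full ranking
has an average precision of 0.87 at match IoU 0.5.

Counting on individual images — a short-trained desk-scale model still
produces loosely localized duplicates, so counting works best with a
tighter overlap threshold than scoring does:

```r
det <- detect_images(attr(run, "checkpoint"),
                     file.path(attr(run, "data_dir"), "test", "images"),
                     config = suppression_config(nj = 0.3),
                     conf_threshold = 0.5)
attr(det, "counts")    # each scene truly contains 3 fish
#> scene_0058.png scene_0059.png scene_0060.png scene_0061.png scene_0062.png
#>              3              5              3              3              4
#> scene_0063.png scene_0064.png
#>              3              3
```

Soft-NMS versus hard NMS on an occluded pair, the package's core
post-processing claim, in four lines:

```r
pair <- tibble::tibble(cx = c(0, 0), cy = c(0, 2.5), w = 10, h = 10,
                       score = c(0.9, 0.8), class_index = 0L)
nms(pair, nj = 0.5)$score        # hard suppression deletes the second fish
#> [1] 0.9
soft_nms(pair, nj = 0.5)$score   # linear decay keeps it: 0.8 * (1 - 0.6)
#> [1] 0.90 0.32
```

A command-line wrapper with `make-synthetic`, `make-anchors`, `train`,
`detect` and `evaluate` subcommands is installed at
`system.file("cli", "fishdet.R", package = "fishdet")`.

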