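---
title: "Atrous attention tail modules for YOLO-style tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrous attention tail modules for YOLO-style tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laamseg)
```

## The problem and the model family

Single-stage detectors of the YOLOv5 family end their backbone with a
spatial pyramid pooling (SPP) block: parallel 5/9/13 max-pools that mix
receptive-field scales at no parameter cost but with no learnable
multi-scale reasoning and no feature re-weighting. For brain-MRI tumor
segmentation, where lesions vary widely in size and rim contrast, this
package implements a family of drop-in replacements for that tail slot:

* **ASPP** — the standard atrous spatial pyramid: four parallel branches
  (a 1×1 convolution, 3×3 atrous convolutions at dilation rates 6 and 12,
  and a global-average-pool branch restored by a 1×1 convolution and
  broadcast), concatenated and fused by a 1×1 convolution.
* **APCM** — ASPP followed by a standard CBAM (channel attention via global
  average pooling and two fully connected layers; spatial attention via
  channel mean/max maps and a 7×7 convolution), both applied
  multiplicatively, plus an identity residual from the slot input.
* **LASPP** — a lightweight pyramid: the 3×3 atrous branches use depthwise
  separable convolutions (a per-channel dilated convolution followed by a
  1×1 pointwise convolution), cutting their multiply-accumulate count by
  roughly the kernel area.
* **LAAM** — LASPP plus an *enhanced* simplified CBAM plus a projected
  residual (1×1 convolution + batch normalization on the slot input).
* **LAPCM / LLAAM** — APCM and LAAM with their residual connections removed,
  closing the ablation grid.

All variants are shape preserving and live behind one registry
(`build_variant()`), so `build_model()` can swap them without touching the
backbone, neck or head wiring.

## The enhanced attention branch: a design decision

Two readings of the published architecture are possible for the simplified
attention in LAAM/LLAAM: either the attention branch is only the cheap gate
(GAP bottleneck + 1×1 spatial map), or it additionally "utilizes multi-scale
dilated convolutions for broader receptive fields" before computing the
gates. The complexity figures decide this: LAAM is reported 4.1 GFLOPs above
LASPP, while a bare gate plus a 1×1 residual projection accounts for only
about 0.2 GFLOPs at the slot geometry (512 channels, 20×20). Two full-depth
3×3 dilated context convolutions (rates 6 and 12) inside the attention
branch cost ≈3.8 GFLOPs and close the gap. We therefore implement the
enhanced CBAM as: context = sum of the two dilated convolution blocks;
channel weights and the spatial weight map are both derived from that
context and multiply the pyramid output sequentially. The bare-gate reading
remains available through the individual building blocks
(`channel_attention_simplified()`, `spatial_attention_simplified()`).

The same arithmetic shows that two published figures cannot be reproduced by
*any* composition consistent with the ablation grid: APCM is printed
2.6 GFLOPs above ASPP although a standard CBAM plus an identity residual is
computationally negligible; and LLAAM is printed *below* LASPP although it
is a strict superset of it. The profiler reports what the declared
architecture implies; those two discrepancies are documented here rather
than forced.

## Complexity accounting and the one-time calibration

`profile_network()` propagates shapes symbolically and counts
multiply-accumulates of convolution and fully connected layers only;
`GFLOPs = 2·MACs/1e9`. Normalization, activation and pooling are excluded
(an `include_elementwise` convention flag exists but the frozen default is
off). Under this convention a faithful YOLOv5s segmentation layout with two
classes lands at 25.69 GFLOPs at 640×640 — matching the published baseline
to the printed precision, which strongly suggests it is the convention the
original measurements used. Parameters total 7.4 M, also matching the
published architecture.

One architectural quantity is not stated anywhere: the width of the
parallel pyramid branches. It is the only free knob that scales every
variant's cost, so it was calibrated **once**: with branch width
`round(1.42 × in_channels)` the four reproducible complexity figures
(baseline, ASPP, LAAM, LASPP) are simultaneously matched within ±0.4 GFLOPs.
The value is frozen in `laam_options()` and used identically for every
variant; per-variant fitting is deliberately impossible through the public
interface.

## The native layer stack

No deep-learning runtime is involved: convolutions (stride, dilation,
depthwise groups), batch normalization, SiLU, max pooling, nearest
upsampling, the attention gates and the full backbone–neck–head graph are
implemented directly on BLAS matrix products (im2col), each with a
hand-derived backward pass. Every backward pass is verified against central
finite differences in the unit tests. This keeps the package self-contained
and makes the gradient path — which Grad-CAM and the training harness rely
on — fully inspectable.

## Training harness

The loss follows the YOLOv5 segmentation recipe: distance-IoU (DIoU) box
regression on decoded boxes, IoU-valued objectness targets (detached from
the box gradient, so the confidence head learns to rank detections by
localization quality) with per-scale balance weights (4.0, 1.0, 0.4),
per-class BCE, and prototype-mask BCE cropped to the ground-truth box and
normalized by its area; gains 0.5 / 1.0 / 0.5 / 1.0. Anchor assignment uses
the v5 rule (size ratio < 4, center cell plus two nearest neighbor cells).
SGD uses momentum 0.937 and weight decay 5e-4, with a 20-step linear warmup
and linear decay to 10 % of the initial rate — the published protocol
(batch 8, lr 1e-2) is the default configuration.

Three desk-scale choices deviate from the large-scale recipe, all because a
handful of images cannot carry population statistics:

* the objectness term is logged as a KL divergence — soft-target BCE minus
  the target entropy, which leaves the gradient untouched but makes the
  objective vanish on a perfect fit instead of plateauing at an
  irreducible entropy floor;
* the objectness BCE adds a mean over the positive cells to the usual mean
  over all cells. With hundreds of images per batch-epoch the two
  normalizations differ only by a constant; with ten images the pure
  population mean dilutes the positive gradient by the cell count and the
  detector simply never fires within the step budget;
* after training (and before every in-training evaluation probe) the
  batch-norm running statistics are recomputed over the training set with
  frozen weights ("precise BN"), so inference-mode normalization reflects
  the final weights rather than an exponential tail of the trajectory.

One failure mode is worth recording because it is invisible in the training
loss: at batch size 1, batch normalization degenerates to per-image
(instance) normalization, the network learns to exploit it, and
inference-mode normalization with population statistics no longer
reproduces the fit — training-mode objectness logits of +26 at the correct
cells coexisted with inference-mode logits of −4. No recalibration can
repair this, because the learned function itself depends on per-image
statistics; the batch size must be large enough that batch statistics
approximate population statistics. The desk-scale protocol therefore
trains at batch 5 (half the ten-image set per step).

Evaluation decodes at confidence 0.001 (the standard setting for computing
average precision, where ranking matters and thresholding does not), with
greedy class-wise NMS at IoU 0.45.

## Synthetic phantoms: what they emulate, and what they do not

Each phantom is an elliptical brain on a dark background with mild
low-frequency texture, plus exactly one tumor-like blob: the
glioma surrogate is an irregular star-convex region (cosine harmonics 3–6)
drawn at low contrast with a diffuse rim (Gaussian blur, σ = S/320); the
meningioma surrogate is a compact near-ellipse at high contrast with a
sharp rim. Tumor centers are drawn uniformly from x ∈ [0.2, 0.8],
y ∈ [0.2, 0.6] and bounding-box sizes from [0.2, 0.6] — the annotation
statistics of the clinical datasets the pipeline targets — with the star
shape affinely normalized so the stored label box equals the drawn box
exactly (sizes are clipped only as needed to keep the box inside the
image). Labels are exact by construction: polygon (72 vertices plus the
four extreme boundary points, so its bounding box equals the drawn box
to machine precision) and raster
mask come from the same radial profile, so their IoU exceeds 0.98 at any
practical resolution.

What passing tests on phantoms shows: the geometry of the pipeline —
assignment, decoding, mask assembly, matching, the metric definitions — and
the trainability of every architectural path. What it does not show:
performance on real MRI (no scanner noise statistics, no anatomy, no
inter-rater ambiguity, no domain shift). The published precision/recall
tables are therefore out of scope by design.

## Problem sizes in the test suite

The architecture is size-agnostic (any multiple of 32), so the test suite
exercises it at the smallest faithful geometry: unit tests run 32–64 px
models at quarter width; the learning sanity check trains the LAAM variant
on ten 96-px phantoms for 120 epochs at batch 5 (240 SGD steps, about five
minutes on one CPU) and must reach a final loss below 10 % of the first
epoch and training-set mAP@50 above 0.9; label-distribution checks draw
1000 instances at 64 px (normalized statistics are resolution-free). The
complexity profile always runs at the full 640×640 geometry — it is
analytic and costs milliseconds.

## Numerical notes and limitations

* Batch normalization uses eps 1e-3 and momentum 0.03 (YOLO convention);
  weight initialization is Kaiming-uniform, seeded through the
  configuration, so builds and forwards are bit-reproducible.
* The DIoU gradient uses indicator subgradients at interval ties; for
  disjoint boxes the IoU term is flat and the center-distance penalty
  supplies the pull, so regression cannot stall at zero overlap.
* Greedy IoU matching (each prediction, in confidence order, takes the
  highest-IoU unmatched ground truth) is the standard evaluator's choice.
  It is *not* the optimal assignment: when a confident prediction grabs the
  ground truth a rival needed, greedy counts one true positive where the
  optimum finds two — even with well-separated IoU values. The test suite
  asserts the exact properties instead: greedy never exceeds the optimum
  and equals it whenever no such competition is possible.
* `mAP@50` pins the AP matching threshold at 0.5 while precision/recall
  follow the configured matching threshold; a flag (`ap_at_matching_iou`)
  lets AP follow the threshold instead, since published multi-threshold
  tables are ambiguous on this point.
* Timing figures are hardware-dependent and are reported, never asserted.
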