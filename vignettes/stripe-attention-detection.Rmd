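---
title: "Detecting elongated, occluded plant organs with stripe attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting elongated, occluded plant organs with stripe attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stripedet)
```

## The problem

Slender fruit such as field peppers are hard for standard detectors.  Three
properties of the data cause most failures: strong shape variation within a
class (straight, bent, thick, thin), elongated geometry with aspect ratios
commonly between 5:1 and 10:1 that square convolution kernels represent
poorly, and frequent partial occlusion by leaves that fragments the visible
evidence while the annotation still covers the whole fruit.

`stripedet` implements three mechanisms aimed at exactly these failure
modes, carried by a deliberately small anchor-free detector so that every
experiment in this package runs on a single CPU:

1. **MS-LSAM**, a multi-scale stripe local spatial attention block;
2. **ICC**, a dual-level (instance + class) supervised contrastive
   regulariser on RoI features;
3. **TR-Loss**, a masked strip-response reconstruction penalty.

## Model

### Pyramid contract

The backbone is a stack of stride-2 convolutions feeding a top-down feature
pyramid with four levels at strides 8, 16, 32 and 64, all unified to 96
channels.  On a 640x640 input the levels measure 80x80, 40x40, 20x20 and
10x10.  The carrier network is intentionally generic: the contribution
lives in the three modules below, which only rely on the stride/channel
contract holding.

### Stripe attention (MS-LSAM)

Each pyramid level `x` is refined in two multiplicative stages.

*Channel gate.*  Global average and max pooling give two channel
descriptors; a shared two-layer MLP (reduction ratio `r = 16`) maps each,
and the gate is `sigmoid(MLP(avg) + MLP(max))`, broadcast over space:
`x' = x * gate`.

*Spatial gate.*  `x'` is compressed to a 2-channel per-pixel mean/max
descriptor.  For each kernel length `k` in {7, 11, 21} a horizontal `1xk`
and a vertical `kx1` strip convolution are applied (zero padding keeps the
spatial size) and fused by an elementwise maximum into a response `A(k)`.
The three responses are stacked into the 3-channel *strip stack* `S`, their
mean is squashed by a sigmoid into the spatial gate, and `x'' = x' * gate`.
The stack is kept *pre-sigmoid* because the reconstruction loss needs
unsquashed responses whose channel means are meaningful.

Three kernel lengths cover short, medium and long visible spans.  On the
stride-64 level a 640 input gives a 10x10 map, smaller than the longest
kernel; zero padding simply truncates the kernel's support there, which we
accept and flag.  Whether strip convolutions carry biases is configurable
(`bias`), on by default.

The spatial branch is also available as a single 3x3 convolution
(`gate_type = "square"`, the ablation used to show the stripe advantage)
and as a constant gate (`gate_type = "uniform"`, the control for which the
Edge Concentration Score is exactly 1 by construction).

### Dual-level contrastive regularisation (ICC)

During training each image passes through two independently sampled
augmentation pipelines (horizontal flip, color jitter, region masking —
exactly these three families; geometric transforms move the boxes, the
photometric ones never do).  Ground-truth boxes — not predicted proposals —
are RoI-aligned (7x7, bilinear) on the stride-16 and stride-32 levels,
average-pooled and fused by the mean of the two 96-vectors.  Two separate
heads (96 → 256 → 128, ReLU, l2-normalised output) embed each RoI:

* the **instance** branch labels embeddings by instance id so the two views
  of one object are mutual positives (temperature 0.07 — selective);
* the **class** branch labels by category (temperature 0.15 — looser, so
  legitimate shape variation within a class is not crushed).

Both use the supervised contrastive loss.  We exclude the anchor itself
from the denominator and skip anchors without positives, the standard
reading under which a perfectly aligned positive pair reaches loss 0; the
literal variant with the self term is available via `include_self = TRUE`.
The branch losses combine as `0.05 * L_inst + 0.3 * L_cls`.  Embeddings
are taken from the post-attention refined features, since those are what
the head consumes.

### Masked reconstruction (TR-Loss)

Each ground-truth box is assigned to the pyramid level whose stride best
matches its scale.  The stated rule is "closest stride-to-scale match"; we
implement it as minimising `|log2(sqrt(area) / (8 * stride))|` — the level
where the box spans about 8 feature pixels — with ties to the finer
stride.  The box is projected by dividing by the stride, flooring the
top-left and ceiling the bottom-right corner.  A RoI is accepted when
*either* side of the projected box reaches 4 feature pixels, which keeps
extremely elongated boxes whose short side collapses to 1–2 pixels.

Inside each accepted RoI on the strip stack, one rectangular mask (25% of
each side, rounded half-up, clamped to a minimum of 2 pixels, position
uniform, shared across the three channels) is filled with the channel-wise
mean of the visible positions.  The penalty is the mean squared deviation
of the filled crop from the original, `(1/3hw) * sum (S_recon - S_RoI)^2`,
averaged over accepted RoIs, and 0 when none exist.  Gradients flow
through both the crop and the mean fill by default — the masking is a
training-time perturbation, not a fixed regression target; a stop-gradient
variant is available (`detach_target`).  The loss is excluded at
inference.

### Total objective

```
L_total = L_cls + L_loc + 0.35 * L_ICC + 0.1 * L_TR
```

The head losses are not part of the contribution and use standard choices:
focal classification (alpha 0.25, gamma 2) over all locations and an IoU
loss (`1 - IoU`) on positive locations, assigned by centre sampling with
the same scale-based level rule as TR-Loss.  Optimisation is SGD with
momentum 0.937, weight decay 5e-4 and a cosine schedule down to 1% of the
base rate.  The base learning rate is configuration-exposed; the package
default is 0.005, chosen for from-scratch training of the tiny carrier
(pretrained initialisation is deliberately out of scope).

## Synthetic scenes

Every experiment in the package runs on generated data, so the generator
is first-class, seeded and bit-reproducible.  A scene is a cluttered
background (soil tones, leaf-colored blobs, pixel noise scaled by
`clutter_level`) on which capsule-shaped fruits are rendered: rectangles
with semicircular caps, optionally bent along a circular arc
(`curvature_range`, degrees), with aspect ratio drawn from `ar_range` and
three classes distinguished by green/green/red hues.  Occluder blobs
(leaf-green ellipse unions) are drawn over each object until a drawn
coverage fraction is reached; `visibility` records the complement.

Two deliberate choices:

* **Boxes annotate the pre-occlusion extent** — the fruit, not its visible
  fragment.  The reconstruction loss is only meaningful if the annotation
  covers the occluded whole.
* **Objects are axis-aligned** (horizontal or vertical).  The aspect-ratio
  buckets G1–G4 are defined on axis-aligned boxes, so controlled-AR
  experiments need the rendered AR to survive into the annotation; free
  rotation would fold high-AR capsules into near-square boxes.

The default `ar_range = c(1, 12)` spans all four buckets (G1: AR < 2.5,
G2: < 5, G3: < 8, G4: >= 8).  What the generator does *not* emulate:
photoreal texture, wrinkles, specularity, 3-D plant geometry, perspective.
Passing tests therefore demonstrate mechanism correctness and qualitative
behaviour (e.g. stripe attention concentrating on elongated boundaries),
not field-ready accuracy on real imagery.

## Evaluation

The suite reports COCO-style AP: 101-point interpolated AP averaged over
IoU 0.50:0.05:0.95 and over classes, AP@50/AP@75, and size buckets below
32^2, between 32^2 and 96^2, and above 96^2 pixels (restricted ground
truths are ignored together with their matched detections).  Boxes are
half-open, so widths are `x2 - x1` exactly; VOC's 1-based closed
convention is translated only at the XML boundary.

The **Edge Concentration Score** of an attention map is the mean intensity
over the 3-pixel-wide strip just *inside* each projected box edge divided
by the whole-map mean.  We place the strip inside the box (the alternative
— straddling the edge — samples background attention), count corners once,
and score each ground truth on the gate of its assigned pyramid level with
the same level rule as TR-Loss, so bucketed ECS tables are internally
consistent.  Bucket means are instance means, not image means.  Any
constant map scores exactly 1.

## Numerical choices and degenerate inputs

* Gates use exact sigmoids, so both are strictly inside (0, 1) and
  `|x''| <= |x|` elementwise — useful invariants for testing.
* Elementwise-max fusion routes gradients to the larger branch; ties go to
  the horizontal branch.
* RoI alignment samples one bilinear point per bin at the bin centre, with
  pixel centres at half-integer coordinates and border clamping.
* A mask that covers a whole (tiny) RoI, a RoI empty after projection, or
  an image with no boxes all silently drop out of the reconstruction loss;
  the loss is exactly 0 when nothing remains.
* Anchors without positives are skipped in the contrastive loss; an empty
  box list short-circuits all auxiliary losses to 0.
* The l2-normalisation is epsilon-guarded against zero projections.

## Problem sizes in the shipped experiments

The tests and the acceptance script run everything at 128x128 input (the
pyramid then spans 16x16 down to 2x2), with 200 scenes of 2–4 objects for
the stripe-vs-square comparison trained for 200 steps per arm, and 4
scenes of 1–2 objects for the 500-step overfit check.  These sizes were
chosen as the package's desk-scale study conditions: large enough for all
four AR buckets to be populated (the 200-scene set contains roughly
100/180/230/100 instances in G1–G4) and for the capacity check to reach
AP@50 = 1.0, small enough that the whole suite runs on one CPU core in
minutes.  A worked 640-input configuration is the generator default and
works unchanged, just slower.

## Known limitations

* The carrier network is intentionally tiny; absolute AP values on real
  datasets are out of scope, and no pretrained weights are used.
* Cross-image relation modelling and memory-bank contrastive schemes are
  explicitly not implemented.
* Occlusion is modelled by opaque elliptical blobs; realistic occlusion
  priors (thin overlapping leaves, self-occlusion) are not.
* Single-rectangle masks only in the reconstruction loss; no irregular or
  multi-rectangle masking.
* Training uses one image per step; the contrastive batch is therefore
  within-image, which weakens the class branch when a scene contains a
  single object (its loss is legitimately 0 in that case).
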