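# stripedet

Detection toolkit for **elongated, occlusion-prone plant organs** — slender
fruit such as field peppers whose aspect ratios commonly run from 5:1 to
10:1 and whose bodies are routinely broken up by leaves.  Standard
detectors built on square convolution kernels lose exactly the cues that
matter here: long parallel boundaries and the continuity of a partially
hidden body.

The package implements, tests, and evaluates three mechanisms on top of a
compact anchor-free detector with a four-level, 96-channel feature pyramid
(strides 8/16/32/64):

* **MS-LSAM** — multi-scale stripe local spatial attention.  A channel gate
  `σ(MLP(avgpool x) + MLP(maxpool x))` (shared MLP, reduction 16) followed
  by a spatial gate built from horizontal `1×k` and vertical `k×1` strip
  convolutions at `k ∈ {7, 11, 21}` over a per-pixel mean/max descriptor,
  fused per length by elementwise max, averaged across lengths, and
  squashed by a sigmoid.  The pre-sigmoid per-length responses are kept as
  a 3-channel *strip stack* `S`.
* **ICC** — dual-level supervised contrastive regularisation.  Ground-truth
  RoIs from two independently augmented views are RoI-aligned on the
  stride-16/32 levels, fused, and projected by two heads (96→256→128,
  ℓ2-normalised) into an instance branch (views of one object are mutual
  positives, τ = 0.07) and a class branch (same-category objects attract,
  τ = 0.15); `L_ICC = 0.05·L_inst + 0.3·L_cls`.
* **TR-Loss** — masked strip-response reconstruction.  Per ground-truth RoI
  on `S` (scale-assigned pyramid level, floor/ceil projection, accepted
  when either projected side ≥ 4), a rectangular mask (25% per side, min 2
  px, uniformly placed) is filled with the visible channel mean and the
  mean squared deviation is penalised:
  `L_TR = (1/3hw) Σ (S_recon − S_RoI)²`, averaged over RoIs.

The total training objective is

```
L_total = L_cls + L_loc + 0.35 · L_ICC + 0.1 · L_TR
```

with focal classification and IoU box-regression head losses.

Everything runs on synthetic field scenes generated by the package itself
(seeded, bit-reproducible, written as Pascal VOC datasets), so no external
data or GPU is needed.  The evaluation suite provides COCO-style
mAP/AP@50/AP@75 with size buckets, aspect-ratio buckets G1–G4
(AR < 2.5 / < 5 / < 8 / ≥ 8), and the **Edge Concentration Score**
`ECS = μ_E / μ_G`: mean attention on the 3-pixel strip inside a box's
edges over the whole-map mean (1.0 means no boundary concentration).

## Worked example

```r
library(stripedet)

# 1. A seeded synthetic scene: curved capsule "fruits", leaf occluders
spec <- scene_spec(image_size = 128, n_objects = c(2, 3), seed = 3,
                   length_frac_range = c(0.25, 0.5))
sc <- generate_scene(spec)
sc$boxes
#>      x1 y1  x2  y2
#> [1,] 54 44 115  49
#> [2,] 24 69  33 110
sc$visibility
#> [1] 0.8239203 0.6194969

# 2. Train the tiny stripe-attention detector for a few hundred steps
scenes <- lapply(1:8, function(i) generate_scene(spec, seed = 200 + i))
model <- train_detector(scenes, model_config(), steps = 600, seed = 1)
tail(model$log[, c("step", "l_cls", "l_loc", "l_inst", "l_ccls", "l_tr")], 1)
#> # A tibble: 1 x 6
#>    step l_cls l_loc  l_inst l_ccls   l_tr
#>   <int> <dbl> <dbl>   <dbl>  <dbl>  <dbl>
#> 1   600 0.186 0.304 0.00353 0.0123 0.0879

# 3. Detect and evaluate
ev  <- evaluate_model(model, scenes)
map_suite(ev$dets, ev$gts)
#> mAP 0.329 | AP@50 0.653 | AP@75 0.304 | S/M/L 0.290/0.442/NA
bucketed_report(ev$dets, ev$gts, ev$gates)
#> # A tibble: 4 x 4
#>   bucket  n_gt    map mean_ecs
#>   <chr>  <int>  <dbl>    <dbl>
#> 1 G1         5 0.538     0.903
#> 2 G2         5 0.390     0.819
#> 3 G3         8 0.0920    0.921
#> 4 G4         1 0         1.01
```

The first scene holds one long horizontal fruit (aspect ratio about 12:1)
and one vertical one, each partly covered by occluders -- `visibility` is
the uncovered area fraction.  The loss log shows all five components the
trainer optimizes (focal classification, IoU localization, the two
contrastive branches, the reconstruction penalty).  After 600 steps on
eight 128-pixel scenes the detector finds most objects at the loose IoU
threshold (AP@50 = 0.65) and the per-bucket mAP falls with elongation --
exactly the failure mode the stripe modules target; at this tiny training
scale the gates' edge concentration still hovers around 1.  The 200-scene
comparison run by `scripts/acceptance.R` (below) is where the
stripe-vs-square ECS contrast appears.

A thin command-line wrapper for dataset synthesis, training, prediction
and evaluation lives at `inst/cli/stripedet.R`.

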