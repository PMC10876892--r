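---
title: "Weakly-supervised retinal detachment localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised retinal detachment localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal detachment (RD) is an ophthalmic emergency: the neurosensory retina
separates from the pigment epithelium, and the preoperative posture that
slows progression depends on *where* the detachment sits. On ultra-widefield
(UWF) fundus photographs an RD appears as an elevated, corrugated region,
but pixel-accurate expert contours are scarce. `rdmap` implements a
weakly-supervised pipeline that learns only from image-level RD / non-RD
labels and still outputs a spatial localization: a per-pixel probability
map, a binary pseudo-mask, an anatomical assignment into four clock-hour
zones and 48 partitions, and the matching postural advice.

The pipeline has five stages:

1. **Preprocessing** — an ROI template erases the four information-free
   corners of the square UWF canvas, then CLAHE enhances local contrast on
   the luminance channel.
2. **Classification** — a 4-stage convolutional backbone with a single-logit
   sigmoid head is trained with focal loss (alpha = 0.65, gamma = 1.15,
   learning rate 0.01).
3. **Attention modulation** — channel attention modulation modules (AMM) are
   inserted between every two consecutive stages and the network is
   fine-tuned at learning rate 0.001. Each AMM computes channel attention
   `a` (global average pool, bottleneck, sigmoid), recalibrates it as
   `a~ = (a + 1 - rank(a)/C)/2`, and scales channels by `1 + lambda * a~`.
   The recalibration lifts minor-but-relevant channels so they survive into
   the localization maps.
4. **Localization** — Grad-CAM on the stage-4 feature maps
   (`ReLU(sum_k w_k A_k)` with spatially pooled gradients `w_k`), per-image
   min-max normalization to [0, 1] over the ROI, bilinear resampling to the
   original grid, ROI re-masking, and thresholding at probability 0.5 into a
   pseudo-mask.
5. **Anatomy and guidance** — a coordinate frame calibrated by the manually
   annotated fovea and the segmented optic disc assigns every pixel a
   clock-hour zone (superior 10–2, right 2–4, inferior 4–8, left 8–10) and
   one of 48 partitions; the posture rule maps the primary zone to supine /
   sitting / right-lateral / left-lateral, with posterior-pole involvement
   overriding to supine plus urgent referral.

## The 48-partition construction

The published zoning text specifies 15-degree clockwise sectors (24 of them)
and a posterior pole defined as the fovea-centered circle containing the
optic disc. Crossing the 24 sectors with the inside/outside-pole split gives
the 48 anatomical regions shown in the reference figure; we adopt that
reading (the only alternative producing 48 regions, 7.5-degree sectors,
contradicts the stated 15 degrees). Partition indexing is
`ring * 24 + floor(theta / 15)` with ring 0 inside the pole circle. A
partition bit is set when **strictly more than** `min_pixels` lesion pixels
fall into it; the printed rule is 50 pixels at a 512-pixel canvas, and the
threshold scales as `(canvas / 512)^2` so the rule is resolution-consistent
(at the desk-scale 128 canvas the effective threshold is 3.125). Boundary
conventions are half-open: an angle exactly on a sector edge belongs to the
clockwise-later sector, and a probability exactly at the 0.5 threshold is
kept in the pseudo-mask.

Ties in the primary zone (equal pixel counts) resolve by the fixed order
superior > inferior > right > left; this is a determinism device, not a
clinical claim. Posterior-pole involvement reuses the same `> min_pixels`
counting rule, since only the probability threshold is specified for that
task.

## Desk-scale model

The reference implementation used a ResNet-101; nothing in this environment
provides a GPU or a deep-learning runtime, so `rdmap` ships a from-scratch
4-stage backbone (RcppArmadillo convolutions with exact analytic backward
passes, verified against finite differences in the test suite). The 4-stage
contract, AMM insertion points between consecutive stages, and the stage-4
Grad-CAM source are preserved. Stage strides are 2/2/2/1/1 including the
stem, so a 128-pixel input yields 16 x 16 stage-4 maps; the coarser 8 x 8
alternative smeared wedge boundaries across 15-degree sectors after
upsampling and measurably hurt partition precision.

Design choices worth knowing about:

* **Feature standardization before the head.** The GAP feature vector is
  standardized by running statistics (BatchNorm-style, constants in the
  backward pass, frozen at inference). Without it the class-separating
  information lives in tiny absolute feature differences and the head
  cannot be trained at the stated learning rates. The logit remains linear
  in the stage-4 maps, so Grad-CAM stays exact (the effective CAM weights
  are `w_c / sd_c`).
* **Weight decay 5e-4** on convolution and head weights. Besides the usual
  regularization it concentrates the activation maps on the discriminative
  channels, which is what gives the *baseline* model its tight,
  high-precision/low-recall maps — the phenotype the attention modulation
  is then meant to correct.
* **Short fine-tuning (2 epochs at lr 0.001).** Training far past
  classification convergence degrades map quality for both the plain and
  the modulated network (the focal loss saturates and weight decay keeps
  eroding the discriminative channels). The 10-fold learning-rate drop in
  the reference protocol points at the same concern.
* **AMM internals.** The cited recalibration scheme is a two-branch
  architecture; the text adopted here describes only modules "between every
  two stages", so the AMM is implemented as channel attention plus the
  rank-inversion blend above, with a bottleneck (reduction ratio 4)
  initialized so the initial attention is monotone in channel energy. The
  backward pass treats the rank as locally constant. `lambda = 0` is
  bit-exactly the identity, which is the tested contract that the
  AMM-equipped network reproduces the pretrained classifier.
* **Optimizer** is momentum SGD (0.9), batch size 16, random initialization
  (no transfer learning at desk scale). Horizontal-flip augmentation is
  deliberately disabled: a flip swaps the nasal/temporal sides and corrupts
  the laterality semantics of the zone system.
* **Probability-map normalization** is per-image min-max over the ROI; the
  0.5 pseudo-label threshold is meaningless without it and no normalization
  is stated. A constant map normalizes to all zeros — no lesion claimed.
* **Disc segmentation** is a small 2-level encoder-decoder with skip
  connections, trained with class-balanced pixel-wise cross-entropy and
  leaky ReLU. With the disc at ~0.5% of pixels, an unbalanced loss drives
  the network into the all-background collapse. The sidecar disc, when
  present, is preferred as the oracle landmark; the active source is
  recorded in the frame for provenance.
* **CLAHE** (clip 2.0, 8 x 8 tiles, 256 bins) is applied deterministically
  to every image, train and inference. Whether the original protocol used
  it as a fixed step or a stochastic augmentation is not stated; a fixed
  step is reproducible. It operates on the Rec. 601 luminance with chroma
  carried as offsets.

## The synthetic world

No public UWF/RD dataset exists, so the generator is the test substrate for
every stage. It emulates exactly the features the pipeline depends on: a
centered circular fundus field (radius 0.48 x canvas) with four empty
corners; an optic disc (radius 0.04 x canvas) at a horizontal offset of
0.22 x canvas on the nasal side (image-right for OD, image-left for OS); a
slightly darker fovea at the canvas center; and, for RD samples, a
contiguous wedge lesion spanning a clock-angle sector and a radial band,
brightened with a sinusoidal radial corrugation (period canvas/24,
amplitude 0.5 of the lift). The shallow variant scales the intensity lift
by 0.3, creating the low-contrast cases that real systems miss. Optional
bright rim arcs emulate camera-pad artifacts for robustness experiments.
Lesion photometry is an artifact choice, not a claim about real OPTOS
imagery.

Samples are deterministic functions of their seed; OS images are the exact
horizontal mirror of the canonical OD rendering, so mirror invariants hold
byte-for-byte. The RD decision is the first RNG draw of each sample, a
documented contract that lets dataset-level RD counts be derived from seeds
alone. Truth partition vectors are recomputed from the rendered mask
through the anatomy module, so generator and geometry cannot drift apart.

What a green test does **not** establish: the generator has no vessel
trees, no illumination gradients from eyelids or media opacity, no real
corrugation texture statistics, and lesions are single contiguous wedges.
Model metrics on this world say the pipeline's machinery works end-to-end,
not that the desk-scale network would approach the published operating
points on clinical images.

## The scaled-down comparison

The headline comparison (baseline without AMM: high precision, limited
recall; modulated model: recall up at a small precision cost) is reproduced
directionally on the synthetic world: 500 samples at 128 pixels (80/20
split, half RD, 30% of lesions shallow), the baseline being the pretrained
classifier and the proposed model its AMM fine-tune, with identical seeds.
The suite asserts `recall(AMM) > recall(baseline)`,
`precision(baseline) >= precision(AMM) - 0.02`, and a >= 70% rate of the
pseudo-mask centroid falling inside the true lesion's bounding box. The RD
prevalence is set to 0.5 rather than the clinical ~10% because the
anatomical evaluation — like the published one — runs on the RD subset
only, and a desk-scale benchmark needs enough RD test images for stable
pooled counts. One honest caveat, also visible in the numbers: part of the
recall gain comes from fine-tuning itself, not only from the modulation;
the lambda = 0 control fine-tune broadens the maps too, but loses more
precision than the modulated variant at equal epochs.

## Statistics

All proportions carry Wilson score 95% intervals; the published report does
not name its CI method, but with the pooled-decision denominators
(~467 x 48) Wilson reproduces intervals of the printed width. The F1
interval propagates the Wilson bounds through the harmonic mean (a
documented approximation). Cohen's kappa is unweighted with the standard
asymptotic variance `p_o(1-p_o) / (n (1-p_e)^2)`. Average precision uses
step-wise integration of the precision envelope over recall (the dominant
modern convention; whether the original used step or trapezoid
interpolation is unstated), on a 101-point threshold grid by default — the
suite checks a 10x finer grid moves AP by less than 0.01. Partition
decisions are pooled over images (micro-averaging); macro-averaging is
deliberately not the default because the printed CI widths imply pooling.

The 80:20 split uses `floor(n * train_fraction)` for the train size; on the
reference dataset size of 24,208 this gives 19,366/4,842 where the original
reports 19,365/4,843 — a one-image convention difference that is asserted
(with a note) rather than reverse-engineered.

## Known limitations

* The desk-scale backbone is orders of magnitude smaller than a ResNet-101;
  absolute metric values are not comparable to the published ones, only
  patterns are.
* Macula-OFF images (no fovea annotation) are excluded from anatomical
  evaluation by a hard guard, mirroring the published 467/482 subset; the
  pipeline offers no macula ON/OFF discrimination.
* UWF optics are not modeled: partitions are computed in image space, not
  in degrees of retina; no spherical projection correction is applied.
* The CLI stores images as PNM and configuration as JSON (no raster-PNG or
  YAML library is part of the supported dependency set); the formats are
  otherwise equivalent to the stated interfaces.
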