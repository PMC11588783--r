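---
title: "Distinct and completed borders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinct and completed borders: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usborder)
```

## The evaluation model

Expert delineation of structures in B-mode ultrasound mixes two cognitive
modes. Where a tissue interface reflects strongly, the annotator traces a
visible edge; where the signal is lost — dropout, shadowing, depth
attenuation — the annotator completes the contour from anatomical prior
knowledge. `usborder` makes that distinction operational:

1. an **edge map** is computed from the image as a thresholded,
   Gaussian-smoothed Sobel gradient magnitude;
2. each class border `B` (the inner one-voxel boundary of the class mask)
   is split by the Hadamard product with that edge map into `B_distinct`
   (edge-supported) and its exact complement `B_completed`;
3. predictions are scored per border regime: the true-positive share of
   the reference border decomposes exactly as
   `B_TP = B_Distinct + B_Completed`;
4. **Seg-Grad-CAM** explains what a model looks at when scoring a given
   border pixel set: gradients of the summed class score over the set with
   respect to a layer's feature activations, global-average-pooled into
   per-feature weights, recombined and rectified.

The split is a *measurement on the image/annotation pair*, not a learned
quantity: it assumes only that edge evidence is what a gradient operator
can detect after speckle suppression.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `edge.smooth_sigma` | 2.0 | voxels | suppresses speckle at ~0.28 mm voxels without erasing interfaces |
| `edge.threshold_method` | Otsu on normalized gradient | — | parameter-free, invariant to affine intensity rescaling |
| `edge.threshold_value` | — | fraction / percentile | used by the `fixed` / `percentile` methods |
| `split tolerance_radius` | 0 (`split_border`), 1 (pipelines) | voxels | 0 is the strict Hadamard product; see below |
| `match_tolerance` (TP rule) | 1 | voxels (Chebyshev) | border masks are one voxel thick; strict overlap punishes half-voxel shifts |
| `nsd tau` | 1 voxel (mean spacing) | mm | conventional "within one voxel" surface agreement |
| aggregation | mean ± sample (n−1) sd per case | — | small test sets; per-case aggregation matches how results tables report spread |

**Why pipelines default to a split tolerance of 1 voxel.** The Sobel
response of a bright ridge is zero at the ridge crest and peaks on its
flanks, so the detected edge band sits about one voxel off an annotated
border that runs along the crest. Radius 0 remains the faithful reading of
the Hadamard product and is the `split_border` default; the evaluation
pipelines and the phantom studies use radius 1 so that crest-aligned
borders are credited. This is the package's resolution of an otherwise
open choice in the method; the tolerance is monotone (distinct can only
grow with radius), which the tests assert.

**Edge thresholding details.** The gradient is normalized to [0, 1] by its
maximum before thresholding (so results are invariant to affine intensity
rescaling), Otsu runs on a 256-bin histogram, and when the between-class
variance plateaus across an empty histogram gap the middle of the plateau
is returned. A constant gradient (blank image) yields an all-false edge
map with a warning rather than an error.

## Seg-Grad-CAM conventions

* The target is the **sum** of pre-softmax scores over the pixel set:
  summing per-pixel gradients inside the pooled weight equals
  differentiating the summed score, and pre-softmax scores keep classes
  uncoupled.
* The default layer is the last convolution before the classification
  head (`dec1` in the shipped encoder–decoder); any named layer can be
  inspected.
* Maps are bilinearly upsampled to the input grid; no post-ReLU smoothing.
* Display normalization (dividing by the map maximum) happens only in
  plotting code; similarity scores and region means are computed on
  unnormalized maps.
* Pre-ReLU maps are additive over disjoint pixel sets (linearity of
  differentiation), and the stored weights/activations reconstruct the map
  exactly — both are asserted in the tests, alongside equality with a
  central finite-difference oracle at 1e-3 relative tolerance.

## The phantom generator

The generator emulates the statistical structure the border split assumes,
not ultrasound physics:

* three blob-shaped structures (smooth random closed contours, wider than
  tall) stacked in depth on a 96×96 grid at 0.28 mm spacing — echoing a
  calf cross-section with three muscle bellies;
* per-tissue homogeneous echogenicity (0.45/0.60/0.75 vs background
  0.20), multiplied by `exp(-mu * depth)` with `mu = 0.03`/mm;
* a Gaussian interface ridge (peak 0.9, width ~1 voxel) along the
  designed-distinct border, attenuated by the same depth law;
* multiplicative log-normal speckle (`sd = 0.15` of the log);
* **engineered dropout**: a designed fraction (default 0.45, the
  completed-border share typical of deep leg-muscle annotations) of each
  structure's border carries no ridge, placed on the deepest border arcs
  (`deep_sectors`) so completion correlates with depth as it does in vivo;
  local intensity contrast is blended away around dropout segments so the
  completed border is genuinely invisible, and the ridge amplitude
  retreats ~3 voxels from each distinct/dropout junction with a short
  taper — terminating a bright ridge otherwise creates an endpoint edge
  that leaks edge evidence into the dropout sector.

The designed masks partition the border exactly and the completed share
matches the requested fraction to rounding (±0.5 voxel). Determinism is
bitwise under a fixed seed.

**What the phantoms do not model:** coherent scattering and realistic
speckle statistics (Rayleigh/Rician envelopes), refraction and reverberation
artifacts, anisotropic point-spread functions, freehand-sweep compounding
stripes, and annotation noise. Passing tests on phantoms therefore show
that the *measurement machinery* is correct and well-calibrated under the
assumed structure — not that the split reproduces expert judgement on any
particular clinical dataset.

## Toy models

No deep-learning framework is assumed: the fixtures are a small
convolutional encoder–decoder written directly in R (3×3 convolutions,
2×2 max-pool, nearest-neighbour upsampling, skip concatenation; ~3 000
parameters) and a fully deterministic `fixed_linear` model with hand-set
weights whose gradients are known in closed form. Training follows common
practice for this task: inverse-frequency weighted cross-entropy, Adam at
lr 1e-3 with a step decay of 0.5 every 10 epochs, batch size 2,
vertical-axis flips, min-max intensity normalization; 200 steps over 32
phantom slices at 64×64 (about half a minute on one CPU). The network also
receives a normalized depth coordinate as a second input channel: depth
attenuation makes appearance depth-dependent, and a small
translation-equivariant CNN has no other way to use that fact.

All analytic gradients (convolution, pooling, upsampling, loss) are
verified against central finite differences in the tests; the
Seg-Grad-CAM oracle check runs through the same forward-with-override
mechanism.

## Numerical and degenerate-input choices

* Distances use an exact Euclidean distance transform (separable
  lower-envelope of parabolas) honoring anisotropic spacing; the testthat
  oracle is all-pairs brute force.
* HD95 uses the pooled symmetric surface-distance distribution and R's
  default (type-7) quantile.
* Empty masks make surface metrics *undefined*: they raise an error and
  are recorded as missing in tables, never as 0. Two empty masks have
  Dice 1 by convention. An empty prediction border yields an all-zero
  decomposition row with a warning.
* Reference fractions are computed as `distinct` and `100 - distinct`,
  and `tp_total` as the sum of its two parts, so the stated identities
  hold exactly in floating point.
* Reflect padding everywhere in filtering; grid-edge voxels of a class
  count as border (field-of-view truncation behaves like an interface).
* Report CSVs are rounded to 3 decimals for reading; full-precision
  values live in the JSON files next to them, and `validate_report`
  re-checks every invariant from the CSVs at rounding tolerance.

## Problem sizes

The test suite and the acceptance script run on desk-scale data by
design: 96×96 phantoms (64×64 for training and batch demos), 20 seeds per
stochastic claim, ≤16³ masks for brute-force oracle comparisons, 8×8
feature maps for finite-difference CAM checks, and ≤64³ grids for 3D code
paths.

## Known limitations

* The split inherits the edge detector's biases: very weak but real
  interfaces below the threshold count as completed, and strong
  non-anatomical edges (artifacts) near a border count as distinct.
* Border masks are voxel sets, not sub-voxel surfaces; all tolerances are
  integers in voxel units.
* The toy models exist to exercise and verify the explanation machinery,
  not to represent publication-scale architectures; CAM findings on them
  should not be read as statements about UNet-family models trained on
  clinical data.
* 3D phantoms extrude 2D cross-sections with ellipsoidal caps; they
  exercise the 3D code paths but are geometrically simpler than compounded
  freehand volumes.
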