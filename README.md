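# usborder

Clinician-inspired evaluation of ultrasound segmentation: split anatomical
borders into **distinct** and **completed** parts, score predictions
separately on each, and explain model decisions with **Seg-Grad-CAM** over
border pixel sets.

## The problem

B-mode ultrasound does not show organs the way CT or MRI do. Tissue
intensities fluctuate, and experts delineating a structure rely on two very
different kinds of evidence: bright tissue interfaces where the acoustic
reflection is strong (they *see* the border), and anatomical prior
knowledge where the signal is gone — shadows, dropout, depth attenuation
(they *complete* the border). A segmentation network trained on such
annotations inherits both behaviours, but a single Dice score cannot tell
whether a model fails on the visible evidence or on the interpolated
anatomy. This toolkit evaluates the two regimes separately.

## The method

**Border split.** Given an image `I` and an expert border label `B`, the
edge-supported part of the border is

```
B_distinct = Thres(I * K_smooth * K_sobel) ⊙ B
B_completed = B \ B_distinct
```

i.e. the Hadamard product of the border mask with a binary edge map (a
Gaussian-smoothed Sobel gradient magnitude, thresholded — Otsu by default).
The two parts partition the border, so their shares of the total border sum
to 100 %.

**True-positive decomposition.** Predicted borders are scored against the
reference border: a reference voxel is a true positive if a predicted
border voxel lies within a small Chebyshev tolerance. The total
true-positive share `B_TP` decomposes exactly into `B_Distinct` +
`B_Completed`, the shares recovered on each part of the split. Alongside,
the standard boundary metrics Dice, HD95 (95th-percentile symmetric
surface distance, mm) and NSD (fraction of surface within a tolerance
`tau`) are reported per case and class.

**Seg-Grad-CAM.** For a class `c` and a pixel set `Y^c` (a distinct
border, a completed border, the background, a whole class), the
localization map is

```
L^c = ReLU( Σ_f [ (1/wh) Σ_ij ∂Y^c_ij / ∂A^f_ij ] · A^f )
```

— gradients of the summed class score over the pixel set with respect to
the activations `A^f` of a chosen layer, globally average-pooled into one
weight per feature map, recombined and rectified. Any model satisfying a
small adapter contract (per-pixel pre-softmax scores; activations and
gradients at a named layer) can be explained; the package ships a
deterministic `fixed_linear` fixture and a trainable `small_unet`.

**Phantoms.** A generator produces ultrasound-like 2D/3D phantoms with
known ground truth: blob-shaped soft-tissue structures, bright interface
ridges that decay exponentially with depth, multiplicative log-normal
speckle, and engineered dropout sectors (deepest border arcs by default)
where the interface carries no signal — so the designed distinct/completed
split is known exactly and every claim the toolkit makes can be tested
without external data.

## Worked example

```r
library(usborder)

ph <- generate_phantom(phantom_spec(seed = 7))
ph
#> <phantom> 96 x 96, 4 classes, border 233 voxels (45.1% designed completed)

em <- compute_edge_map(ph$image)          # smoothed Sobel + Otsu
em
#> <edge map> 96 x 96, 1024 edge voxels (11.1%), threshold 0.2931 (otsu)

splits <- split_all_classes(ph$labels, em, tolerance_radius = 1)
tidy(splits$class_1)
#>   class_id n_border n_distinct n_completed distinct_pct completed_pct
#>          1       76         44          32         57.9          42.1

pred <- simulate_prediction(ph$labels, "elastic_jitter", 2, seed = 1)
tp_decomposition(splits$class_1, extract_border(pred, 1L),
                 match_tolerance = 1)
#>   reference_distinct_pct reference_completed_pct tp_total_pct
#>                     57.9                    42.1         89.5
#>   tp_distinct_pct tp_completed_pct
#>              55.3             34.2

case_metrics(pred, ph$labels, case_id = "phantom_7")
#>     case_id class_id  dice hd95_mm   nsd
#>   phantom_7        1 0.923   0.560 0.487
#>   phantom_7        2 0.873   1.010 0.341
#>   phantom_7        3 0.872   0.792 0.368
```

Reading: 57.9 % of the first structure's annotated border coincides with
detected edges (distinct); the jittered prediction recovers 89.5 % of the
reference border, and the 10.5 points it misses are split between the two
regimes (distinct 57.9 → 55.3, completed 42.1 → 34.2 — the degraded
prediction loses completed border much faster than distinct, mirroring how
models struggle most where annotators interpolated).

Batch evaluation with report files shaped like the tables above:

```r
res <- run_evaluation(run_config(mode = "phantom", n_cases = 10,
                                 error_model = "dilate", magnitude = 2,
                                 seed = 1, out_dir = "report"))
validate_report("report")$pass
```

Seg-Grad-CAM of a trained toy model:

```r
m <- toy_model_fixture("small_unet", seed = 0)    # ~25 s on one CPU
cams <- cam_for_split(m, ph$image, splits$class_1)
autoplot(cams$distinct)
render_overlay(ph$image, cams$distinct, "cam.png",
               contour = splits$class_1$border)
```

A command-line front end with subcommands `phantom`, `split`, `metrics`,
`cam`, `validate` is installed at `system.file("cli/usborder",
package = "usborder")`.

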