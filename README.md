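# plaquekit

Quantification of disclosing-gel stained dental plaque in oral
photographs.

A three-tone disclosing gel stains dental plaque by maturity: **new**
plaque (hours old) stains pink, **mature** plaque (2–3 weeks) stains
purple, and **over-mature** (mineralizing) plaque stains blue. plaquekit
turns an RGB photograph of a stained mouth into quantitative plaque
measurements:

- **Normalization** — HSV-space preprocessing that suppresses lips,
  clamps glare (value channel capped at 230), removes clean white enamel,
  and snaps every remaining pixel onto a four-color canonical palette
  (new `(120,200,200)`, mature `(125,200,200)`, over-mature
  `(100,200,200)`, white `(0,0,255)` in OpenCV-style HSV). Overlapping
  class ranges resolve toward the clinically more severe class.
- **Segmentation** — per-class pixel masks, connected-component labeling
  with a minimum-area filter, and YOLO-format bounding boxes.
- **Detection evaluation** — class-aware greedy IoU matching (TP at
  IoU ≥ 0.5), precision/recall, PR curves with all-point interpolated
  average precision, and mAP@50; YOLO `.txt` label I/O.
- **O'Leary index** — per-subject plaque burden as the affected
  percentage of 48 examined tooth surfaces (4 per tooth), with
  Mild (≤ 25) / Moderate (≤ 50) / Severe categorization and cohort
  summaries.
- **Synthetic data** — a seeded stained-mouth generator whose ground
  truth (masks, boxes, surface charts, indices) is computed analytically
  from the same rasterization the renderer uses, so noise-free scenes are
  recovered by the pipeline *exactly*. MixUp and CutMix augmentations
  with label bookkeeping are included.
- **CLI** — `simulate`, `preprocess`, `segment`, `evaluate`, `oleary`,
  and `run-all` subcommands (see `inst/scripts/plaquekit`).

## Worked example

```r
library(plaquekit)

# a seeded synthetic mouth: 6 of 48 surfaces affected
s <- generate_scene(random_scene_spec(seed = 7, k_affected = 6,
                                      width = 256, height = 256))

# preprocessing pipeline
norm <- rgb_to_hsv(s$image)
norm <- suppress_lips(norm)
norm <- reduce_brightness(norm)          # V capped at 230
norm <- suppress_white(norm, default_profile())
norm <- normalize_colors(norm, default_profile())

# segmentation to boxes, scored against the generator's ground truth
masks <- extract_class_masks(norm)
pred <- do.call(rbind, lapply(masks, masks_to_boxes))
evaluate_detections(list(pred), list(s$gt_boxes))
#> <eval_report mAP@50 = 1.0000, P = 1.0000, R = 1.0000 at conf >= 0.25>
#>  class_id n_gt ap precision recall
#>         0    1  1         1      1
#>         1    2  1         1      1
#>         2    3  1         1      1

# plaque burden
compute_index(chart_from_masks(masks, s$spec$layout))
#> <oleary_result 12.50% (6/48 areas) -> MILD>

categorize_oleary(c(10, 30, 70))
#> [1] "MILD"     "MODERATE" "SEVERE"
```

The command-line equivalent:

```sh
Rscript inst/scripts/plaquekit run-all --n 5 --seed 7 --out results/
```

## Testing

The test suite is pure-text and generates every fixture at run time:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "plaquekit",
                               load_package = "installed")'
```

It includes property-based checks against independent oracles (a scalar
hexcone HSV conversion, a rasterization IoU oracle, an exhaustive
matcher, and a step-integration AP oracle) plus end-to-end acceptance
blocks in `tests/testthat/test-acceptance.R`.

## Documentation

Function documentation lives in roxygen comments in `R/`; the methods
vignette (`vignettes/methods.Rmd`) describes the color model, the
preprocessing pipeline, the scoring conventions and the synthetic
generator's exactness guarantee.

## License

MIT (see `LICENSE`).
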