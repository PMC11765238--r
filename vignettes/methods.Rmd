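---
title: "Methods: HSV plaque quantification, detection scoring, and the O'Leary index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HSV plaque quantification, detection scoring, and the O'Leary index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(plaquekit)
```

# The measurement problem

A three-tone disclosing gel stains dental plaque by maturity: *new* plaque
(hours old) stains pink, *mature* plaque (2–3 weeks) stains purple, and
*over-mature* (mineralizing) plaque stains blue. Given an RGB oral
photograph taken after gel application, plaquekit

1. normalizes the image to a four-color canonical palette in HSV space,
2. segments the three plaque classes and converts pixel masks into
   bounding boxes,
3. scores detector output against ground truth (precision, recall, PR
   curves, mAP@50), and
4. summarizes per-subject plaque burden with the O'Leary index.

A seeded synthetic generator provides ground-truthed images so the entire
chain can be validated without clinical data.

# Color model

## HSV scales

Pixels are held on OpenCV-style scales: hue in `[0, 180)` half-degree
units, saturation and value in `[0, 255]`. One deliberate refinement: hue
is stored as a *double* (possibly fractional), while S and V are rounded
integers. Rounding hue to whole half-degrees discards up to a quarter
degree, which is enough to move an RGB round trip by more than one
intensity step; keeping hue exact bounds the reconstruction error of
`hsv_to_rgb(rgb_to_hsv(x))` at one intensity level per channel, and the
value channel (`V = max(R, G, B)`) is preserved exactly.

## Canonical palette

Normalization snaps every pixel onto four HSV triples:

```{r}
normalized_palette()
```

Background and non-dental content are excluded through a *sentinel mask*
carried alongside the raster: masked pixels hold the sentinel triple
`(0, 0, 0)` and are ignored by all downstream statistics. Suppressed white
(clean tooth) pixels are a special case — they are masked out of analysis
but still carry the canonical white `(0, 0, 255)`.

# Preprocessing pipeline

The normalization stage applies, in order:

1. **Lip suppression** (`suppress_lips()`): pixels inside the reddish lip
   hue range are removed, together with border-touching connected
   components that are mostly lip-colored after a small dilation (the
   fringe left by interpolation at lip boundaries). Pixels inside any
   plaque class range are never removed.
2. **Brightness reduction** (`reduce_brightness()`): the value channel is
   *clamped* at `T = 230` (`min(V, T)`), not rescaled. Clamping only
   alters specular highlights and glare, and it is idempotent; rescaling
   would shift every pixel and break the palette equalities downstream.
3. **White suppression** (`suppress_white()`): pixels with `S <= s_cut`
   and `V >= v_cut` are clean enamel; they are set to canonical white and
   masked. The cuts either come from annotated statistics
   (`s_avg + k_s * s_sd`, `v_avg - k_v * v_sd`) or are given explicitly.
   The default `v_cut = 225` sits below the brightness cap on purpose —
   the cap runs first, so a cut above `T` could never fire.
4. **Color normalization** (`normalize_colors()`): each remaining pixel is
   tested against the three class hue/saturation/value ranges and snapped
   to the class triple. Where ranges overlap, the clinically more severe
   class wins (over-mature > mature > new), because under-reporting
   mineralizing plaque is the costlier error. Everything unmatched becomes
   sentinel. The operation is a projection: applying it twice is a no-op.

Range and threshold statistics can also be *learned* from annotated
samples with `build_profile()`, which pools pixel statistics across
images (pixel-level averaging is the default: images contribute in
proportion to their annotated area, so a nearly unannotated image cannot
dominate the estimate).

# Segmentation and boxes

`extract_class_masks()` recovers per-class logical masks by exact palette
equality (it refuses un-normalized input). `masks_to_boxes()` labels
connected components with a run-based union–find labeler (4- or
8-connectivity), drops components below `min_area_px` (default 25 px,
speckle noise), and emits YOLO-convention boxes: normalized
`cx cy w h` with pixel extents counted inclusively
(`w = cmax - cmin + 1`). Class ids are 0 = new, 1 = mature,
2 = over-mature.

# Detection scoring

`match_detections()` performs class-aware greedy matching: detections in
descending confidence order each claim the unmatched ground-truth box of
highest IoU, provided IoU ≥ 0.5 (inclusive). Edge conventions: zero
predictions give precision 1.0 (no false alarms were raised); zero ground
truths give recall 0.0 with a warning. PR curves re-match at every
distinct confidence threshold, and `average_precision()` integrates the
all-point interpolated envelope. `map50()` averages AP over classes that
have at least one ground-truth box — a class absent from the ground truth
carries no evidence either way and must not dilute the mean. Detections
without confidence scores (deterministic segmenters) are treated as full
confidence throughout.

# The O'Leary index

Each tooth contributes four examined surfaces (cervical, middle,
incisal/occlusal, and lingual/vestibular). The index is the affected
percentage,

$$ I_L = 100 \cdot \frac{\mathrm{NAPC}}{\mathrm{NTAE}}, $$

the number of areas with plaque over the number of areas examined.
Severity bins are left-inclusive at the top: Mild `<= 25` < Moderate
`<= 50` < Severe. With the full 12-tooth chart (48 areas), the largest
index still categorized Mild is exactly `100 * 12 / 48 = 25`:

```{r}
teeth <- sprintf("T%02d", 1:12)
pres <- matrix(FALSE, 12, 4); pres[1:12] <- TRUE
compute_index(surface_chart(teeth, pres))
```

`chart_from_masks()` converts pixel masks into a chart by zone coverage:
a surface is marked affected when plaque covers at least `min_coverage`
(default 5%) of its zone, which keeps single-pixel speckle from flipping a
surface.

# Synthetic scenes and exactness

`generate_scene()` renders a stylized mouth — background, lip bands, a
12-tooth grid, and elliptical stain blobs whose HSV colors sit strictly
inside the class ranges. The crucial property is that ground truth is
*analytic*: the renderer and the truth generator share one rasterization
routine (`ellipse_row_extents()`), so at zero noise the pipeline's
recovered masks, boxes, charts and indices equal the generator's truth
exactly, not approximately. Gain and Gaussian noise knobs let tests probe
robustness; `generate_cohort()` draws seeded cohorts with a requested
Mild/Moderate/Severe mix, and `mixup()` / `cutmix()` provide
augmentations with label bookkeeping (CutMix drops a box when more than
80% of it is occluded by the patch).

Limits worth stating: scenes are frontal, axis-aligned, and noise is
i.i.d. Gaussian in RGB — no shadows, wet-surface specularity or occlusion.
The generator validates anatomy (blobs must lie inside the image) but
does not model inter-class mixing within one blob.

# Problem sizes

All shipped tests and examples run on one CPU with no fixtures on disk.
Unit tests use 96–256 px scenes; the round-trip suite uses 50 scenes at
640×640, chosen so the full suite completes in a few minutes while each
blob still spans hundreds of pixels. These sizes are the package's own
test-budget choice; the pipeline itself is size-agnostic and handles
camera-sized inputs (e.g. 1280×1280 in a few seconds).

# Worked example

```{r}
s <- generate_scene(random_scene_spec(seed = 7, k_affected = 6,
                                      width = 256, height = 256))
norm <- rgb_to_hsv(s$image)
norm <- suppress_lips(norm)
norm <- reduce_brightness(norm)
norm <- suppress_white(norm, default_profile())
norm <- normalize_colors(norm, default_profile())
masks <- extract_class_masks(norm)
pred <- do.call(rbind, lapply(masks, masks_to_boxes))
evaluate_detections(list(pred), list(s$gt_boxes))
compute_index(chart_from_masks(masks, s$spec$layout))
```
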