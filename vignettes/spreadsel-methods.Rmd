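---
title: "Metaphase spread selection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaphase spread selection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadsel)
```

## The model

`spreadsel` treats metaphase-spread quality assessment as a per-object
shape-classification problem. The underlying assumptions are those of
routine Giemsa work: chromosome bodies are dark, elongated, roughly
constant-width objects on a light background; a straight chromosome
nearly fills its bounding rectangle once rotated upright; a bent one
does not; two crossing chromosomes produce rows that cut through more
than one body; and debris is either much smaller, much wider, or much
more compact than a chromosome.

The pipeline per image is:

1. **Binarization.** Otsu's threshold maximizes between-class intensity
   variance; the side of the threshold with the *lower mean* is taken as
   foreground, so inverted scans do not silently flip the segmentation.
2. **Components.** Foreground is split into 8-connected components
   (8-connectivity keeps one-pixel-wide diagonal chromosome arms
   connected). Components below `min_object_px` pixels are discarded as
   stain noise.
3. **Orientation.** Each component is rotated so its principal axis
   (eigenvector of the second-order central moment matrix of the mask) is
   vertical, using nearest-neighbor resampling so the mask stays strictly
   binary and the pixel count stays meaningful. If the two principal
   moments agree within 1e-9 there is no defined major axis and no
   rotation is applied.
4. **Features and rule tree.** Shape ratios (documented in
   `?basic_features`, `?relative_features`) feed a fixed four-class rule
   tree (`?classify_object`, `?rule_thresholds`).
5. **Ranking.** Spreads are ordered by their count of individual
   chromosomes with a deterministic tie-break cascade (`?rank_spreads`).

## Why Otsu runs on the original image, not the equalized one

Global histogram equalization is exposed (`equalize()`) and follows the
textbook definition: intensity `v` maps to `round(255 * cdf(v))`. The
pipeline, however, thresholds the *original* image. Equalization is a
monotone remap, so it cannot change which intensity quantile best
separates foreground from background — but it does change the *variance*
Otsu measures. On fields dominated by background (a metaphase spread is
mostly background) equalization stretches the background mode across the
whole intensity range, after which the maximal between-class-variance
split falls inside the background. We observed exactly this failure on
synthetic spreads with pixel noise: segmentation dissolved and class-1
recall fell to zero. Thresholding the original image is invariant to that
pathology and loses nothing, because Otsu only cares about the histogram,
not perceived contrast.

## The thresholds and what they mean

| constant | default | role |
|---|---|---|
| `area_gate` | 0.6784 | rectangle fill above which an object is treated as straight |
| `wrect_lo` | 0.9897 | lower `Wrect_ratio` bound of a straight chromosome |
| `wrect_hi` | 1.5597 | upper `Wrect_ratio` bound; above it: large residue |
| `hi_min` | 0.7507 | `Hi_ratio` below which a non-straight object is residue |
| `wmax_gate` | 2.3453 | `Wmax_ratio` above which it is an overlapping cluster |
| `discard_factor` | 1.5 | `W_i` multiple excluded from the width average |

All are dimensionless ratios; `area_gate` is stored as a fraction and
rendered as a percentage only in reports, which avoids mixed-unit bugs.
Boundary semantics follow the published inequalities literally: strict
`>` at the area gate, inclusive `Wrect_ratio` band, strict `<` for the
residue cutoff, strict `>` for the overlap gate. The source text contains
one sentence that gates the skewed/overlap branch on `Wrect_ratio` where
its flowchart and every surrounding sentence use the area ratio; we
implement the area-ratio reading but expose the alternative through
`rule_thresholds(gate_feature = "wrect_ratio")` rather than resolving the
ambiguity silently.

`W_max` is defined here as the maximum per-row foreground count of the
vertically oriented mask. The original description says only "maximum
object width"; the per-row reading matches how `W_i` (a per-row average)
is defined and is rotation-consistent. Note the consequence: a *bent*
chromosome is an elbow, and a horizontal row cuts an elbow once, so its
widest row stays near the body width. Only genuinely overlapping bodies
— where one row cuts two chromosomes — push `Wmax_ratio` past the gate.
This is the geometric content of the skew/overlap distinction.

The width average `W_avg` is a two-pass estimate: mean `W_i` over
straight candidates, exclusion of objects wider than
`discard_factor ×` that mean, then the final mean over the surviving set
`O_w`. Discarded-but-straight objects still pass through the rule tree,
where `wrect_hi` routes them to Class 4. An image with *no* straight
candidate falls back to the median `W_i` over all objects (flagged
`fallback_used` in every report) so that every image remains rankable.

## Threshold calibration

Each constant was originally chosen as the intercept of two Gaussian
densities fitted to labeled feature samples. `calibrate_threshold()`
reproduces this: sample means and n−1 standard deviations per class, then
the closed-form crossing of the two log-densities (the root of a
quadratic) between the means; equal spreads give the exact midpoint. The
kernel density estimate (Gaussian kernel, Silverman bandwidth) is
attached for visual diagnostics only — thresholds always come from the
Gaussian fits.

One degeneracy deserves a name: if one class's density is much narrower
than the other's and the means are close, the narrow density dominates
the whole interval between the means and *no* crossing lies between them
(both roots sit outside). No single cutoff separates such nested classes,
so `gaussian_intercept()` raises an error instead of returning a
meaningless boundary. For one-sample calibrations a documented quantile
mode (`quantile_threshold()`, mean ± z·sd) is provided.

## The synthetic world

No clinical images are distributed, so validation rests on a generator
(`synth_spec()`, `render_spread()`) whose defaults state one fixed world:

* 512 × 640 px field, background 200, object base intensity 60, additive
  Gaussian noise sd 8 — mid-gray contrast typical of digitized Giemsa.
* 20 straight + 14 bent bodies + 3 clusters of 2–3 fused bodies ≈ the 46
  chromosome complement of a human cell, plus 6 debris objects.
* bodies 8 px wide, 36–90 px long (chromosome lengths span roughly a
  factor of 4); transverse sinusoidal banding with period 7 px and
  contrast 0.35 — the bands exist to exercise thresholding realistically;
  the classifier itself sees only binary masks.
* bent bodies bend 45–90°. The lower bound keeps the elbow's rectangle
  fill below the straight gate (at 45° the fill is ≈ 0.42 for a 60 px
  body, against a gate of 0.6784); no upper bound is needed because an
  elbow's widest row is `w / cos(bend/2) ≤ √2·w`, far below the overlap
  gate of `2.3453·w`.
* cluster bodies cross at 76–90°. A row through two bodies crossing at
  angle γ counts ≈ `2w / cos(γ/2)` pixels; solving
  `2/cos(γ/2) > 2.3453` gives γ > 63°, and 76° leaves more than a pixel
  of margin against resampling jitter.
* debris alternates three shapes aimed at the three residue branches:
  small round blobs (Ø ≈ 6.5 px → `Wrect_ratio < wrect_lo`), thin
  shallow arcs (compact mass → `Hi_ratio < hi_min`), and large roughened
  ellipses (Ø 18–24 px → `Wrect_ratio > wrect_hi`). Blob roughness is
  kept at 0.05 because boundary lobes extend the bounding box and would
  otherwise push a blob's fill below the area gate, into a branch the
  generator does not intend.
* placement is rejection sampling (budget 1000 tries per object) with a
  2 px dilated collision test, so non-cluster components are never
  8-adjacent and noise-free segmentation recovers exactly one component
  per ground-truth record.
* every draw comes from R's RNG seeded from `spec$seed`; the rendered
  output is bit-reproducible.

What this world does *not* contain: uneven illumination, focus blur,
touching (as opposed to crossing) chromosome pairs, nuclei, sister
chromatid structure, or photorealistic banding. A green end-to-end test
therefore establishes that the geometry of the rule tree is implemented
correctly and that the pipeline is stable under additive noise — not
that the published clinical accuracies transfer to real microscopes.
The headline clinical accuracy table of the original study (measured on
192 undeposited patient images) is deliberately not reproduced; the
synthetic per-class agreement floors (≥ 90 % for classes 1–2, ≥ 85 % for
classes 3–4 on 50 noise-free spreads) are its desk-scale stand-in.

## Numerical choices

* Otsu ties broken by the smallest qualifying threshold; constant images
  raise "no separable classes".
* Rotation uses inverse-mapped nearest-neighbor sampling; canvas extents
  use a 1e-7 slack before `ceiling()` so exact 90° rotations do not grow
  by a row of numerical dust. Re-orienting an already vertical object
  changes the angle by under 2°.
* Object ids are assigned in raster order of each component's bounding
  box corner; all coordinates in reports are 0-based, row-major,
  top-left origin.
* Border-touching objects are kept and flagged (`touches_border`), never
  silently dropped.
* The ranking comparator ends with a lexicographic image-id tie-break so
  batch output is a deterministic function of the input set, independent
  of directory listing order.
* The Class-3 tie-break direction is *more is better*, exactly as the
  published workflow instructs (clusters hold chromosomes recoverable by
  manual editing); users who consider this a mistake can flip it with
  `rank_spreads(..., class3_more_better = FALSE)`.

## Known limitations

* No TIFF reader is available in this build's dependency set; TIFF files
  are reported as skipped. PNG, JPEG, uncompressed BMP and PGM/PPM are
  supported, with >8-bit inputs rescaled linearly to [0, 255].
* The classifier is purely geometric: a straight residue of
  chromosome-like width is indistinguishable from a chromosome, and a
  cluster of nearly parallel touching chromosomes can fall below the
  overlap gate.
* `W_avg` estimation degrades on images with very few straight
  chromosomes; the median fallback keeps them classifiable but the
  ratios are then anchored to a less meaningful scale (hence the
  `fallback_used` flag in every report).
* Histogram equalization is global; adaptive/illumination-corrected
  variants are out of scope.
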