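---
title: "Methods: line-scan grain analysis and threshed-panicle compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-scan grain analysis and threshed-panicle compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscan)
```

## The measurement problem

Rice yield is assembled from per-panicle components: the total spikelet
number, the fraction of spikelets that are filled (seed setting rate), grain
dimensions, and grain weight. The practical route to these numbers is to
thresh each panicle and image the loose grains on a conveyor under a
line-scan camera. Two systematic problems stand between the raw images and
trustworthy traits:

1. **Residual spikelets.** A mechanical thresher leaves some spikelets —
   disproportionately the light, unfilled ones — attached to the panicle.
   Every count based only on the threshed grains is therefore biased low,
   and the bias is concentrated in exactly the quantity (unfilled fraction)
   that the seed setting rate needs.
2. **Touching grains.** Even after a vibration feeder spreads the grains,
   some land in contact and merge into single connected regions under any
   threshold, so naive component counting undercounts.

`grainscan` addresses the first problem by *threshed-panicle compensation* —
counting the residual spikelets on an image of the threshed panicle (TPSN)
and adding them to the conveyor count — and the second by an ellipse-gated
area-division rule described below.

## Grain counting pipeline

The conveyor images are strongly bimodal: bright grains on a dark belt. The
pipeline is deliberately classical and deterministic:

1. optional background subtraction (`clamp(image − background, 0, 255)`);
2. fixed-threshold binarization (default gray level 100, configurable);
3. 8-connected component labeling (8-connectivity prevents a grain from
   fragmenting across a diagonal pixel step);
4. impurity removal by area and length–width ratio;
5. an ellipse gate that classifies each surviving region as one *isolated*
   grain or a *touching* blob;
6. counting and per-grain shape measurement.

**Impurity filter.** A region is kept when its area lies in
`[area_min, area_max]` (default 400–12,000 px²) and the length–width ratio
of its second-moment equivalent ellipse lies in `[lwr_min, lwr_max]`
(default 1.0–6.0). The lower area bound is the working part of the filter:
dust and fragments are far smaller than the ≈1,400 px² of a nominal
60 × 30 px grain. The upper bounds are intentionally loose because this
filter runs *before* the isolated/touching split and must not delete merged
blobs of several grains: a flank-to-flank pair has LWR close to 1 and a
four-grain blob can reach ≈6,000 px². Bounds that bracket only a single
plausible grain would silently remove precisely the regions the counting
rule needs.

**Ellipse gate.** For each region the outer contour is fitted with a direct
least-squares conic (the numerically stable partitioned formulation), and
the fit is scored by boundary agreement: the fitted ellipse is sampled at
360 uniform parameter angles and the score is 1000 × the fraction of
samples whose nearest contour point lies within `tol_px` (default 2 px), so
1000 is a perfect match. A region is *isolated* when the fit exists, its
full axes fall inside single-grain ranges (defaults 40–90 px major,
18–45 px minor, scaled from the 60 × 30 px nominal grain), and the score
reaches `min_score` (default 800). Merged blobs fail on one or both
conditions: a side-by-side pair is far too wide for the minor-axis range,
and its waist notches push fitted-boundary samples further than `tol_px`
from the contour. The two conditions are deliberately redundant.

**Counting.** With isolated regions counted directly, each touching region
contributes `area / mean(isolated area)` grain-equivalents; the quotients
are summed over all touching regions and rounded half-up once:

```
total = n_isolated + round( Σ_touching areaᵢ / mean isolated area )
```

Summing before rounding avoids accumulating per-region rounding bias. A
scene with touching regions but no isolated grain is an error (the mean is
undefined) rather than a silent zero. A useful robustness property falls
out of the design: an isolated grain that *fails* the gate (an odd fit, an
extreme size) is counted as a touching region of roughly one grain-area, so
the total is nearly unaffected by borderline gate decisions.

**Shape.** Grain length (GL) is the distance between the two farthest
contour points; grain width (GW) is the maximal perpendicular extent of the
contour about the GL chord (largest excursion on each side, summed).
Integer boundary coordinates lose up to half a pixel per side, which at a
30 px grain width is a 2–3% systematic underestimate, so the measurement
contour is computed at sub-pixel precision: marching squares at iso-level
0.5 on the region mask, then a 9-point circular moving average. The
smoothing matters because GL/GW are *maxima* over contour vertices and the
±0.5 px marching-squares jitter would otherwise bias them upward (an
extreme-value effect). With this contour, recovered GL/GW stay within 2% of
the analytic axes across the generator's grain-size distribution; the
residual error is the irreducible pixelation of a ≈30 px-wide object.
Millimetre values use the instrument pitch, 100 µm/px by default.

## Line-scan stitching

A line-scan camera builds the image row by row while the belt moves, so
consecutive frame buffers abut exactly; a grain crossing a buffer boundary
appears split across two frames. Stitching is vertical concatenation in
acquisition order — nothing more — because whole-composite labeling then
reconnects every split region by construction. The package verifies this
property against a single-canvas oracle rendering in its tests rather than
estimating any inter-frame registration; a `overlap_rows` option exists for
hardware that emits overlapping buffers (default 0).

## Detector building blocks

The threshed-panicle detector that motivates this package is a two-stage
region-proposal network tuned for small objects; its paper-accuracy
training needs a GPU-scale annotated dataset and is out of scope here. What
the package provides are the independently verifiable operators, each
checked against a naive oracle:

* **Anchors**: the cross product of area scales {32², 64², 128²} — sized
  for a ≈30 × 60 px grain rather than the generic {128², 256², 512²} — and
  ratios {1:1, 1:2, 2:1}, nine per feature-map cell, centred on cell
  centres; sides `w = round(√(scale/ratio))`, `h = round(w·ratio)`.
* **RoIAlign**: each output bin averages `s²` bilinearly interpolated
  samples at exact sub-pixel locations (value (r, c) at continuous
  (c−0.5, r−0.5), border-clamped); no coordinate is ever rounded. This is
  the operator that removes the box-placement error that quantised pooling
  introduces for small, close-packed objects.
* **Squeeze-and-excitation**: the per-channel squeeze merges global average
  and global max pooling — elementwise sum by default, concatenation as an
  option — followed by a two-layer bottleneck (`relu`, then `sigmoid`)
  producing one gate per channel in (0, 1). Defaults: reduction ratio 16,
  leaky-rectifier slope 0.1 where a CBL block is assembled.
* **NMS** (greedy, descending score, deterministic ties by x₀ then y₀) and
  **TPSN counting** (detections with score ≥ 0.5 after NMS).

Any `function(image) → detections` can back the pipeline; the packaged
classical fallback emits every region that passes the single-grain ellipse
gate as a score-1.0 box, so the end-to-end system runs without trained
weights. On dense panicles it is, by design, far weaker than a trained
detector — grains fused with the rachis are not isolated regions — which is
the very reason the original system uses a learned model; the fallback's
role is to exercise the interface and the compensation arithmetic.

## Metrics

Detection quality uses precision, recall, F1 and average precision with a
0.5 IoU positive threshold. AP is computed by all-points rectangle
integration of the precision–recall curve (the direct discretisation of
∫P(r)dr), not the 11-point interpolation; an interpolated-precision variant
is available behind a flag since published curves do not always state their
convention. Greedy score-ordered matching is prefix-consistent, so one
cumulative pass equals exhaustive per-cutoff re-matching; the tests assert
this against an enumeration oracle at 1e−9.

Agreement between system and manual measurements reports the
scatter-ratio form `R² = Σ(Xₐᵢ−X̄ₘ)² / Σ(Xₘᵢ−X̄ₘ)²` exactly as printed in
the source literature for this instrument class. That form is *not* the
standard coefficient of determination — it can exceed 1 when the system
values spread more than the manual ones — so the squared Pearson
correlation is always reported alongside, clearly labelled. MAPE is
reported both as a fraction and ×100; any zero manual value makes MAPE
undefined and raises an error rather than returning 0.

## The synthetic generator and what it does (not) show

Every stage is tested against scenes with exact ground truth. The generator
renders grains as flat-intensity ellipses (levels 180 on 20, Gaussian noise
σ = 5) because the pipeline's fixed threshold only requires bimodality; it
does not emulate shading gradients, awns, curved spikelets, husk texture,
or the real instrument's background, so green tests demonstrate the
*arithmetic and geometry* of the pipeline, not its robustness to real
imaging conditions. Axis lengths are drawn from N(60, 4) × N(30, 2) px
(major × minor), matching the nominal grain at the 100 µm pitch.

Touching clusters place members flank to flank: parallel orientations,
centres offset along the shared minor axis by 0.7–0.9 × the sum of the two
semi-minor axes. This guarantees that members merge into one connected
component (the dichotomy the classifier assumes) at the cost of a physical
impossibility: real grains abut, synthetic ones interpenetrate. The lens of
overlap removes a measured 0.12 ± 0.13 grain-equivalents of area per
touching pair, which is the dominant error source of the area-division
count on synthetic scenes — a *negative* bias of about one grain per eight
touching pairs, to which the grain-size spread adds ≈0.13 grains of noise
per pair. Isolated-only scenes are counted exactly for every seed.

The counting battery (`evaluate_counting_recovery()`) fixes the study
conditions: 50 scenes of 1024 × 1024 px (two stitched 512-row frames; half
the width of the full 2,048 px sensor at unchanged grain scale and
density), 10–24 isolated grains, 0–4 impurities, and a cluster load of
0/0/1/1/2 clusters cycling across scenes with sizes 2–4 weighted
0.6/0.3/0.1 — a vibration-fed belt mostly yields pairwise contacts. Under
these conditions the battery recovers the exact total in ≈92–100% of
scenes depending on the master seed (98% at seed 1) and is never off by
more than ±1; the miss rate is attributable to the overlap bias above, not
to misclassification, which the per-scene diagnostics in the battery's
output make easy to confirm.

## Numerical and interface choices

* Coordinates are 0-based, origin top-left; boxes half-open
  `[x0, x1) × [y0, y1)`. On disk, PASCAL VOC XML uses the conventional
  1-based inclusive corners (`xmin = x0 + 1`, `xmax = x1`); the round trip
  is exact.
* One RNG stream per scene, seeded in the `scene_spec`; generation
  restores the caller's RNG state, and identical specs give bit-identical
  frames and annotations.
* Degenerate inputs fail loudly: infeasible packing, empty frame
  sequences, mismatched widths, boxes outside the image, touching regions
  without an isolated reference area, zero manual measurements in MAPE,
  constant manual vectors in R².
* Undefined statistics (precision with no detections, thousand-grain
  weight with zero filled grains) are reported as missing values, never
  as 0.
* Ellipse-fit failures return `NULL`; set `options(grainscan.verbose =
  TRUE)` to log the reason (short contour, degenerate conic, axes outside
  the single-grain ranges).
* The seed setting rate is computed against the compensated total; the
  uncompensated variant is reported alongside in every trait record so the
  effect of compensation is visible per panicle.

## Known limitations

* The classical fallback detector cannot separate grains that touch the
  rachis; realistic TPSN extraction requires plugging in a trained model
  through the detector interface.
* Counting on scenes with many touching pairs carries the systematic
  overlap deficit described above; it is a property of the synthetic
  contact model, and on real imagery the analogous error source is instead
  the under-segmentation of tightly packed grains.
* Default thresholds (gray level 100, area/LWR bounds, axis ranges) are
  calibrated to the synthetic generator's contrast and grain scale and
  must be re-tuned for a physical instrument.
* Watershed-style splitting of touching grains is intentionally absent:
  the counting rule divides area rather than instanced grains, so per-grain
  shape is only measured on isolated grains.
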