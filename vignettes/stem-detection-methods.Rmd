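---
title: "Stem detection and diameter estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem detection and diameter estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemyield)
```

## The measurement problem

A depth camera mounted on a harvester looks sideways and upward at a row
of willow stems from about 1.22 m away, tilted 28.5° above the ground
plane. Each frame supplies two aligned rasters: an 8-bit grayscale image
and a depth map in raw units (here 1 unit = 1 mm; zero encodes a failed
stereo match). The quantities of interest per frame are the number of
stems and each stem's diameter where it crosses the bottom image row. The
pipeline is classical computer vision throughout — masks, histograms,
flood fill, contours — chosen so it can run on embedded hardware; there is
no learned component.

Two geometric facts carry the whole measurement:

* **The tilted threshold plane.** Rays through higher image rows travel
  farther before reaching the vertical plane that contains the row. With
  the bottom-row cutoff anchored at 1.23 m (the row centre), equal height
  steps up the row plane between the bottom-ray and top-ray intersections
  give each row's cutoff as the hypotenuse from the camera centre. With
  the default optics (58° vertical FOV, 28.5° tilt) the top-row cutoff
  computes to ≈2.29 m. Anything beyond the plane is background and is
  discarded before any intensity analysis.
* **The pixel–millimetre ratio.** At distance $D$ mm, half the frame
  width spans $\tan(\mathrm{FOV}_x/2)\,D$ mm across $W/2$ pixels, so one
  pixel is worth $r(D) = \tan(\mathrm{FOV}_x/2)\,D/(W/2)$ mm
  (≈1.82 mm/px at 1.28 m for the default 87° × 1280 px optics). A stem's
  diameter is its bottom-row pixel width times $r$ at its measured depth.
  The quantization floor of the whole system is therefore $\pm r/2$ per
  edge, about ±1–2 mm at row distance.

## Parameters

| stage | parameter | default | meaning |
|---|---|---|---|
| depth filter | `median_kernel` | 5 | square median window, px |
| CLAHE | `clip_limit` | 40 | relative per-tile histogram clip |
| CLAHE | `tiles` | 8 | tile grid per side |
| histogram | `peak_range` | 50 | candidate band width around the peak, bins |
| histogram | `low_limit` | 10 | lowest admissible intensity bin |
| histogram | `count_difference` | 50 | allowed drop below peak count (0–255 normalized) |
| flood fill | `lowdiff` / `updiff` | 10 / 30 | band below/above the seed intensity |
| flood fill | `connectivity` | 4 | pixel adjacency |
| detection | `close_kernel` | 15×2 | upright closing rectangle, rows×cols |
| detection | `min_area` | 600 | minimum filled contour area, px² |

`low_limit` and `count_difference` have no published reference values;
they are deliberately explicit, mandatory entries in the configuration so
that every run records what was used. The histogram can be computed over
the whole equalized frame or only over depth-mask pixels
(`histogram_scope`, default `"masked"`); masking is what makes the stem
intensity spike dominant, and the switch exists because the alternative
reading is defensible.

## What the synthetic scenes emulate — and why they look the way they do

`generate_scene()` renders: vertical stems spanning the full frame height
at row depth (1.22 m ± 3 mm), with bottom-row pixel width set to the
*exact inverse* of the measurement chain (`round(diameter / r(depth))`) so
ground truth and estimate share one geometry; slanted branch clutter at
stem-like depth and intensity (the designated false-positive source);
a horizontal illumination gradient and optional saturated patches;
Gaussian depth noise and dropout zeros. Everything is deterministic per
seed.

The intensity model deserves explanation, because it is where adaptive
equalization bites. Histogram equalization is rank-based: it allocates
output range in proportion to pixel mass. A stem that occupies fraction
$f$ of its CLAHE tile is therefore stretched over $\approx f \cdot 255$
output levels *no matter how flat its bark texture is* — only the
distribution of stem pixels across that band is controllable. Three
consequences shaped the generator defaults:

* **Uniform bark texture (±20 intensity).** A flat texture distribution
  makes the equalized stem histogram flat, so the dynamic threshold admits
  essentially the whole stem band and nearly every stem pixel can seed its
  own flood. Gaussian or very low-amplitude textures concentrate the
  equalized mass into a few widely spaced levels, the fixed flood band
  cannot span them, and the fill fragments — reproducing the "skeletal
  contour" failure mode this class of pipeline is known for.
* **Dappled deep shadow (12% of background, mean 25).** A dark population
  present in every tile anchors the stems' equalized band at a consistent
  rank just above the seed `low_limit`, in stem-free and stem-bearing
  tiles alike. Without it, the stem band's position swings from tile to
  tile and the asymmetric flood band (−10/+30) misses it.
* **Per-stem shade jitter.** Stems of visibly different shade in the same
  tile equalize to different bands, and the dimmer band captures the
  range. Clean scenes use ±1 (uniform bark); the paper-like and stress
  presets raise it to ±5 and ±8 — it is the principal difficulty dial.

The presets define the study conditions: `clean` (no clutter, no noise),
`paper_like` (≈4 branches/frame, gradient amplitude 30, 30% chance of a
saturated patch, depth noise σ = 10 raw units, 5% dropout, shade jitter
±5), and `stress` (heavier everything, plus one stem per suite whose
depth is dropped over the bottom 80 rows with a small halo past its edges,
as stereo failure around occlusions behaves, forcing the frame-median
depth fallback).

What the generator does **not** model: leaf canopy and occlusion, lens
distortion, smooth radial shading on cylindrical stems, spatially
correlated shadow blobs, motion blur, and stems leaning or curving within
the frame. Passing the synthetic suites therefore demonstrates that the
implementation is faithful and self-consistent and that the method behaves
as designed under its own assumptions — not that field accuracy would
match; on real recordings this class of pipeline reports markedly higher
diameter error.

## Numerical choices

* **Histogram normalization** is min–max to 0–255; the intensity-list
  test is *strictly greater than* `255 − count_difference`. Peak ties go
  to the lowest intensity.
* **Flood fill** always compares against the original seed's intensity
  (fixed-range), not the growing region; seeds already inside the mask are
  skipped without flooding, so the final mask is order-dependent by
  design — determinism comes from the row-major seed ordering.
* **Closing** uses OpenCV-style anchors (`floor(k/2)`); out-of-frame
  pixels count as background for dilation and foreground for erosion, so
  closing never erodes at the frame border and bottom-row contact
  survives. Even kernel widths shift the result one column, as they do in
  the reference implementations.
* **The threshold plane** acquires a running maximum from the bottom row
  upward: when the tilt is smaller than half the vertical FOV the lowest
  rays dip below horizontal and the raw hypotenuse has a sub-0.1 mm
  minimum a few rows above the bottom; the correction enforces the
  documented monotone profile and is orders of magnitude below measurement
  resolution.
* **Bottom-row runs**: the trimmed row is split at every interior gap
  (equivalently, all maximal solid runs are enumerated); the widest run is
  the stem, the leftmost wins ties. This generalizes the single split of
  the original description and coincides with it when there is one gap.
* **Medians** over even counts average the two middle values and round to
  the nearest integer depth unit. Zeros never enter a depth median; a span
  with no valid depth takes the median depth of the frame's other trees,
  and if no tree has depth, the row-centre distance (1.23 m) in raw units.
* **Contour area** is the filled pixel count, not a boundary-polygon
  area — for 1–2 px wide shapes polygon area underestimates badly.
  Components are 8-connected. Fragmented stems are *not* regrouped,
  faithfully to the original design.
* **Degenerate inputs**: an empty depth mask yields an empty intensity
  list, zero seeds and an empty segmentation (no error); zero pixel width
  or zero depth yield a zero diameter.

## Problem sizes

The test suite exercises every operator against brute-force oracles on
frames up to 32×32 (exhaustive, seconds), and the full pipeline at the
native 1280×720 resolution: 100 clean frames (800 stems) for parameter
recovery, 5 paper-like frames (40 stems, mirroring a 40-tree field
validation design) for degradation behaviour, and 25 depth-noise frames
(200 stems) for the noise-robustness bound. The acceptance script re-runs
the two study suites at the same sizes. A full run of the suite takes a
few minutes on one core.

## Known limitations

* Diameter is measured at the bottom image row only; no height remapping
  is applied, so comparisons against callipering at a different stem
  height inherit that offset.
* Overlapping frames are not deduplicated: a stem seen in consecutive
  frames is counted twice in the transect. The transect is a per-frame
  count sequence, not a spatial interpolation.
* The flood-fill parameters are constants; scenes whose equalized stem
  band exceeds `lowdiff + updiff` (wide stems crossing several tiles, or
  strongly shade-jittered stems) fragment and under-measure. This is a
  property of the method, reproduced deliberately.
* Frame and GPS clocks are assumed synchronous up to a constant,
  user-supplied offset.
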