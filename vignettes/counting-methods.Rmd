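---
title: "Counting leaf epidermal cells from contact micrographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting leaf epidermal cells from contact micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicount)
```

## The imaging model

A fresh leaf pressed between two glass slides keeps its epidermal cells
turgid; each cell's convex outer surface touches the upper slide over a
small *contact footprint*. Imaged under incident light with the focal
plane at the glass, those footprints are the only in-focus structures:
compact, roughly convex patches separated by a contrasting inter-cell
phase. Counting cells reduces to counting footprints.

`count_cells()` implements a six-stage deterministic pipeline over such
micrographs. Everything downstream of loading operates on 8-bit
intensities in a plain R matrix, indexed 1-based as `(row, col)` with the
origin at the top-left pixel — the package's single fixed raster
convention, used for marker coordinates, ground truth, and overlays alike.

## Parameter scaling

Five operator parameters drive the pipeline, all derived by
`derive_params()` from the pixel size $x$ (µm/pixel) so that each
corresponds to a fixed physical length on the leaf:

| parameter           | rule (px or iterations) | physical scale | role |
|---------------------|-------------------------|----------------|------|
| `sigma_px`          | $1/x$                   | 1 µm           | Gaussian smoothing |
| `erode_iterations`  | $1.25/x$                | 1.25 µm        | peel footprint rims |
| `open_iterations`   | $2.5/x$                 | 2.5 µm         | break inter-footprint necks |
| `noise_tolerance`   | $1.75/x$ (round)        | 1.75 µm        | merge spurious maxima |
|                     | $4.75/x$ (bottleneck)   | 4.75 µm        | merge the two lobes of a waisted footprint |

Values are rounded to the nearest integer with ties rounded **half away
from zero** (`round_half_away`): base R's round-half-even would be equally
able to reproduce the published example sets (neither printed example hits
a tie), but one convention has to be fixed and tested; half-away matches
the everyday reading of "nearest integer". Any value that would round to 0
(pixel sizes coarser than ~2 µm/px) is clamped to 1 with a warning, since
every operator needs a positive parameter. The shape class is declared by
the user — there is no quantitative criterion for "round" vs "bottleneck"
footprints beyond visual inspection, so the package does not guess.

## Stage-by-stage numerical choices

**Red channel.** RGB input is reduced to its red plane; single-channel
input passes through with a message. Images with alpha or extra channels
are rejected rather than silently flattened.

**Gaussian blur.** Separable convolution with kernel half-width
$\lceil 3.5\sigma \rceil$, implemented as banded sparse row/column
operators. At the border the truncated kernel is renormalised (no padding
bias), which preserves the image mean to within one intensity level; the
result is re-quantized to 8-bit (half away from zero). This is deliberately
not delegated to a library blur, whose boundary conventions differ.

**Minimum-method threshold.** The 256-bin histogram of the *blurred* image
is smoothed with a 3-bin moving average (edges replicated) until exactly
two strict interior local maxima remain, then cut at the first valley bin
$t$ between the peaks with $h_{t-1} > h_t$ and $h_{t+1} \ge h_t$.
Histograms that never become bimodal within 10,000 smoothing passes
(uniform or single-mode images) raise a "threshold not found" error naming
the source image — a featureless micrograph is a data problem, not a count
of zero. By default the **dark** side of the threshold is foreground;
whether contact footprints image dark or bright depends on the illumination
geometry and is not knowable a priori, so `polarity` is an explicit flag,
and `polarity = "bright"` is the first knob to try if counts are grossly
wrong on real imagery.

**Morphology.** Counted-neighbour binary operators: with quota
`neighbor_count = c`, erosion removes a foreground pixel with ≥ c
background 8-neighbours, dilation is the dual, and opening is n erosion
passes followed by n dilation passes. The default c = 1 gives classical
3×3 box operations. Pixels outside the raster count as background for
*both* operations — the simplest consistent convention; any divergence
from edge special-casing in other tools is confined to a border band
`iterations` pixels wide.

**Distance map.** Exact Euclidean distance to the nearest background
pixel, with outside-the-raster again counting as background (enforced by
computing the transform on a one-pixel background-padded copy). The
`strict_imagej_edm` flag additionally rounds distances half-away to
integers and clips at 255, emulating pipelines that store the distance map
as an 8-bit image; quantization is a storage artifact, not part of the
method, so the exact map is the default. Both behaviours are first-class
and tested.

**Maxima detection.** Candidates are positive pixels ≥ all 8 neighbours,
processed in descending value (ties: smaller row, then column). Each
unclaimed candidate of height $v$ flood-fills the 8-connected region of
positive pixels above $v - \text{tolerance}$; reaching previously claimed
territory merges the candidate into that maximum (no marker), otherwise it
is accepted. Because background is never claimed, separate blobs can never
merge — the tolerance only fuses peaks *within* a blob, which is exactly
what makes one waisted bottleneck footprint count as one cell. Equal-valued
plateaus (common on quantized distance maps) yield a single marker at the
plateau pixel nearest the plateau centroid, ties again by smaller row then
column. Every rule here is a determinism choice: identical input and
parameters give bit-identical results, which the test suite asserts.

Edge-touching maxima are *kept* by default (`exclude_edge_maxima = FALSE`):
cells cut by the image border are counted, consistent with treating the
small automatic-vs-manual discrepancy on real imagery as a border-handling
difference. The flag drops maxima whose claimed region touches the border
for users who prefer the other convention.

## The synthetic scene generator

`generate_scene()` renders what the optics deliver, not the whole leaf: it
places non-overlapping convex footprints (round: ellipses with axis ratio
0.8–1.25; bottleneck: two overlapping equal lobes whose waist width is
40–60% of the lobe width) by rejection sampling with a capped attempt
budget (100 × n; saturation returns fewer cells with a warning), renders
them with a ~1.5 px linear edge ramp at the footprint level over the
background level, adds Gaussian sensor noise, and quantizes to 8-bit. A
single seed drives all randomness; the caller's RNG state is saved and
restored.

Default conditions — 800 × 800 px at 0.5 µm/px (a 0.16 mm² FOV), 100 round
footprints, dark footprints (60) on a brighter surround (160), noise SD 8 —
put the scene in the density regime of real epidermis micrographs
(hundreds of cells/mm², mean spacing ~40 µm, footprint spacing comparable
to the published example imagery). Two geometric constraints are derived
from the method itself and fix the footprint-size defaults:

* **Erosion-scale visibility.** The pipeline erodes every footprint by
  1.25 + 2.5 = 3.75 µm — up to $\sqrt 2$ more along diagonals, because the
  structuring element is a square. A footprint whose minimum half-width is
  below that scale is erased by the opening stage and invisible *by
  construction*. The method is validated on imagery where every contact
  patch is comfortably resolvable, so the round default (radius
  10 ± 0.5 µm, truncated at ±3σ, minimum semi-axis ≥ 0.8 × radius) keeps
  every footprint above the erosion scale.
* **Saddle depth vs merging tolerance.** For a bottleneck footprint to
  count as one cell, the distance-map saddle at its waist must lie within
  the 4.75 µm bottleneck tolerance of the lobe peaks; the saddle depth is
  approximately $(1 - w)\,r$ for waist fraction $w$ and lobe radius $r$.
  The lobe default 9 ± 0.5 µm keeps that depth below the tolerance across
  the specified waist range. Lobed cells whose waists sit near the
  tolerance boundary are genuinely ambiguous to this method — the
  generator does not hide that, and waist fractions near 0.4 with
  unfavourable (diagonal) orientation remain the hardest case.

What the generator does **not** emulate: optical point-spread blur, uneven
illumination, veins and trichomes, footprints cut by the image border
(placement keeps footprints fully inside), debris, or chromatic structure
(scenes are rendered as a single channel; the pipeline's red-extraction
step is exercised by RGB unit fixtures). Passing the synthetic recovery suite therefore demonstrates the
correctness and stability of the *algorithmic chain*, not robustness to
every nuisance of real microscopy; the published-image comparison (below)
covers the latter and requires the original supplementary micrographs.

## Validation utilities

`match_markers()` formalizes "the automatic markers are the same cells as
the manual ones" as greedy one-to-one nearest-pair matching under a
distance cap, reported as precision/recall plus count errors. A
scale-aware default cap is the mean footprint radius (synthetic) or
$0.5\sqrt{\text{mean cell size}}$ in pixels (real images). Matching is
symmetric: swapping the two sets swaps precision and recall, which the
tests assert. `density_and_size()` computes cells/mm² and µm²/cell from
the raster geometry; the two are exact reciprocals through 10⁶ µm²/mm²,
and a zero count reports density 0 with the mean size missing rather than
an error.

## Problem sizes and test design

The test suite regenerates every fixture from code. Operator correctness
is established against independent brute-force oracles (per-pixel loops
for morphology, all-pairs scans for the distance transform, exhaustive
smoothing/valley search for the threshold, threshold-connectivity checks
for maxima merging) on 32 × 32 random masks and constructed two-peak
height maps — sizes where exhaustive computation is trivially correct.
End-to-end recovery runs 20 seeded default scenes (800 × 800 px, 100 cells
each) plus the noiseless limit, which must be counted exactly; these sizes
keep the full suite around a minute on one core while matching the density
regime of real data. The comparison against the published validation
micrographs and their counts (125, 49, 45) runs whenever those files are
placed under `inst/extdata/supplementary/`; closest agreement should be
sought with the default configuration first, then under
`strict_imagej_edm` and the opposite `polarity`.

## Known limitations

* The shape class (and hence the 1.75 vs 4.75 µm tolerance) is a user
  declaration, not an inference.
* Footprint polarity (dark vs bright) must be confirmed visually once per
  acquisition setup.
* Bottleneck footprints with waists near the merging-tolerance boundary
  can split into two markers, and the square structuring element makes
  the outcome mildly orientation-dependent.
* Cells whose contact patch is narrower than the ~3.75–5.3 µm erosion
  scale are invisible to the method at any resolution.
* The pipeline counts footprints; it does not segment cell outlines or
  measure per-cell areas — mean cell size is FOV area over count.
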