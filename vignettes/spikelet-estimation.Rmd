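---
title: "Estimating spikelet number per panicle from low-resolution scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spikelet number per panicle from low-resolution scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paniclescan)
```

## The measurement problem

Spikelet number per panicle (SNPP) is a core yield component of rice, and
the hardest one to count: a mature panicle can carry well over 200
spikelets on a dozen primary branches. Image-based counting of individual
spikelets needs high-resolution images of panicles whose every grain has
been spread apart, because grains and branches live at very different
spatial scales. `paniclescan` takes the opposite route: at a low scanner
resolution (nominally 72 dpi, where one pixel is 2.54/72 cm ≈ 0.35 mm) it
measures *branch-level* traits that are cheap to extract, and converts
them to SNPP through a linear model, exploiting the physiology of the
panicle rather than fighting the resolution.

Two traits are used, both computed from the segmented primary-branch
regions:

* **area** — the number of pixels in all branch regions. Because grain
  size and filling are approximately uniform within a variety, the
  silhouette area of a spikelet-covered branch grows proportionally with
  the number of spikelets on it.
* **TLPB2** — the total length of the primary branches. Each region's
  length proxy (PBL2) is the major-axis length of the ellipse with the
  same normalized second central moments as the region; TLPB2 is the sum
  over regions. Spikelets sit at a roughly constant linear density along
  a branch, so total branch length also scales with SNPP.

Either trait `x` maps to a count through `SNPP = a·x + b`, fitted by
ordinary least squares.

## The segmentation pipeline

A scan is a dark panicle on a light background. The pipeline is fixed, in
this order:

1. **Grayscale** by the unweighted channel mean `(R+G+B)/3`, rounded
   half-up. The unweighted mean is deliberate (not luminance weights):
   contrast is strong in all channels and the arithmetic is exactly
   reproducible.
2. **Otsu threshold** on the 256-bin histogram; the threshold maximises
   the between-class variance, and among (numerically) tied maximisers
   the smallest is taken — thresholds inside a histogram gap describe the
   same split, so the tie-break only fixes a convention.
3. **Binarization**, by default `dark_foreground` (pixels `≤ t`). An
   `auto` polarity (minority class is foreground) is available for
   inverted scans.
4. **Morphological opening** with a disk of radius 1 — the 3×3 diamond
   (centre plus 4-neighbours). This is the step that gives the method its
   structure: the rachis and the pedicels are 1–2 px wide at 72 dpi and
   vanish under the opening, while the spikelet-covered branches are an
   order of magnitude wider and survive. What remains is one region per
   primary branch. A radius-1 disk is the smallest non-trivial disk; the
   radius is exposed for other resolutions.
5. **Hole filling**: every background component not 4-connected to the
   image border becomes foreground (reconstruction from a border marker).
   Touching spikelets and awns enclose small holes that would otherwise
   bias the area trait.
6. **Small-component removal**: 8-connected components with strictly
   fewer than 100 pixels are deleted (dust, detached fragments). The
   cutoff is strict (`< 100`; a 100-px component is kept).
7. **Labelling** of the surviving 8-connected components, in raster-scan
   order of first pixel.

Conventions worth stating once: foreground uses 8-connectivity and
background (holes) 4-connectivity — the standard dual pair; rasters are
row-major with origin at the top-left; all intermediate stages are plain
matrices and can be inspected via the `debug` flag of
`extract_branch_regions()`, including the classical extraction-check
overlay `b − b·(−f)` of the raw binary image `b` against the final mask
`f`.

## Trait measurement

The region area is the exact pixel count. The length proxy is the
moment-equivalent-ellipse major axis: with area-normalized central
moments `uxx`, `uyy`, `uxy`,

```
PBL2 = 2·sqrt(2) · sqrt( uxx + uyy + sqrt((uxx − uyy)² + 4·uxy²) ).
```

Each diagonal moment is augmented by 1/12, the variance of a unit pixel.
This correction matches the convention of the classical region-properties
tools, makes a single pixel read ≈ 1.1547 rather than 0, and makes the
digitized measurement track the continuum value (a digitized ellipse with
semi-axes `a ≥ b ≥ 3.5` px reads within 2% of `2a`). Purists can disable
it with `pixel_correction = FALSE`.

Note a property of this definition that matters for interpretation: the
moment-ellipse length of a *mass-uniform* bar of length `L` is
`2·sqrt(2)·sqrt(L²/6)` ≈ 1.155·L, while a region whose mass tapers like an
ellipse reads exactly `L`. Real spikelet-covered branches taper towards
the tip, so the convention is well matched to the organ being measured;
the residual scale factor is absorbed by the calibration slope in any
case (which is also why calibration operates on raw pixel traits — units
cancel in the linear model; lengths are additionally reported in cm via
`cm = px·2.54/dpi`).

A thinning-based skeleton with junction/terminal vertices
(`skeleton_vertices()`, Zhang–Suen thinning; terminal = skeleton pixel
with one 8-neighbour, junction = three or more) is provided as an
architectural diagnostic; it plays no role in the SNPP estimate.

## Calibration

The linear model can be fitted two ways:

* **80/20 split** (`split_80_20`): fit on a random 80% of the labelled
  panicles, evaluate on the rest. The split seed is recorded in the
  model.
* **5-point calibration** (`five_point`, the default): fit on five
  panicles chosen *uniformly across the trait scale* — for each target
  value `min + j·(max−min)/4`, `j = 0..4`, the unused sample nearest the
  target is taken (ties to the lower value). The first and last targets
  are the extremes, so the model never extrapolates over its training
  range. Five manual counts are all that is needed to port the method to
  a new variety or site.

"Uniformly" is read as value-uniform rather than rank-uniform: the
quantity that controls leverage in a straight-line fit is the spread of
trait values, not of ranks. Both alternatives (and a random baseline) are
available via the `strategy` argument for methodological comparison.

Predictions are floored at zero and left real-valued by default; mean
spikelet numbers are compared unrounded, and a `round` flag exists
because counts are integers.

Two statistics summarise accuracy, and they are deliberately different in
kind:

* per-panicle **estimation error** (absolute, percent):
  `|SNPP(cal) − SNPP(manual)| / SNPP(manual) × 100`, summarised as the
  fraction of panicles below 5% and 10% error;
* **SNPS deviation** (signed, percent): the spikelet number per unit
  field area is estimated by averaging SNPPs, so the relevant error is
  the signed relative difference of the *means*,
  `(mean(cal) − mean(true)) / mean(true) × 100` — a ratio of means, not a
  mean of ratios.

`evaluate_model()` refuses any overlap between the calibration panicles
and the evaluation set: samples used to establish a model never enter its
error statistics.

## The synthetic generator

No public scan set accompanies the method, so the package carries a
generator (`generate_panicle()`, `generate_variety()`) that renders
panicle-like scans with exact ground truth; every end-to-end claim in the
test suite is made against it.

What it emulates: a thin, slightly swaying rachis; 5–15 primary branches,
each a gently curved axis (branches on a scanner cannot be straightened
perfectly) in its own lane; spikelets as filled ellipses centred on the
axis at a per-branch linear density with 7% coefficient of variation;
near-constant spikelet size within a variety (one minor semi-axis per
variety, ±1% per panicle), reflecting the uniform-grain assumption; a
dark foreground (60) on light background (230) with additive Gaussian
channel noise (sd 6); and lognormal spikelet numbers across a variety
(sdlog 0.18). At the variety level, total branch length is derived from
the target spikelet number at the variety's density — the physiological
premise that makes the linear model work. Default geometry at 72 dpi:
spikelet minor semi-axis 4.2–5.0 px, aspect ratio 2.2 (≈ a 7 × 3 mm
grain), branch lengths 100–400 px, rachis width 2 px.

Two generator choices are design decisions rather than attempts at
realism:

* **Spikelet size tapers along the branch** following a semi-elliptic
  profile (widest mid-branch). This gives each branch region the
  ellipse-like mass profile under which the moment-length convention
  reads the true arc length (see above); with uniform spikelet sizes the
  length trait would read a systematic ~15% high, which calibration
  would absorb but which would decouple the generator's ground-truth
  length from the measured TLPB2.
* **A 3-px axis stroke bridges consecutive spikelets**, so a branch
  survives the opening as one connected region even where the sampled
  spacing exceeds the spikelet length, while the 1-px pedicel stem
  joining branch to rachis is removed by it — mirroring how real branch
  silhouettes behave under the same operation.

What it does **not** emulate: awns, colour variation and shading,
overlapping or adhering branches, curled branch tips, soil or chaff
debris. Adhesion is exactly the failure mode that degrades TLPB2 (but not
area) on real scans, so passing tests here demonstrate correctness of the
pipeline and the calibration machinery, not robustness to badly spread
panicles. Generator constants are synthetic and are not calibrated to any
real variety.

## Numerical choices and degenerate inputs

* Grayscale rounding is half-up (`floor(x + 0.5)`).
* A constant image has no Otsu threshold; segmentation reports "no
  panicle detected" (the blank-scanner case).
* Opening of a radius-`r` disk is applied as `r` passes of the 3×3
  diamond (the disk is the `r`-fold Minkowski sum of the diamond), each
  pass four vectorized matrix shifts; outside the image counts as
  background.
* Component labelling is run-length based (per-row runs merged by
  union-find), so its cost scales with the number of runs.
* The empty mask is legal everywhere except `measure_panicle()` (no
  regions) and `region_area`/`region_major_axis` (empty region).
* 5-point selection with a zero trait range, OLS with a constant trait,
  and evaluation with zero manual counts are all errors, not warnings.

## Problem sizes

The shipped evaluation study (`simulation_study()`, also what
`scripts/acceptance.R` reruns) uses six varieties × 100 panicles with
mean SNPPs of 90, 110, 105, 90, 185 and 200 — two japonica-sized, two
intermediate and two indica-sized populations — segmenting all 600
scans, fitting one 5-point area model per variety and scoring the 95
held-out panicles each. The property suites run Otsu against an
exhaustive maximiser on 1000 random histograms and the geometry oracles
on dozens of random masks; the whole suite is sized to run in a few
minutes on a laptop.

## Limitations

* The linear model is per variety and per site; pooling varieties with
  different grain sizes breaks the area premise by design.
* TLPB2 from images degrades when branches adhere or cannot be
  straightened; the area trait is the robust default.
* The 100-px cleanup cutoff and radius-1 opening are calibrated to
  72 dpi; other resolutions need the exposed knobs scaled accordingly.
* No uncertainty intervals are attached to predictions beyond the
  model's R²; with five calibration points, interval estimates would be
  mostly prior.
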