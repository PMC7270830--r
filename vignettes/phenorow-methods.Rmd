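---
title: "Methods: from ortho-mosaic to per-plant biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ortho-mosaic to per-plant biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenorow implements a computational phenotyping workflow for spaced-plant
forage breeding trials: a multispectral drone ortho-mosaic and an
ultrasonic ground-vehicle track go in; per-plant NDVI, height and
predicted dry-matter yield (DMY) come out, aggregated to plot level and
validated against measured harvests. This vignette explains each model
and procedure, the tunable parameters, the numerical choices, and what
the synthetic generator does and does not emulate.

## The trial model

The reference design is a randomized complete block trial of 50 entries
in 10 blocks (one replicate per block). A plot is 8 m x 1.8 m and holds
3 plant rows of 32 spaced plants: 25 cm between plants, 60 cm between
rows, 96 plants per plot, 48,000 plants in all. Imagery has a 2 cm/pixel
ground sampling distance; blocks are stacked north-south and separated
by a 1 m bare alley (machinery access; the source design does not state
the alley width, so a typical value was fixed once). The field is
georeferenced in a metric UTM CRS (zone 54 south by default).

## Radiometric calibration and NDVI

Digital numbers (DN) are converted to reflectance by the empirical-line
method: four grey panels of known reflectance (6, 11, 22, 33 %) are laid
in the field margin, the mean DN over each panel region is extracted per
band, and ordinary least squares gives `reflectance_pct = gain * DN +
offset` per band. The regression direction (reflectance on DN) is chosen
so that application is a direct affine map; its inverse is what the
synthetic renderer uses to make DN, so the loop closes exactly.
Reflectance is clipped to [0, 1] with clip counts logged.
`NDVI = (NIR - Red)/(NIR + Red)`; zero-denominator pixels become nodata.
On noiseless synthetic renders the calibrated NDVI reproduces the
ground-truth NDVI raster to well below 1e-6.

## Perspective rectification

Four corner ground-control points (GCPs) bound the area of interest. A
homography estimated from their pixel/world correspondences maps an
axis-aligned, north-up output grid (at the native GSD) back into the
source image; nearest-neighbour resampling is the default because it
preserves NDVI extrema (bilinear is available). When the homography is
an integer translation the source block is copied verbatim. The inverse
mapping reports any rectified-space polygon in source-pixel and world
coordinates. The crop retains a 0.5 m soil margin around the plots so
that the outermost plant rows are flanked by background on all sides.

## Block and row segmentation

Plant blocks are found on the vertical projection profile (row-wise sums
of the rectified NDVI image, shifted to be non-negative if it has
negative values; the shift is recorded). The profile is opened with a
flat line structuring element (SE) of half the expected plant-row length
(400 px here), eroded with an SE of a third of that length, and the
regional minima of the result mark the inter-block troughs. A regional
minimum is a maximal run of equal values strictly lower than both
neighbours, with borders counting as +Inf; a run spanning the entire
profile is the image, not a trough. The same procedure with the expected
plant width (12 px) as the feature length finds the rows inside each
block. Only these two lengths are external parameters.

Numerical choices:

* SE lengths are forced odd by rounding even lengths up. Rounding up
  guarantees that the opening's dilation window covers the eroded
  interior strip of a block, which makes the opened profile provably
  unimodal inside each block for every random draw — rounding down
  leaves a few columns uncovered and can admit a spurious interior
  minimum.
* On a plateau of tied minima the centre is the lower median index.
* Bands shorter than half the expected row length are discarded: they
  are the soil-margin slivers between a border trough and the first
  alley trough, not blocks.

Initial row boxes take their horizontal extent from the row intervals
and their vertical extent from trough edge to trough edge. Because the
final erosion widens every trough, these boxes deliberately
under-estimate the rows' vertical extent; recovering the cut-off plants
is the job of box growing.

## Box growing

Vertically adjacent boxes with x-overlap are linked; the link rectangle
spans the gap rows and the intersection of the two column ranges. Its
row-wise profile `f(1..n)` is walked from both ends: the heavier end row
is absorbed into its box (both on a tie) and the loop stops when the
unabsorbed mass drops below a scaled background threshold
`t * width * rows`. The background level `t` is estimated as the median
pixel intensity outside all initial boxes — the median, not the mean,
because that region contains exactly the plant overhangs growing must
recover, and a mean would inflate the estimate and choke growth.

Two threshold scalings are implemented. The printed formula scales by
`n - j + 1`, which keeps counting rows already absorbed into the bottom
box; on symmetric overhangs this slack grows with absorption and stops
growth about halfway through the plant zones, leaving outer plants
unassigned. The default is therefore the prose reading — scale by the
rows actually remaining between the growing edges, `k - j + 1` — which
absorbs until only background-level mass separates the boxes; the
printed variant is retained as `variant = "printed"`. Both variants
agree on gaps whose mass is one-sided or background-only, and growth
can never make boxes overlap (`top + bottom <= n` by construction).

Boxes on the field boundary have no partner to link to, so they are
additionally grown toward the image border through a virtual border
link: the same profile procedure runs on the strip between the box and
the border, and rows assigned to the border side are discarded. Without
this, plants in the eroded outer margins of the first and last blocks
would never be recovered.

When several imaging dates are segmented, the consensus polygon set is
the date whose polygon-area sample variance is smallest (ties go to the
earliest date).

## Plant centre detection and polygons

Individual plants are found by template matching. A template is the
pixel-wise mean of 35 sample windows of 20 x 20 px extended by a 4 px
context margin (effective 28 x 28); sample picking was interactive in
the original workflow, so the pipeline either reads a samples file or
picks the brightest NDVI pixel of 35 row boxes spread across the field.
The matching score is zero-normalized cross-correlation (ZNCC),
invariant to local brightness scale and offset; flat windows score 0.
Local maxima with score >= 0.6 survive, and detections closer than 3 px
are merged keeping the higher score (ties to the smaller row, then
column). One refinement pass then rebuilds the template as the mean of
all accepted windows — which span the full range of plant sizes — and
re-matches; this lifts small plants crowded by large neighbours above
the threshold and mirrors the template-update step of the original
workflow.

Centres outside every row box are discarded; a file-driven edit list
(add/remove with pixel coordinates) replaces interactive quality
control. Each row box is then split at the midpoints between
consecutive centres, perpendicular to the row axis, the first and last
polygons extending to the box ends. The polygons partition the box
exactly (areas sum to the box area, always), and plant IDs encode
block, plot, row-in-plot and position.

## Height extraction

The ground vehicle carries six ultrasonic sensors on a boom 0.6 m above
ground, georeferenced by a single RTK antenna. Fixes are projected to
UTM (the transverse-Mercator series is implemented in the package;
round-trips are exact to 1e-9 degrees and grid distances agree with
geodesic ones to the expected scale factor). Sensor positions are the
fix plus the lateral offset rotated to the right of travel, with the
heading taken from consecutive distinct fixes (stationary fixes carry
the last moving heading). Height is `(0.6 - range) * 100` cm, floored
at 0. Samples are assigned to plant polygons by point-in-polygon under
the half-open pixel convention; the per-plant statistic is the median
(robust to stray echoes), after discarding samples at or below 1 cm as
bare-ground baseline returns — the boom also sees the soil between
plants, and on end-of-row polygons baseline returns would otherwise
outvote the plant.

## Biomass prediction and validation

The combined predictor is `NDVIsq_PH = NDVI^2 * height_cm`, computed
from the polygon NDVI statistic and the ultrasonic height. The exact
formula was defined in a companion study of the original workflow, so
the exponent is configurable and the active definition is recorded in
every output. Seasonal DMY per plant (grams) is an affine function of
the predictor with winter2018 the reference season: base intercept
-4.62 g and slope 5.088 g per unit, with offsets +5.76 / +1.49 for the
first late-spring harvest and +16.86 / +3.68 for the second. The
published winter equation prints a unit slope while the late-spring
equations add offsets to the full base line; the default
"reconstructed" mode gives winter the base slope 5.088, and
"as_printed" reproduces the printed unit slope — both agree at
predictor 0. `fit_seasonal_model()` recovers all six coefficients of
the interaction model `measured ~ predictor * season` by OLS, exactly
(to 1e-8) on noiseless data.

Plot predictions are the sum of per-plant grams over the 96 plants of a
plot, divided by exactly 1000; plants with missing traits are excluded
and counted. Validation regresses measured on predicted kg/plot and
reports the slope, R² (squared Pearson correlation, which is
sign-blind, so the slope sign is reported alongside), the RMSE of the
raw prediction errors, and the RMSE of the regression residuals — both
RMSE definitions are exported because published reports rarely say
which was used.

## The synthetic generator

The generator emulates the trial so every stage is testable without
real imagery. Choices made once:

* Soil NDVI is a single per-render draw from U(0.05, 0.15), spatially
  uniform (per-pixel texture is available but off by default): the
  projection method needs trough contrast between soil and canopy, not
  speckle.
* Each plant has a latent vigor (uniform plus an entry-level effect)
  that jointly drives peak NDVI (0.40–0.95), height (about 4–26 cm plus
  noise, floored at 2 cm) and canopy radius (9–15 cm, so neighbouring
  tussocks at 25 cm spacing touch). Tying size to greenness and height
  is what a real sward does, and it makes polygon-level statistics
  informative about biomass.
* Blobs are isotropic Gaussians with radius = 2 SD, truncated at 4 SD,
  normalised so the pixel nearest the centre equals the plant's peak
  NDVI exactly, and composed by pixel-wise maximum.
* NIR reflectance is constant at 0.40 and red follows by NDVI
  inversion, so calibration followed by NDVI reproduces the truth
  raster exactly; panels and GCP markers are spectrally flat (NDVI 0).
  Default DN gain is 0.1 %/DN with zero offset.
* The vehicle path is one straight pass along each row at 1 m/s and
  10 Hz (the original platform's driving pattern is not documented);
  sensor offsets (-0.6, -0.3, 0, 0.3, 0.6, 0.9 m) put three sensors
  over rows and the rest over gaps.
* Simulated harvests evaluate the seasonal equation at the true
  predictor plus Gaussian noise; negative grams are kept by default
  (the model is linear and can go negative), truncation is optional and
  recorded.

What the generator does not emulate: photorealistic canopy texture,
illumination and BRDF effects, stitching artefacts of real
ortho-mosaics, sonar beam footprints, wind. Passing tests on synthetic
scenes therefore demonstrate the correctness of the geometry,
arithmetic and algorithms — not robustness to real-world noise sources
the renderer does not model.

## Problem sizes used in the test suite

Unit and property tests run on miniature trials (2–3 entries x 2
blocks, 384–576 plants, ~230 x 900 px renders) where every stage
completes in seconds; the structural acceptance check runs the full
default trial (48,000 plants, ~4750 x 4700 px) once. Parameter-recovery
checks use 480 observations per season with 100 replicates. These sizes
were chosen so the whole suite exercises every code path at full
fidelity while remaining comfortable to run on a laptop.

## Known limitations

* Rows must be straight and axis-aligned after rectification; curved
  or rotated rows are out of scope.
* Overlapping canopies are not separated into instances; the midpoint
  split assumes detectable centres.
* On-disk rasters use a float32 band-sequential format with a JSON
  header rather than GeoTIFF (values round-trip exactly at float32
  precision).
* The printed-variant box growing is faithful to its source but can
  under-grow symmetric overhangs; see the box-growing section.
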