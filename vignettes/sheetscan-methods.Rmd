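---
title: "Counting cultured cells from pattern-sheet scanner images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cultured cells from pattern-sheet scanner images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Adherent cell cultures are routinely counted by trypsinising an aliquot and
loading it into a counting chamber — an invasive, manual procedure — or by
imaging a handful of microscope fields and extrapolating, which is
noninvasive but biased whenever cells are unevenly distributed across the
vessel. A consumer flatbed scanner can image an entire 10 cm dish at
10 um/pixel in one pass, but unstained cells are nearly transparent and
invisible under its diffuse illumination.

Placing a perforated opaque film (a *pattern sheet*) between the scanner's
light source and the dish changes that. The sheet restricts the angular
diversity of the light, and at every black-white transition of its shadow
the refractive and scattering perturbation a cell imposes on the transmitted
rays becomes visible as a local shading anomaly. Cells are visible inside a
band roughly 680 um wide centred on each transition, so a sheet whose holes
tile the dish with transitions makes nearly every cell countable.

`sheetscan` implements this measurement chain end to end on synthetic data:
scene generation with exact ground truth, the object-likelihood transform
(the *information volume map*), a rule-based detector, the four-way error
taxonomy, the geometric sheet-selection criterion, a ray-optics
demonstration of the visualisation mechanism, and the field-of-view
sampling-bias simulation that quantifies what whole-dish imaging buys over
microscope extrapolation.

## The information volume map

The scan is decomposed against a slightly blurred version of itself. With
$G_\sigma$ a Gaussian blur,

$$\mathrm{IVM}(I) \;=\; G_{1.5}\!\big(\max(I - G_{1.0}(I),\,0)\big)
 \;+\; G_{1.5}\!\big(\max(G_{1.0}(I) - I,\,0)\big).$$

The sheet's shading varies over hundreds of micrometres and survives the
1-pixel background blur almost unchanged, so it cancels in the residual;
cells and debris perturb the image at the 1-3 pixel scale and do not. Both
half-maps are blurred at $\sigma = 1.5$ and summed, giving a nonnegative
per-pixel object likelihood. Values are tiny; they are amplified by 200 for
display and by 100 before computing *object contrast*, with anything above
1.0 clipped to pure white.

Numerical conventions, fixed so that tests can compare against a
dense-convolution oracle exactly: kernels are truncated at $4\sigma$ and
renormalised, and borders replicate the edge pixel. The blur is implemented
as a separable convolution in compiled code (`stats::filter`) with explicit
replicate padding.

Two scalar metrics summarise image quality: the brightness mean and its
sample standard deviation (denominator $N-1$; a single-pixel image has
deviation 0 by definition), and object contrast, the population variance
(denominator $N$) of the amplified, clipped map. The ambiguity in
"deviation" is resolved this way because the two quantities play different
roles: the deviation describes data spread, the contrast is a fixed
functional of the map.

Agreement between the IVM and an independent cell segmentation is scored
with pixel-wise binary cross-entropy in natural logarithms, the predicted
map clamped to $[10^{-7}, 1-10^{-7}]$; the x200 display map is the
prediction. Gibbs' inequality guarantees the score is minimised when the
maps agree, which the tests exercise on random map pairs.

The *local brightness difference*, max minus min over a disk of 10 px
radius, is the empirical visibility covariate: across patterned, stepped
and constant shading, the mean IVM around cell sites correlates positively
with it (Spearman's rank correlation; the suite requires $\rho > 0.5$ and
observes about 0.93).

## Phase-contrast cell regions

The reference segmentation from phase-contrast images follows a fixed
recipe: white top-hat with a radius-1 disk (the 5-pixel plus), Gaussian
blur at $\sigma = 0.75$, intensity enhancement $x^{0.15}$, Otsu's global
threshold, then removal of 8-connected objects with fewer than 2 pixels.
Two design points deserve explanation:

* **Order.** The enhancement must precede thresholding — a power transform
  after binarisation is a no-op on a binary image. This is the only order
  in which every listed step has an effect.
* **What "area" means.** The blur spreads even a single-pixel speck over
  twenty-odd pixels, and the heavy $x^{0.15}$ compression lifts that halo
  above any global threshold, so a rule that measured the *halo's* area
  could never remove anything. The minor-area rule therefore counts a
  component's pixels that exceed the threshold in the **raw top-hat**
  (the Otsu threshold mapped back through the enhancement as
  $t^{1/0.15}$). A 1-px speck has exactly one such core pixel at any
  amplitude and is removed; a cell has many and survives.

One caveat is inherent to a global threshold: adding a cell to an image
shifts the Otsu threshold minutely, so a marginal fringe (< 2% of region
pixels in the suite) may flip far from the new cell. A per-tile or fixed
threshold would remove this at the cost of the recipe's simplicity.

## The detector

The published system recognises cells with a trained segmentation network;
its inference contract is simple — clear white areas are cells, black is
background, gray is uncertain. `sheetscan` keeps that contract behind a
pluggable rule-based detector on the x200 display map: pixels at or above
`white_thresh` seed components, support at or above `gray_thresh` is grown
around them (hysteresis), components below `min_area_px` are dropped, and
components above `max_single_cell_area_px` are split at distance-transform
maxima at least `split_min_distance_px` apart, with intensity-weighted
centroids throughout.

The defaults (`white 0.75`, `gray 0.55`, `min_area 2`, `max_single 40`,
`split_min 3`) were calibrated once on the default synthetic scene and then
frozen: the display-map noise floor of that scene sits near 0.28 with rare
excursions to 0.54, while cell peaks exceed 0.91, so the thresholds sit in
the gap with margin on both sides. On ten seeded scenes spanning 50-500
cells/cm^2 the detector recovers counts within 2% and localises matched
cells to a fraction of a pixel.

Two error modes are physical rather than parametric, and the taxonomy below
names them: cells closer than about 5 px fuse into one saturated blob that
no threshold can re-separate (*lack of resolution*), and cells whose local
shading gradient is near zero stamp almost no contrast (*blind spots*).

Whole-vessel counts tile the masked scan with overlapping tiles (overlap 64
px, beyond the IVM kernel radius), keep each detection exactly once via the
tile that owns its centroid, and merge residual seam duplicates within 5 px
— about the footprint of one cell at 10 um/px.

## Error taxonomy

Detections are matched one-to-one to ground-truth nuclei greedily by
ascending distance (ties: truth index, then detection index), never beyond
`max_dist_px` (default 5 px = 50 um, above a cell footprint, below typical
nearest-neighbour spacing at the densities simulated). Unmatched items are
classified:

| direction | category | rule |
|---|---|---|
| over | image-origin | within `debris_radius_px` of a debris centroid |
| over | large-cell | nearest true cell is already matched to another detection |
| under | blind-spot | centroid inside the dark-zone mask |
| under | resolution | another true cell within the crowd radius |

Precedence when two rules apply is image-origin over large-cell and
blind-spot over resolution; anything left is reported as unclassified, and
the report's accounting identities (matched + overs = detections,
matched + unders = truths) hold exactly by construction. The crowd radius
defaults to twice the median cell diameter in pixels — "densely populated"
made operational. Percentages are relative to the true cell count, the
reference population.

The printed error rates of the original study (1.5-3.7% per category)
belong to its cultures and trained network and are not targets here; the
taxonomy's own tests use constructed fixtures where each category occurs
exactly once, plus trend checks (doubling the dark-zone area does not
decrease blind-spot counts).

## Sheet geometry and the coverage ratio

Cells are visible within 340 um (half of 680 um) of a black-white
transition. The *coverage ratio* of a sheet layout is the fraction of sheet
area within that distance of an open/closed boundary, computed on the
unblurred hole raster by two distance transforms (one per phase) with a
half-pixel interface correction, so the raster estimate converges to the
geometric value. Closed forms anchor the tests: a single hole of radius $r$
covers $\pi(r+w)^2 - \pi\max(r-w,0)^2$ of an effectively infinite plate to
within 1% at 5 um/px.

The hole pitch and lattice of the manufactured sheets are not public, so
the selection result — 450 um holes achieving the highest coverage — can
only be reproduced conditionally on a layout. Under any pitch rule that
scales with diameter (the package default is pitch = 2 x diameter), the
boundary density, and with it the coverage, increases as holes shrink, so
the smallest diameter trivially ranks first; the observed 450 um optimum
reflects the manufactured layouts' specific pitches. The sweep therefore
reports coverage per diameter under a stated rule rather than asserting an
argmax, and the headline 96.7% is not asserted.

A related geometric fact matters for the synthetic scenes: with the blur
fixed by the 680 um step identity ($2.5631\sigma = 680$, i.e.
$\sigma = 265.3$ um), a 450 um hole is narrower than the transition band
itself, so the rendered shading never reaches the full white level and the
10-90% width is only measurable across an isolated boundary (a large hole),
where the suite finds 700 um at 10 um/px.

## Ray-optics demonstration

A deliberately minimal 2-D Monte-Carlo model demonstrates the visualisation
mechanism: a row of point emitters with uniform emission inside a 60°
half-angle, an aperture sheet (450 um holes every 1000 um in cross-section),
model cells as circles of refractive index 1.360 in medium of 1.335
(culture-medium-like, configurable; the hardware study does not print it)
that scatter each incident ray with probability 0.3 and otherwise refract
it by Snell's law at entry and exit, and straight-line propagation to a
binned sensor. No lens, no polarisation, no sheet-material optics.

The observable is *cell contrast*: the sign-free normalised difference
between sensor bins under each cell's geometric shadow and flanking
background bins. The mechanism is angular: without a sheet, rays reach each
sensor point from the full ±60° fan, smearing a 20 um cell's shadow over
hundreds of micrometres; with the sheet, only a few narrow direction bands
survive, and the shadow stays concentrated. With the sensor plane 50 um
under the cells and cells placed under aperture centres, the simulation
yields mean contrast ≈ 0.05 with the sheet versus ≈ 0.013 without, ordered
correctly in every seed tested; replacing the apertures by an 80% diffuser
(each ray's direction randomised with probability 0.8) collapses contrast
back to the no-sheet level, mirroring the homogeneous-illumination control.
Ray accounting (binned + out-of-sensor + absorbed + lost) is exact by
construction and asserted on every trace.

## Field-of-view sampling bias

Twenty-five microscope-sized fields (640 x 480 px at 10 um/px by default)
are placed on a regular 5 x 5 grid over the largest box inscribed in the
vessel mask. The whole-vessel estimate from $k$ fields is the mean
per-field count scaled by area; its percentage discrepancy against the true
total is the sampling bias. For $k = 1$ all 25 singletons are reported; for
larger $k$, five random subsets (without replacement, seeded), following
the original presentation. The estimator is unbiased (verified by exhaustive
enumeration for $k \le 3$) with variance following the finite-population
correction $(\sigma^2/k)\,(25-k)/24$ (verified empirically within 20%), and
on clustered scenes the $k = 1$ spread strictly exceeds the $k = 20$
spread, while sparse frames spread wider than dense ones — the qualitative
behaviour that motivates whole-dish imaging.

## The synthetic scene generator

Every module is tested against scenes with exact ground truth. A scene is a
matched triplet — scan, phase-contrast-like image, nuclear-stain-like image
— plus truth tables. The defaults are the study conditions: 1000 x 1000 px
at 10 um/px (exactly 1 cm^2), a 450 um hexagonal sheet at 900 um pitch,
shading between 0.15 and 0.85 blurred with sigma = 265.3 um, cells of
15-20 um diameter placed uniformly at random with a minimum separation of
one cell diameter (rejection sampling, 100 retries per cell, so the truth
count is exact), additive Gaussian scan noise of sd 0.002, and no debris
unless requested.

A cell's scan appearance is a zero-mean radial dipole (bright plus dark
crescent, footprint ≈ diameter + 2 px) oriented along the local shading
gradient, with amplitude

$$A_i = \texttt{cell\_amplitude} \times
 \big(v\, g_i + (1 - v)\big),$$

where $g_i$ is the normalised shading-gradient magnitude at the centroid
and $v$ is `visibility_coupling`. With $v = 1$ cells vanish exactly where
the truncated blur leaves the shading flat — the mechanism the sheet
exists to defeat; the default $v = 0.8$ leaves a 20% gradient-independent
floor, representing the residual visibility real cells retain. The
perturbation's zero mean mimics refraction redistributing rather than
absorbing light. Debris are dark monopole specks stamped in scan and phase
but never in nuclei, so they surface as image-origin false positives.
`cell_amplitude = 0.2` puts cell perturbations at a few percent of full
scale — strong enough to saturate the x200 display locally, as real cells
do.

What the generator does **not** emulate: optical point-spread asymmetries,
illumination drift, confluent colonies and 3-D aggregates, cell morphology
classes, and debris in focus gradations. Passing tests therefore certify
the pipeline's internal correctness and its behaviour under the stated
image-formation model, not performance on any particular real culture.

Scene noise deserves one note: the IVM takes absolute residuals *before*
smoothing, so zero-mean pixel noise does not cancel — it sets a uniform
display floor of roughly $200 \times 0.8 \times$ `noise_sd`. The default
0.002 keeps that floor (~0.28) clearly below cell peaks (> 0.9); detector
thresholds were placed in the gap once and frozen.

Growth series follow an exponential curve with a stated doubling time
(optionally logistic-capped), with frame $t$ carrying `round(curve(t))`
cells; positions persist across frames (earlier frames are prefixes), so
fixed fields see coherent time-lapse data. A 265-frame series at 30-minute
intervals spans 132 hours.

## Problem sizes and determinism

All randomness in a scene, trace or pipeline run flows from a single
integer seed; identical parameters give bit-identical outputs, and the
end-to-end pipeline writes byte-identical artifacts on re-run, which the
suite asserts by checksum. Test problem sizes are chosen to exercise each
property at the smallest scale where it is meaningful: oracle comparisons
on ≤ 32 x 32 images, detection recovery on ten 1 cm^2 scenes of 50-500
cells, ray traces of 10^6 rays, FOV enumeration on C(25,3) subsets, and a
300 x 300 px pipeline dish with three replicate dishes for the
determinism check; the acceptance script uses fifteen 0.25 cm^2 dishes for
its correlation.

## Known limitations

* The detector is a calibrated stand-in for the published trained network;
  absolute error percentages are not comparable to those reported for real
  cultures.
* The ray tracer is 2-D with an ideal sensor mapping; it demonstrates the
  contrast ordering, not illuminance values.
* Global Otsu thresholding makes the phase segmentation weakly non-local
  (see above).
* Live/dead discrimination is out of scope — the underlying measurement
  cannot distinguish them.
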