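---
title: "Quantifying conifer ray parenchyma: models, artifacts and sampling design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conifer ray parenchyma: models, artifacts and sampling design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raypar)
```

## The measurement problem

Rays are thin, radially oriented sheets of parenchyma running pith to bark
through conifer xylem. On thin wood sections they are quantified as the
percentage of ray surface (PERPAR) — on an unbiased section an estimate of
the relative ray volume — together with counts of rays initiating within a
ring (NEWRAY), ray dimensions, and their year-to-year variability. Two
things make these numbers treacherous:

1. **The cutting plane.** A 10–15 µm section is transparent, so the
   perceived outline of a ray is the *maximum projection* of its body
   through the entire slab thickness. For a sheet some 25 µm wide viewed
   in the radial plane, the projection inflates the apparent outline
   enormously; in the cross-sectional plane the same effect acts weakly
   through the tapering upper and lower extremities of the fusiform
   profile; tangential sections cut the sheet perpendicular to its long
   axes and are essentially unbiased. If the slab normal is additionally
   misaligned with the ray orientation, rays drift out of a cross-section
   along the radius and spuriously "end" (and others spuriously
   "initiate") — the ending-ray artifact.
2. **How much wood is measured.** PERPAR from a single small window is a
   noisy estimate; its accuracy improves with the measured surface and
   with the number of samples as `n^(-1/2)`.

Because the raw micrographs behind published ray statistics are generally
not available, this package makes the measurement chain itself the object
of study: a parametric 3D generator provides ground truth, a virtual
microtome reproduces the artifacts, and the measurement and accuracy
stages are the same functions a user would apply to imported label maps or
outline tables.

## The synthetic wood model

`wood_config()` / `generate_wood()` build a Cartesian sector with
coordinates in mm: `r` radial (pith to bark), `t` tangential, `z` axial.
Stem curvature is ignored — at breast height a sector a few cm wide
subtends so little arc that the curvature bias is far below the other
noise sources. Rings follow a lognormal width distribution (default mean
1.047 mm, a typical mature Scots pine value; CV 0.2 as a realistic
inter-annual spread) and split into earlywood and latewood at a fixed
latewood fraction (default 0.3, typical of the species).

Each ray is a fusiform uniseriate sheet: at normalized axial offset
`u = 2(z - z_center)/h` its tangential half-width is
`(w/2)(1 - u^2)^p`. The profile exponent defaults to `p = 1` (a pointed
spindle); `p = 0` gives a rectangular sheet. The breadth factor
`B(p) = sqrt(pi)/2 * gamma(p+1)/gamma(p+3/2)` makes the lens area
`w * h * B(p)` (`B(1) = 2/3`). Ray height is lognormal with mean 180 µm
(CV 0.25) and the maximum width is 25 µm; these are placeholders typical
of uniseriate conifer rays, not fitted values, and are exposed in the
configuration. An optional linear height increase with cambial age
(`ray_height_slope`) is available and off by default.

Ray demography uses two pools:

* **persistent rays** (`ray_density` per mm² of tangential plane) spanning
  the whole radial extent — rays that keep their connection with the
  cambium;
* **ring-initiated rays** (`initiation_density` per mm² of tangential
  plane per mm of radial growth; latewood intensity scaled by
  `latewood_initiation_multiplier`) with a per-border termination
  probability. Terminations happen *at* ring borders, which ties ray
  demography to the cessation of cambial activity and keeps them distinct
  from the mid-ring apparent endings created by misalignment; with
  `termination_probability = 1` every ring is statistically identical
  (stationary demography), which is the regime used for calibrated
  studies. In a Cartesian slab there is no circumference growth, so
  stationarity must come from this turnover rather than from geometry.

Centers are placed by a Poisson process on a window dilated beyond the
sector faces by a ray width/height, so coverage is stationary up to the
boundary. Poisson placement (rather than a hard-core process) is the
default because it gives the exact Boolean-model coverage law
`E[areal fraction] = 1 - exp(-eta)`, on which all calibration rests; a
simple-sequential-inhibition hard-core option (`placement = "hardcore"`,
minimum tangential gap of one ray width between co-occurring rays) is
available when visually distinct uniseriate rays matter more than exact
calibration.

Year-to-year variability enters as a multiplicative lognormal year factor
(mean 1, CV `interannual_cv`) on ray width in each ring.

### Calibration

* `calibrate_volume_fraction()` sets the persistent density so the
  analytic expected ray volume fraction equals a target percentage,
  inverting the Boolean law: `d = -log(1 - p/100) / (w h B(p))`.
* `calibrate_cross_sections()` solves, in closed form, four parameters
  (persistent density, initiation intensity, latewood initiation
  multiplier, latewood width multiplier) so that the *expected measured*
  values on a cross-section of the given thickness equal four targets:
  early/latewood PERPAR and early/latewood standardized NEWRAY. The
  expectation accounts for the slab projection term
  `eta = d * w * (h B(p) + thickness)` and for the residence of
  ring-initiated rays (a ray initiating uniformly within a zone is
  present, on average, over half of it). Infeasible target combinations —
  initiation counts requiring more standing rays than the PERPAR targets
  allow — raise an error rather than returning a nonsense configuration.
* `calibrate_interannual_cv()` finds the year-factor spread whose
  *measured* mean sensitivity matches a target, inverting the closed form
  for i.i.d. lognormal steps (`E[MS] = 200 E[tanh(|N(0,1)| sigma/sqrt 2)]`)
  through the mildly saturating coverage transform by quadrature
  (midpoint rule in probability space, 48² nodes) and root finding.

`true_volume_fraction()` reports the exact analytic volume of the realized
ray set (piecewise over ring/zone segments, clipped at the sector faces);
where bounding boxes overlap, the double-counted volume is removed by a
Monte-Carlo estimate confined to the overlap boxes, seeded from the model
so the result is reproducible.

## The virtual microtome

`cut_section()` intersects the model with a finite-thickness slab in one
of the three anatomical planes and rasterizes, per ray, the union of its
outline over the slab depth. The projection is binary — a ray present
anywhere in the depth marks the pixel — matching the transparency argument
above; no staining contrast, focus blur or section compression is
modelled. Misalignment tilts the cross-sectional slab about the tangential
axis (its axial position then drifts with radius, which is exactly what
creates apparent ray endings) and the radial/tangential slabs about the
axial axis. The tilt is applied to the slab *center*; the cosine
thickening of an inclined slab (≤ 3.5 % at the 15° cap) is neglected, and
for tangential cuts the tilt is evaluated at each ray's tangential center
(across one 25-µm ray width the drift is < 0.1 µm).

The raster is 0-based with half-open pixel footprints; a pixel belongs to
a ray when its *center* falls inside the projected outline, which makes
the areal fraction an unbiased estimator at any resolution. The default
2 µm/px resolves a 25 µm ray width with ~12 pixels while keeping a
4 × 4 mm section near 4 Mpx. Where two projections overlap, the pixel
goes to the lowest ray id and the contest is tallied in `overlap_px`. Ids
are assigned in order of increasing radial span, so short-lived rays keep
their pixels: a long band partially covered elsewhere retains its
identity, whereas a short ray fully contained in a band would vanish from
the image — the information-preserving choice. Fully hidden rays and
sub-pixel slivers near the visibility edge remain genuinely unmeasurable,
an honest analogue of merged outlines in real vectorized micrographs; they
cost the initiation counts about 2 % (see the recovery tests).

## Ray metrics

`extract_outlines()` groups the label map by ray id and measures areas,
axis-aligned extents and centroids. Dimension conventions follow
vectorized-micrograph practice: tangential sections measure ray *height*
(axial extent) with width derived as area/height; cross and radial
sections measure the radial *length*. Outlines touching the image
boundary are flagged and excluded from dimension statistics but retained
in areal fractions.

On cross-sections, a ray *initiates* in a ring when its pith-side end
lies more than one pixel inside the ring's inner border (the tolerance
prevents rasterization jitter from minting initiations), and it is
assigned to the zone containing that end; *disappearing* rays end more
than one pixel short of the outer border. With a perfectly aligned slab
and persistent rays both counts are zero; under misalignment the two
artifacts grow together and approximately in balance.

`ring_metrics()` reports, per ring, PERPAR overall and by zone, raw and
standardized NEWRAY, disappearing counts and dimension means. Two
standardizations coexist:

* the whole-ring `newray_per_mm` divides by the measured tangential
  width;
* the zone values `newray_early_per_mm` / `newray_late_per_mm` divide
  each zone's count (over the full section width) by the *zone's radial
  extent* in mm. Early- and latewood share the same tangential width but
  occupy very different radial shares of a ring, so a correction for
  their unequal tissue contributions has to divide by the quantity in
  which they differ. There is also a quantitative argument: under
  uniseriate geometry (h ≈ 180 µm, w ≈ 25 µm, PERPAR ≈ 6 %), zone
  initiation rates of ~22 rays per *tangential* mm per ring would require
  several times more standing rays than the PERPAR level admits, whereas
  the same numbers read as counts per mm of zone radial extent are
  jointly attainable — that reading is therefore what
  `calibrate_cross_sections()` targets and `ring_metrics()` reports.

`assemble_time_series()` turns per-ring metrics into year-ordered annual
series; `simulate_annual_perpar()` produces the model-level annual PERPAR
series (year factors through the expected coverage, without raster or
window noise) for variability studies.

## Accuracy analysis and sampling design

`sample_windows()` places windows uniformly at random, fully inside the
image, overlaps permitted — no exclusion rule is imposed, matching the
exchangeable-pool treatment downstream. Tangential windows are squares of
a given mm²; cross-sectional windows are full-height strips of a given
width, so a 1-mm strip on ~1-mm rings measures a surface comparable to a
1-mm² tangential window.

`bootstrap_accuracy()` simulates measuring increasing wood surface: for
each size `s` it draws `reps` estimates, each the *mean* of `s` values
resampled with replacement from the pool, and records the mean and CV
(n−1 standard deviation over mean) of the estimates. The mean — not the
sum — is the aggregator because PERPAR is intensive; resampling means of
i.i.d. draws also gives the clean check `cv(s) = cv(1)/sqrt(s)` used in
the tests. `ci95()` converts a per-sample CV into the relative 95 %
confidence interval `100 · 2 · cv / sqrt(n)` (CI95 ≈ 2 SE, SE = SD/√n,
SD = CV · mean), and `required_samples()` inverts it with a ceiling —
conservative for design.

## Statistics

`mean_sensitivity()` uses the standard dendrochronological form with the
mean of consecutive values as denominator,
`100 · mean(|2(x_t − x_{t−1})/(x_t + x_{t−1})|)`, since "average
percentage change" is otherwise ambiguous about the denominator. Values
must be positive; constant series give exactly 0. `pearson_matrix()`
reports pairwise Pearson r with two-sided p from the t distribution on
n − 2 degrees of freedom, flags zero-variance columns as `NA` (never a
silent 0), and applies no multiple-testing correction — significance
marks follow the conventional 0.001/0.01/0.05/0.1 thresholds.
`paired_t_test()` pairs by default (zone or plane comparisons are pairings
of the same tree × ring) with a Welch two-sample fallback; zero-variance
differences are an error, since the t statistic is then undefined.
`fit_allometry()` is ordinary least squares with `R² = 1 − SSres/SStot`,
which equals the squared Pearson correlation — both identities are
asserted in the tests against closed-form oracles.

## Reproducibility and the pipeline

Every source of randomness flows from one seed through named sub-streams
(`sub_seed()`), so `run_pipeline()` is bit-reproducible: identical
configuration and seed give identical MD5 content hashes in the manifest,
and any stage can be re-run in isolation. Label maps travel as 8-bit RGB
PNG with the 16-bit ray id split across the red/green channels (id =
256·R + G) plus a JSON sidecar; all tables are CSV with validated schemas.

## Problem sizes and what the tests show

The recovery studies bundled with the package use: 20 tangential
4 × 4 mm sections for volume-fraction recovery; 40 simulated cores of 20
rings with three serial 15-µm cross-sections each (serial sections from
one core are standard microtome practice and average away the sampling
noise of the ~20 rays visible in any single cut, leaving the estimator
unbiased); and 40 twenty-ring annual series for mean sensitivity. These
sizes keep the full suite within a few minutes on one CPU while holding
Monte-Carlo error well inside the assertion tolerances.

Passing tests show that the measurement chain recovers known synthetic
truth and reproduces the plane ordering, thickness monotonicity and
misalignment artifacts qualitatively. They cannot show that real
micrographs are free of segmentation error, staining variability, section
compression or operator bias — none of which the generator emulates — so
absolute values from real material still require the usual anatomical
quality control.

## Known limitations

* Cell-level anatomy is out of scope: no individual parenchyma cells,
  marginal ray tracheids, pits, resin ducts, or multiseriate rays.
* The cross-sectional overestimation in the simulator is purely
  projection-geometric; if part of the published cross/tangential
  discrepancy is segmentation-driven, the simulated ratio will not match
  it.
* The bootstrap treats windows as exchangeable; spatially correlated
  (block) resampling is deliberately not implemented.
* Ray width is constant per ray (no within-ray width taper along the
  radius beyond the zone/year modifiers).
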