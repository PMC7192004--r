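---
title: "Canopy structure from point clouds and the two-source energy balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy structure from point clouds and the two-source energy balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

This vignette is the package's own account of its models, its numerical
choices, and what its synthetic tests do and do not demonstrate.

## The extraction model

The analysis unit is a square grid cell, 3.6 m by default — the finest
resolution at which the two-source energy balance is usefully applied
over a trellised vineyard. Within a cell the workflow is:

1. **Spectral attribution.** Each point receives the value of the
   horizontally nearest valid pixel per band. Bands keep their native
   resolutions (10 cm optical, 60 cm thermal is the emulated setup), so
   roughly 36 points share one thermal pixel. Ties on a pixel boundary
   go to the lower (row, column) index; a nodata pixel falls back to the
   nearest valid pixel within a search radius (default 1 m), beyond
   which the point is flagged rather than dropped.
2. **Ground reference.** Mode I uses the point cloud alone: points at
   NDVI ≤ 0.6 are ground candidates, and their per-cell minimum z is the
   single ground elevation — a zero-slope assumption within the cell.
   Mode II assigns each point the z of its horizontally nearest LiDAR
   ground point, so within-cell slope is honoured. Relative heights are
   floored at zero; a point more than 1 cm below its reference is
   flagged `below_ground`.
3. **Classification.** NDVI strictly above 0.6 is vegetation; vegetation
   splits at 0.5 m relative height into cover crop (below) and vine
   canopy (at or above — the boundary is inclusive on the vine side,
   a choice this package documents because the thresholds are usually
   quoted without inclusivity).
4. **TIN metrics.** A 2D Delaunay triangulation (via `interp`) with
   relative height as elevation. Volume is the sum over triangles of
   planimetric area times the mean of the three vertex heights — exact
   for a piecewise-linear surface, so no integration-rule error exists.
   Surface area sums 3D triangle areas; projected area sums planimetric
   areas and feeds fractional cover `f_c` and canopy width
   `w_c = row_spacing · f_c`. Duplicate planimetric positions collapse
   to the highest return (photogrammetric clouds stack returns).

### Clipped integration at cell boundaries

A TIN built from points hard-clipped to a cell underestimates area and
volume near the cell boundary: the convex hull of a finite sample stops
short of the clip line by roughly half the point spacing, and cells cut
through several canopy pieces accumulate several such deficits (up to
~10% at 100 points/m²). The extraction therefore triangulates the cell
*plus a 0.5 m buffer* and clips each triangle to the cell rectangle
before integration. Because the surface is linear on each triangle, the
clipped-polygon planimetric area, the area times the height at the
polygon centroid, and the area times the parent triangle's slope factor
are all exact. Counts, spectral means and mean heights still use only
the in-cell points.

### The TIN edge filter

A Delaunay triangulation over a sparse class covers that class's convex
hull, so the vine-class TIN will *bridge* canopy gaps — and, in cells
containing two disjoint row pieces (rows are 3.35 m apart, cells
3.6 m), it will bridge the bare inter-row as well. `max_tin_edge`
removes triangles with any planimetric edge beyond a threshold before
integration. The default is off, matching the method as usually
described; recovery tests against analytic truth engage it at 0.5 m
(between the ~0.1 m point spacing and the 2.35 m inter-strip gap),
because the analytic truth is defined per strip, not per convex hull.
The gap-behaviour test runs *without* the filter, since gap bridging by
the vine TIN is exactly the mechanism that makes vegetation volume fall
below vine volume when gaps exist.

## Component temperatures

Per cell, radiometric temperature is regressed on NDVI over the
thermal-resolution pixels (ordinary least squares, NDVI aggregated to
the thermal grid by averaging — the thermal band is the coarsest, so
the regression lives at its resolution). Substituting a pure-soil and a
pure-canopy NDVI threshold into the line yields two temperatures; the
warmer is soil. Thresholds come either from scene-wide NDVI percentiles
(p5/p95 — the histogram-analysis realization) or as fixed user values
(the route for thresholds derived from an external LAI–NDVI relation).
Cells with fewer than 3 usable pixels or zero NDVI variance degrade to
`Ts = Tc = mean(Tr)` with a `degenerate` flag; a non-negative slope is
physically unexpected and flagged `positive_slope`, not rejected.

## LAI models

Three regression forms over area-normalized metrics (volumes become
m³/m² = m, areas dimensionless; temperature stays in °C). The
spectral-only model is unambiguous and is checked against an
independent re-statement to 1e-12. The structural-only and combined
forms are typographically ambiguous in their printed fraction/exponent
placement; this package stores them as *configurable expressions* with
documented default parses and treats no published numeric claim as tied
to them. Notably, the combined model's default parse contains a
`1.54^Tr` factor that explodes for midday canopy temperatures — a
further sign the printed typography is unreliable — so pipeline runs
using it can produce non-physical LAI; such cells are flagged
`skipped_cell` in the flux stage rather than driving the energy balance
with garbage. Negative predictions are reported raw by default with an
opt-in clamp at zero.

## The energy balance

With component temperatures known, the model needs no Priestley–Taylor
assumption:

* Longwave: grey-body soil/canopy emission; clear-sky emissivity
  `1.24 (10·ea/Ta_K)^{1/7}` (Brutsaert form) for the sky term, chosen
  because vapour pressure is listed as forcing without an equation;
  canopy interception `1 − exp(−k_L Ω LAI)` with `k_L = 0.95`,
  clumping `Ω = 1` by default (a per-cell map can be supplied; canopy
  width is carried in the outputs and exposed to that option rather
  than hard-wired into the resistances).
* Shortwave: beam transmittance `exp(−K_be(θ) Ω LAI)` with the
  spherical leaf-angle extinction coefficient; the full direct/diffuse
  split is out of scope and noted.
* `G = 0.3 · Rn_s` by default (the fraction is configurable; negative
  nighttime values pass through).
* Sensible heat through a series network: `R_a` from the log profile
  with Businger–Dyer corrections, `R_x = (C/LAI)·√(l_w/U_{d0+z0M})`
  with `C = 90 s^{1/2} m^{-1}` (the square root over `l_w/U` is the
  reading consistent with C's printed units), `R_s = 1/(0.004 +
  0.012·u_s)` with Goudriaan in-canopy wind attenuation,
  `d0 = 0.65·h_c`, `z0M = 0.125·h_c` — the standard formulations the
  method's lineage leaves to its references. Air density comes from
  (p, Ta, ea); `c_p` is held at 1013 J kg⁻¹ K⁻¹.
* The Monin–Obukhov length is iterated with a half-step damped update
  (same fixed point, steadier on strongly stable/unstable branches)
  until it changes by less than 1e-5 m, at most 100 passes; unconverged
  runs are flagged. Near-zero sensible heat pins L at ±1e6 m
  (effectively neutral) to avoid division blow-ups.
* Latent heat is the residual of each component balance, so both
  component closures hold to machine precision by construction;
  negative `LE_s` is permitted (residual semantics preserved).

## The synthetic scene generator

The generator emulates the target acquisition: east–west rows 3.35 m
apart, box-section canopies 2.2 m tall and 1 m wide above a ~0.7 m open
trellis space, 1.5 m vine slots (so gaps are missing vines), a cover
crop below 0.5 m in 0.5 m patches, ~100 points/m², LiDAR-like ground
points at 4 points/m² (airborne-LiDAR class) lying exactly on the
terrain, 10 cm optical and 60 cm thermal rasters, and a warm-soil /
cool-canopy thermal field mixed linearly by the vegetated fraction each
thermal pixel sees. Scene generation is a pure function of
(configuration, seed).

Choices worth stating explicitly:

* **Only the upper canopy envelope is sampled** — nadir photogrammetry
  cannot see beneath the canopy — and the canopy boundary is densified
  with breakline points (±2 mm jitter), since structure-from-motion
  clouds resolve sharp texture edges well. Without edge densification
  the convex-hull deficit alone costs several percent of footprint
  area.
* **Vertical noise is 1 cm** (survey-grade ground control). Mode I's
  per-cell minimum-z ground reference inherits a minimum-statistic bias
  of about 3–4σ of this noise (heights read ~1.5% high at 1 cm noise
  against the slope-aware mode II); the mode-equivalence test therefore
  runs on a noise-free control scene, which isolates the
  ground-reference scheme itself.
* **The raster vegetation mask is dilated by half an optical pixel.**
  A binary, centre-sampled synthetic image would erode the canopy edge
  by up to half a pixel (edge points would read soil NDVI and drop out
  of the vine class); real orthomosaics image the canopy top with
  overhang, so edge pixels are vegetation-dominated.
* **Gaps can carry cover crop** (`gap_cover`): light reaching the gap
  floor favours regrowth there even when the mowed inter-row is bare.
  This reproduces the regime in which gap bridging by the vine TIN
  raises vine volume above vegetation volume.
* The ellipsoidal canopy cross-section option is not provided with
  analytic truth; the box shape is the default precisely because its
  TIN metrics have closed forms.

What passing the synthetic tests shows: the geometry, classification,
integration and physics are implemented correctly, at the stated
densities and noise levels. What it does not show: robustness to real
photogrammetric pathologies (doming, holes, vegetation-dependent
density), radiometric miscalibration, or canopies far from a box shape.
Point density is assumed uniform with depth because the emulated data
do not characterize its variation.

## Problem sizes and determinism

The study-scale test scenes are 10 × 10 cells of 3.6 m (~146k points,
~130k optical pixels); a full extraction takes a few seconds on one
core, and the complete suite (including five such extractions and a
1000-draw energy-conservation sweep) runs in under a minute. All
randomness flows from explicit seeds; identical configuration and seed
reproduce byte-identical pipeline outputs, and each pipeline artifact
records a hash of the scientific configuration (output paths and
verbosity excluded).

## I/O formats and limitations

Point clouds: LAS 1.2 (point format 0, millimetre scaling, reader and
writer included) and delimited XYZ text. Rasters: ESRI ASCII grid, a
plain-text georeferenced single-band format; reflectance is validated
into [0, 1] on load, temperature stays in °C at I/O and becomes Kelvin
only inside the radiation physics, and nodata is propagated, never
interpolated. Grids: generated axis-aligned tilings (half-open cells,
row-major ids from the lower-left) or GeoJSON polygon grids. Geographic
(lon/lat) coordinates are rejected rather than silently reprojected —
areas and volumes are only meaningful in a planar metric CRS. Row-aligned
(rotated) grids are not generated; north-up is the supported default.

Known limitations: the mode-I ground reference biases heights upward
under vertical noise (use mode II when ground points exist); the
structural and combined LAI model parses are typographically uncertain
and configurable; the clumping factor default of 1 ignores row-structure
radiation effects unless a map is supplied; flux aggregation to a tower
footprint is a plain mask mean, not a footprint model.
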