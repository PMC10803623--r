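---
title: "Methods: littoral slope, wind exposure and macrophyte status indices"
author: "littoral package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: littoral slope, wind exposure and macrophyte status indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littoral)
```

## What the package computes

`littoral` quantifies two physical properties of a lake's littoral zone at
the survey-transect level — the steepness of the bottom and the wind
energy reaching the shore — and relates them to the structure and
ecological status of macrophyte communities. Transects are the standard
survey unit of national lake monitoring: 30 m wide belts set perpendicular
to the shoreline, running from the shore fringe to the maximum depth still
colonised by plants (C_max). The package implements every stage from raw
geometry and hourly wind records to the final indicator-species and
correlation tables, plus generators for synthetic lakes with known ground
truth.

## Bathymetry and littoral slope

**Depth raster.** The input is a shoreline polygon (the 0 m contour) and
isobath polylines labelled with depth, in planar metric coordinates. The
professional GIS workflow interpolates these contours with a hydrologic
drainage-enforcing algorithm; inside a closed lake basin drainage
enforcement is irrelevant, so `interpolate_depth()` uses a transparent
linear-between-contours rule instead: each cell takes the depth
interpolated linearly, by Euclidean distance, between the two contours
that bracket it. For nested closed contours the bracketing pair is found
by containment (how many rings enclose the cell), which is robust to
uneven contour spacing; for open contour fragments the two nearest
distinct-depth contours are used. Beyond the deepest closed isobath, and
outside the shoreline, the surface continues linearly at the local
gradient. The unclipped surface is retained on the grid object so that
the slope operator sees no artificial flattening at the shore; all
reported depths are masked to the lake polygon and floored at 0. Closed
rings are resampled to at most 256 vertices before the distance sweeps so
cost scales with the grid rather than with digitisation density.

**Slope raster.** `slope_raster()` applies Horn's 3×3 finite-difference
kernel — the operator behind the standard GIS slope tool — and converts
the gradient magnitude to degrees. Raster edges are padded by nearest
neighbour. On any affine depth plane the result is exact to machine
precision away from edges; on curved surfaces the error is of order
(cell/r)² in the curvature radius r.

**Zonal slopes.** A transect's littoral zone is the 30 m wide rectangle
along its inward normal, truncated where depth along the centreline first
reaches the target depth: 1 m for the shallow littoral (`Sl_1m`, the
variable used for emergent vegetation) and the labelled isobath nearest
the lake's maximum colonisation depth for the deep littoral (`Sl_Cmax`,
used for submerged vegetation; ties between equally near isobaths resolve
to the deeper one). The zonal statistic is the arithmetic mean of the
slope raster over cells whose centres fall in the rectangle. Whether the
original workflow used a buffered line or a rectangle, and mean or
median, is not documented; the rectangle/mean choice is exposed through
the zone object so either can be recomputed.

**Units and classes.** Percent grade is `tan(α)·100`; reported values are
rounded half-up to one decimal, which reproduces the printed dual-unit
pairs (15.93° = 28.5 %, 14.23° = 25.4 %, 1.32° = 2.3 %, 8.42° = 14.8 %).
Deep-littoral slopes classify as gentle (< 1.32°), steep (> 8.42°) or
moderate; both inequalities are strict, so the boundary values themselves
are moderate.

## Wind exposure

Five rays leave the transect anchor at −45°, −22.5°, 0°, +22.5° and +45°
around the inward normal (the extreme rays subtend 90°); each runs to its
first transversal intersection with the shoreline or an island. The
effective fetch is their cosine-weighted mean with weights 1, 0.92388
(= cos 22.5°) and 0.70711 (= cos 45°), weight sum 4.26198. Rays that pass
exactly through a polygon vertex are re-cast with a sub-arcsecond jitter;
rays leaving the polygon immediately at a concave anchor get length 0
with a warning.

Hourly wind records are collapsed to calendar days: speeds by arithmetic
mean, directions by the Linear Directional Mean — the arctangent of the
ratio of summed sines to summed cosines with the four-branch quadrant
correction, implemented exactly as the printed algorithm and verified in
the tests against an independent `atan2` resultant-vector oracle. Days
with a near-zero resultant (no defined mean direction) are dropped with a
message.

The exposure index is

$$E = \log\!\left(1 + \frac{f\,w\,h}{d^{2}}\right)$$

with *f* the effective fetch (km), *w* the share of days with wind
towards the site, *h* the mean wind speed (m s⁻¹) and *d* the site depth
(m) — 1 m for helophyte analyses (`Exp_1m`), the transect's C_max for
hydrophytes (`Exp_Cmax`). Three conventions in this formula are not fully
pinned down by its published uses, so each is an explicit, configurable
choice here:

* **Logarithm base** — natural log by default (`log_base` argument). The
  index is used on a relative scale, so the base only rescales it.
* **"Towards the site"** — a day counts when its daily mean direction
  falls within ±45° of the inward (open-water) normal: the same 90°
  sector the fetch rays span (`half_angle` argument). Directions follow
  the meteorological FROM-convention; wind arriving at the shore from
  open water comes *from* the open-water side, so the FROM-direction is
  compared to the inward normal directly. A `convention = "to"` flag
  accepts travel-direction data instead.
* **Mean speed h** — averaged over *all* days in the window, not only
  toward-days; the formula's separation of *w* and *h* reads as
  independent factors.

## Status indices

Diversity uses Shannon H′ with the natural logarithm and Pielou evenness
J′ = H′/ln S. For a monodominant stand S = 1 leaves J′ undefined
(H′max = 0); the default reports J′ = 0, the conservative reading for a
degradation-sensitive index, switchable to 1 via `mono_evenness`.

The lake-level index combines evenness with a colonisation term:
ESMI = 1 − exp[−J′ · (N/iso2.5) · exp(N/P)], with N the vegetated area
(ha), iso2.5 the lake area enclosed by the 2.5 m isobath (computed from
the depth grid as cell area with depth ≤ 2.5 m) and P the lake area (ha).
The transect modification replaces N by the transect's colonisation depth
C_maxTR, iso2.5 by the constant 2.5 (metres, mirroring the 2.5 m isobath
normaliser) and P by the lake's maximum depth:
ESMI_TR = 1 − exp[−J′ · (C_maxTR/2.5) · exp(C_maxTR/Z_max)]. Both indices
live in [0, 1), are zero iff the evenness or the abundance factor is
zero, are strictly increasing in J′ and in the colonisation term, and
coincide exactly on the matched single-transect case
(N/iso2.5 = C_maxTR/2.5, N/P = C_maxTR/Z_max) — all of which the test
suite asserts.

## Community statistics

`indval()` implements the Dufrêne–Legendre indicator value: specificity
A (group mean abundance over the sum of group mean abundances) times
fidelity B (within-group occurrence frequency), reported as the maximum
over groups. A variant using group abundance *sums* (which weights groups
by size) is available via `type = "total-abundance"`. Significance comes
from permuting group labels: p = (r + 1)/(n_perm + 1) with 999
permutations by default, seedable for reproducibility; no multiple-testing
correction is applied, matching common reporting practice for these
tables. The conventional indicator flag is IndVal ≥ 0.50 with p < 0.05.

`simper()` decomposes the average between-group Bray–Curtis dissimilarity
into per-syntaxon contributions (the |xᵢ − xⱼ| numerator terms over the
pair total, averaged over between-group pairs); contributions sum to the
overall dissimilarity, and the tests cross-check the decomposition
against `vegan::simper`. The classical tests — Spearman rank correlation
(average ranks for ties), Kruskal–Wallis with tie correction,
Mann–Whitney follow-ups — delegate to the standard `stats` routines; the
correlation table carries the reporting rule of the published tables
(drop p > 0.1, flag 0.05 ≤ p ≤ 0.1 as non-significant).

Syntaxa with more than three occurrences enter the multivariate analyses
(`community_matrix(min_occurrences = 4)`), mirroring survey practice.

## The synthetic-data generators

The generators exist so that every downstream stage can be tested against
known truth; they emulate the *structure* of a national monitoring
campaign, not any real lake.

* **Lakes** (`make_lake`): star-shaped shorelines — circle, ellipse, or a
  radius perturbed by low-order Fourier harmonics kept small enough that
  the polygon stays simple and ray casting has a unique first hit. Depth
  is a function of distance to shore: conic (linear to the maximum depth
  at the centre), planar-shelf (constant grade, giving a uniform true
  slope of arctan(grade)), or two-slope (a shallow shelf breaking to a
  steeper fall at a set depth). Isobaths are emitted as inward offsets of
  the shoreline, exact level sets for these profiles. Transects sit at
  equal arc-length spacing with inward normals. 8–27 transects per lake
  matches the national survey design.
* **Wind** (`make_wind`): hourly directions from a von Mises law (any
  unimodal circular family would serve; concentration 0 = uniform, ∞ =
  point mass), speeds Weibull with shape 2 scaled to the requested mean,
  over a 6-year window by default.
* **Communities** (`make_survey`): per-transect relative covers from a
  Dirichlet draw over the syntaxa present; charophyte weights scale with
  exp(trophic_effect · z) in the standardised total-phosphorus value, so
  a negative effect reproduces the charophyte decline along the trophic
  gradient that the analyses are meant to detect. TP defaults to the
  0.015–0.049 mg l⁻¹ range of non-impacted lowland lakes, C_max to
  2.0–8.5 m. An optional planted indicator syntaxon restricted to one
  slope class supports power checks of the IndVal stage.

What the generators do *not* emulate: real shoreline complexity
(multi-lobed basins, non-star-shaped bays), multi-basin bathymetry,
spatial autocorrelation between neighbouring transects, depth-structured
within-transect zonation, observer error, and any coupling of community
composition to slope or exposure beyond what is explicitly planted.
Passing tests therefore show the *computational* pipeline is correct and
recovers planted effects at realistic scales — not that real communities
behave this way.

## Default study conditions

`run_config()` encodes the emulated campaign: 16 lakes with 8–27
transects summing to 260; lake radii 250–450 m and maximum depths 6–16 m
(typical of lowland morphometry); shore grades drawn from 2–25 % so the
pool spans all three steepness classes; TP drawn per lake from
0.015–0.049 mg l⁻¹; 6 years of hourly wind per lake; 999 IndVal
permutations. The pipeline grid resolution defaults to 4 m cells — a
full 16-lake run then takes well under a minute of raster work while
leaving dozens of cells per transect zone; the slope-recovery tests use
2.5 m cells on single lakes, where recovery of true slopes between 0.5°
and 16° is accurate to better than 0.1°. All stage seeds derive from the
single master seed, and a rerun with the same configuration is
bit-identical.

## Numerical choices and degenerate inputs

* Ray–segment intersection uses a 1e-9 m tolerance to exclude the origin;
  vertex pass-throughs are resolved by jittered re-casts.
* Point-in-polygon is the even-odd crossing rule; islands subtract.
* The deepest-contour and outside-shoreline extrapolations floor the
  contour gap at half a cell to avoid division blow-ups.
* `zonal_slope` errors on empty zones; `transect_zone` errors when the
  anchor is more than one cell off the shoreline and warns when the
  target depth is never reached (the zone then runs to the far shore).
* An LDM of directions whose resultant vector is (near-)zero — e.g. {0°,
  180°} — is reported as an error, not a number.
* Isobaths crossing the shoreline or each other are rejected at
  construction with the offending depth named.
* `indval_pvalue` uses p = (r + 1)/(n_perm + 1), so the smallest
  attainable p with 99 permutations is 0.01.

## Known limitations

* The contour interpolant is linear between contours; it will not
  reproduce curvature-continuous surfaces between widely spaced isobaths
  the way spline-based GIS interpolators do.
* Band-based bracketing assumes nested closed isobaths (true for simple
  basins); complex multi-basin contour sets fall back to the
  nearest-two-contours rule.
* The geometry stack is planar; inputs must already be in a metric
  projection.
* SIMPER is reported per group pair without the within-group similarity
  breakdown some software prints.
* Lake-level ESMI inputs (vegetated area N) must be supplied or derived
  from coverage; the package's synthetic derivation (colonisable area ×
  mean coverage) is one plausible convention, not a standard.
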