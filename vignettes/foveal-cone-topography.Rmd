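---
title: "Methods: foveal cone topography and its dependence on eye length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foveal cone topography and its dependence on eye length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveatopo)
```

## The problem

Myopic eye growth stretches the retina. Whether that stretching degrades the
eye's sampling of the visual world depends on two competing effects: cones
spread apart on the retina (linear density, cones/mm^2, falls), but the
longer eye also magnifies the retinal image (microns per degree of visual
angle rise). The quantity that governs resolution is the *angular* cone
density, cones/deg^2, and converting between the two unit systems requires a
personalised optical model of each eye. `foveatopo` implements the full
chain: a four-surface paraxial schematic eye for the retinal magnification
factor (RMF), sliding-window density mapping of labelled cone mosaics,
preferred-retinal-locus (PRL) and fixation-stability estimation, hexagonal
Nyquist sampling limits, and cohort-level regression of density on axial
length — plus a synthetic generator that embodies three competing eye-growth
models so every stage can be validated against known ground truth.

## The schematic eye and the retinal magnification factor

Angle-to-distance conversion on the retina is anchored at the eye's
*secondary nodal point* N': a paraxial ray aimed at the first nodal point
exits toward the retina at an unchanged angle, so retinal image size per
degree of visual angle is

I = tan(1 deg) * (x - AN'),

with x the axial length and AN' the distance from the corneal apex to N'
(both mm). The RMF in microns/degree is 1000 * tan(1 deg) * (x - AN').

Each eye's model uses three measured quantities (axial length, front
corneal radius, anterior chamber depth — the IOLMaster triplet) and fixed
Gullstrand-style constants for everything unmeasured:

| constant | value | note |
|---|---|---|
| corneal back radius | 88.31% of front radius | Gullstrand ratio |
| corneal index | 1.376 | |
| aqueous / vitreous index | 1.336 | |
| corneal thickness | 0.5 mm | |
| lens thickness | 3.6 mm | |
| lens radii | +10.0 / -6.0 mm | light travels +z; positive radius = centre of curvature to the right of the vertex |
| lens equivalent index | **1.400** | calibrated, see below |

The crystalline lens is a homogeneous equivalent-index element. The
textbook equivalent index 1.416 reproduces the reference cohort's published
RMF column with a mean relative error of +0.41% (max 0.47%). We performed a
one-time calibration of this single constant against the 28 published
RMF values and fixed it at 1.400, which zeroes the mean residual
(max |error| 0.31%). No other constant was tuned, and the calibration was
not revisited afterwards. Anterior chamber depth is interpreted as corneal
front apex to lens front apex, so the aqueous gap is ACD minus the corneal
thickness.

Cardinal points come from two paraxial ray traces (a parallel ray and its
reverse) rather than matrix algebra; the two formulations are equivalent
and the trace doubles as the engine for the nodal-ray invariance test
(`trace_paraxial_ray()`). Systems with zero equivalent power have no nodal
point and are refused. `build_reduced_cornea_eye()` merges the two corneal
surfaces into one of equal power; it moves AN' by well under 0.2 mm,
which is why fancier corneal models add nothing here.

Bennett's classical reduced-eye shortcut, RMF = 1000 * 0.01306 *
(x - 1.82), is provided for comparison (`bennett_rmf()`; the constants come
from the cited reduced-eye literature since they are conventions, not
measurements). Because it assumes the focal point sits on the retina it
overestimates the RMF of hyperopic eyes and underestimates long myopic
eyes on average — though individual long eyes with unusually flat corneas
(two in the reference cohort, corneal radii 8.72 and 8.98 mm) buck the
per-eye trend.

## Density mapping

A cone mosaic is a set of labelled cone centres in image pixels with a
scale in pixels/arcmin (9.48 by default, the native scale of the imaging
system the reference data came from). Density at a point is the count of
cone centres falling **on or within** the boundary of a 10-arcmin-diameter
circular window, divided by the window area; `density_map()` slides this
window across a regular pixel grid. Design choices worth stating:

* **Edge handling.** Windows crossing the image boundary are flagged
  invalid, never area-corrected. The imaged region in practice extends
  beyond the analysed central field, so interior-only analysis loses
  nothing and avoids edge-correction bias.
* **Unit consistency.** Linear density is derived from the angular window
  by exact unit conversion, D_mm2 = D_deg2 / (rmf/1000)^2, cell for cell.
  An alternative `unit_mode = "micron"` fixes the window's *physical*
  diameter across eyes (10 arcmin at a nominal 300 um/deg, i.e. 50 um)
  instead; the published reference table appears to mix the two
  conventions — its PRL density pairs are exactly unit-consistent while
  its peak pairs disagree by up to 1.6%, consistent with the angular and
  linear peak maps each reporting their own peak location. Both modes are
  provided; neither is asserted as "the" original.
* **Peak ties.** `find_peak()` resolves exact ties by the centroid of the
  maximal set, so a constant map peaks at the centre of its valid region.
* **Annuli.** Eccentricity profiles use 5-arcmin or 25-micron annuli
  around the density peak. Membership is inner-exclusive / outer-inclusive
  with the innermost disk including its centre; the boundary rule is a
  convention (the counting rule only fixes the window case) and is pinned
  by a dedicated test.
* **Grid step.** The formal default is 1 px; the analyses and tests use
  4-10 px steps, which change peak estimates by far less than the window
  averaging itself (the window spans ~95 px).

## PRL and fixation stability

The PRL is the centroid of the fixation scatter. Stability is the
bivariate contour ellipse area (BCEA) at 68% coverage. "The ellipse
containing 68% of the points" is ambiguous between two estimators, and
both are implemented:

* `method = "covariance"` (default): scale the sample-covariance ellipse
  by k = qchisq(0.68, 2) = 2.279, giving BCEA = pi * k * sqrt(det(S)).
  The k constant is computed from the chi-square quantile at the requested
  coverage, never hard-coded, so other coverages work unchanged.
* `method = "empirical"`: dilate the covariance ellipse until it contains
  exactly ceiling(0.68 n) points.

For Gaussian scatter the two agree asymptotically; for heavy-tailed
fixation traces the empirical mode is larger. Degenerate traces (all
points collinear or identical) return BCEA = 0 with a warning rather than
failing, since they are legitimate limiting data. No temporal filtering or
outlier rejection is applied to traces. BCEA in um^2 is the arcmin^2 value
times (rmf/60)^2, exactly.

## Sampling limits

For hexagonal packing the Nyquist limit and centre-to-centre spacing are

N = (1/2) * sqrt(2 D / sqrt(3)) cyc/deg,  s = 60 / (sqrt(3) N) arcmin,

so that a lattice with spacing s has density 2/(sqrt(3) s^2) — the round
trip is exact and tested to machine precision. Applied to the reference
cohort these reproduce every published range endpoint (mean 64.9 cyc/deg
at the peak; 62.5 mean and 50.4 minimum at the PRL; 0.69 arcmin maximum
spacing) to within 0.5%; the single published "59.1" lower endpoint
evaluates to 58.9 from the tabulated minimum density, a 0.3% discrepancy
we attribute to rounding in the original pipeline and report as computed.
The Snellen conversion 20/(20 * 30 / N) via the primary spatial frequency
of a letter E is labelled approximate and used only descriptively.

## Cohort statistics

`ols_fit()` is simple linear regression (via `stats::lm`) reporting the
slope, its t-based 95% CI and two-sided p-value (n - 2 df), and r^2; it is
validated against hand-rolled normal equations and the textbook interval
formula at 1e-10 relative tolerance. Both eyes of a subject are pooled as
independent observations in the headline fits — a deliberate statistical
caveat matched by `one_eye_sensitivity()`, which reruns the four headline
regressions on one eye per subject (right-preferred, left-preferred,
first, or seeded random selection) and confirms the slope signs survive.
No multiple-testing correction is applied. The slope-detection sample size
uses the normal-approximation (Dupont-Plummer) formula; the predictor SD
defaults to 1.65 mm, the value consistent with the published power inputs,
and is exposed as a parameter.

Reproducing the published regressions from the *printed* per-eye table has
one caveat: the original fits were evidently run on unrounded spreadsheet
values, while the table prints densities to 1 cone and axial lengths to
0.01 mm. Slopes reproduce within 1% (749 -> 756; 759 -> 759.4;
-8,490 -> -8,489), but the peak-linear r^2 computes to 0.417 against a
published 39%, and the peak-angular CI to (308, 1204) against a published
(304, 1193). We report what the printed table yields. The published
peak-linear slope "-3,185 (CI -4,578 to -13,793)" is internally
inconsistent (the slope lies outside its own CI, presumably a typo); the
table yields -9,902 (CI -14,619 to -5,184).

## The synthetic generator

`generate_mosaic()` produces quasi-hexagonal point sets by variable-density
dart throwing: candidates drawn uniformly over the field, processed in
order of increasing (anisotropy-weighted) eccentricity, and accepted when
no accepted cone lies within c * s_hex(D(x, y)), where s_hex is the
hexagonal spacing of the local target density

D(r) = peak / (1 + (r / r0)^gamma),  r = sqrt(x^2 + (anisotropy * y)^2).

Two implementation constants were fixed once during development and are
not exposed as dials:

* **Packing factor c = 0.865.** Dart throwing saturates below hexagonal
  density, so the minimum distance must be tightened relative to the
  target spacing. c was calibrated on constant profiles at the default 30
  attempts per candidate (achieved/target ratio 0.997 across seeds) and
  verified to hold within 5% on radial profiles.
* **Candidate budget scaled by the peak density.** With uniform candidates
  a radially falling profile starves its dense centre of attempts and
  leaves it ~5% under-packed; budgeting attempts against the *peak*
  density restores the full budget everywhere (excess candidates in
  sparse regions are simply rejected).

Profile defaults (r0 = 30 arcmin, gamma = 1.2, anisotropy = 1.15 with the
steeper falloff vertical) qualitatively mimic real foveal falloff and its
superior/inferior steepness; they are test fixtures, not biological
claims. What the generator does *not* emulate: cone-size gradients,
imaging noise and label errors, Voronoi-regularity statistics of real
mosaics, or any biomechanics of cone migration. Passing
generator-recovery tests therefore demonstrates the correctness of the
measurement chain, not the realism of the point process.

`generate_cohort()` embodies the three growth models. With the anterior
segment fixed at the baseline biometry (AL 23.5 mm, r 7.8 mm, ACD 3.6 mm)
and RMF from the ray trace:

* **global expansion** — angular density constant; linear density falls;
* **equatorial stretching** — linear density constant; angular density
  rises;
* **over-development** — linear density rises as exp(gain (AL - 23.5)),
  angular density rises faster;
* **mixed** — log-angular density interpolated between the first two,
  D_ang = D0 (rmf/rmf0)^(2 mix); `mix = 0.42` lands the angular slope
  near +750 cones/deg^2 per mm, the regime the reference cohort occupies.

Axial lengths are uniform over the requested range; measurement noise is a
single multiplicative log-normal factor per eye applied to both unit
systems, keeping them exactly consistent (as a shared counting error
would). Paired eyes of a synthetic subject are independent draws, unlike
real inter-eye correlation — another reason the one-eye sensitivity check
exists. Each cohort carries its noiseless OLS slopes as attributes, the
injected ground truth for recovery experiments.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; the same seed
reproduces mosaics, traces and cohorts exactly, and pipeline reports carry
a config hash and seed. The test suite uses mosaics of roughly 1,500-9,000
cones (fields of 15-60 arcmin), fixation traces of 200-20,000 frames, and
a 1,000-replicate slope-recovery simulation at 28 eyes and 8% noise; at
these sizes the whole suite runs in about a minute. The replicate count
was set so the Monte-Carlo error of the coverage estimate (~0.7%) is small
against the 93% acceptance bound (true coverage measured once at 2,000
replicates: 94.6%).

## Known limitations

* The paraxial model ignores accommodation, astigmatic and toric
  surfaces, chromatic dispersion and exact (non-paraxial) ray paths; it
  is a magnification model, not an image-quality model.
* Cone *detection* is out of scope: coordinates are an input, and label
  quality propagates directly into densities.
* BCEA summary statistics of real fixation traces depend on raw data not
  shipped here; only the estimator itself is validated (closed form,
  containment, invariances).
* The printed-table rounding issues above mean second-decimal agreement
  with the original regression inference is not attainable from the
  shipped fixture.
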