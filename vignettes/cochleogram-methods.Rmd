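---
title: "Methods: from annotated cochlear whole-mounts to transduction-rate profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from annotated cochlear whole-mounts to transduction-rate profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleogram)
library(dplyr)
```

## The problem

Viral gene delivery to the inner ear is mosaic: within each cell type of the
organ of Corti, only a fraction of cells express the delivered transgene, and
that fraction varies systematically along the cochlea from base to apex
(mirroring, among other things, the basal-to-apical wave of hair-cell
differentiation). Summarizing an experiment by a single "percent transduced"
number hides this structure. The quantity of interest is a *longitudinal
transduction-rate profile*: for each cell type (inner hair cells IHC, outer
hair cell rows OHC1–OHC3, and optionally supporting-cell types), the fraction
of cells transduced as a function of arc-length position along the cochlear
spiral.

The raw data are point annotations: an operator clicks the centers of
reporter-positive cells in a stitched whole-mount confocal image (e.g. with
the Fiji multipoint tool), labels each point with its cell type, and
delineates the cochlear axis as an ordered base-to-apex polyline along the
organ of Corti. Untransduced cells are never clicked; totals come from
reference cell densities instead. This package turns those annotations into
profiles and provides the statistical comparisons applied to them.

## Pipeline model

1. **Axis fit.** A parametric cubic spline (natural boundary conditions,
   chord-length parameterization) is fitted through the polyline control
   points — interpolating by default, because the delineation *is* the
   operator's statement of where the axis runs. A dense evaluation table
   (≤ 1 µm steps) accumulates arc length by chord summation, mapping any
   position on the curve to a longitudinal coordinate $s \in [0, L]$ with
   base at 0. The chord-summation error is $O(\mathrm{step}^2/R)$ and is
   negligible at cochlear curvature radii (hundreds of µm).

2. **Projection.** Each annotated cell is assigned the $s$ of its globally
   nearest point on the curve (global search over the dense table, refined
   on the adjacent chord segments). Because the cochlea is a spiral, a
   naive local search could land on an adjacent turn; the global search
   plus an acceptance gate on the point-to-curve distance (default 150 µm,
   well below the inter-turn spacing but above the width of the
   organ-of-Corti band) makes misprojection *detectable*: cells beyond the
   gate are rejected and counted per type, never silently misplaced.
   Equidistant ties resolve to the smaller $s$; points projecting past the
   ends are clamped to $[0, L]$ with distance measured to the endpoint.
   Projection is invariant to rigid motions of the image frame and to the
   image y-axis pointing down: arc length and distances do not care about
   axis flips, so no coordinate normalization is applied.

3. **Smoothing (the cochleogram).** The per-type longitudinal coordinates
   $s_i$ are smoothed with a unit-mass Gaussian kernel of standard
   deviation $\sigma$ (default 250 µm, about 1/20 of the cochlear length):
   $$\lambda(x) = \sum_i \varphi_\sigma(x - s_i),$$
   giving a density in cells/µm on a regular grid (default 10 µm ≪ σ;
   linear interpolation between grid points). The unit-mass (density)
   normalization rather than unit-peak is what makes the next step
   dimensionally meaningful: reference densities are stated in cells per
   100 µm, so only a density can be divided by them.

4. **Boundary correction.** Near the base and apex part of each kernel's
   mass leaks outside $[0, L]$, biasing the raw estimate downward by up to
   a factor 2 at the ends. The correction reflects each kernel at both
   domain ends ($s_i \mapsto -s_i$ and $s_i \mapsto 2L - s_i$), restoring
   the leaked mass in place. Among the standard one-dimensional KDE edge
   corrections, reflection is the one that simultaneously (i) conserves
   the per-type cell count essentially exactly for *any* cell arrangement
   ($\int_0^L \lambda \approx n$ to numerical precision — the tests verify
   this to well below 0.5 %), (ii) keeps $\lambda \ge 0$, and (iii)
   leaves an equally spaced arrangement exactly flat. The two rescaling
   alternatives fail one of these: dividing by the in-domain kernel mass
   at the evaluation point preserves flat profiles but loses ~1 % of the
   cells when they concentrate near the base (a realistic scenario for
   embryonic injections), while dividing each kernel by its own in-domain
   mass conserves counts but inflates a uniform density by tens of percent
   at the very edge. Reflection's own cost is a zero-slope bias within
   ~2σ of the ends for sloped profiles, which is why calibration
   statements in the tests are restricted to the interior (≥ 2σ from both
   ends). Correction defaults on and can be switched off for comparability
   studies.

5. **Fraction conversion.** Dividing by the reference longitudinal
   density of the cell type, $f(x) = \lambda(x)\,/\,(\mathrm{ref}/100)$,
   yields the transduction rate. The package ships the neonatal (P0)
   hair-cell values (cells per 100 µm): IHC 11.8, OHC1 13.7, OHC2 13.9,
   OHC3 14.1. No reference values exist for supporting-cell types; they
   must be supplied explicitly — there are deliberately no silent
   defaults. Fractions are *not* clamped at 1: over-unity values mean the
   local density exceeded the reference (annotation duplicates, a
   miscalibrated pixel size, or genuine local crowding) and are surfaced
   as warnings above 1.05.

6. **Fragment merging.** Dissected cochleas are sometimes cut into
   pieces, each annotated in its own frame. Given the pieces in explicit
   base-to-apex order (never inferred), coordinates of piece $j$ are
   offset by $\sum_{m<j} L_m$ and a single cochleogram is computed on the
   concatenated domain. The only information lost at the cut is the
   within-±2σ neighbourhood of the cut position, where each fragment's
   boundary correction operates on a half-window; away from the cut the
   combined profile matches the uncut analysis (verified to < 0.05
   absolute in the tests).

## Statistics

Two tests are provided, matching how such profiles are compared in
practice:

* **Profiles:** a two-sample Kolmogorov–Smirnov test on the empirical
  distributions of the transduced-cell longitudinal coordinates — the data
  the profiles are built from. The KS test is deliberately *not* applied to
  the smoothed grid values: those are heavily autocorrelated (σ ≫ grid
  step), so their empirical distribution does not consist of independent
  observations and the KS null distribution would not apply. Left/right or
  cross-animal comparisons default to relative coordinates ($s/L$), since
  cochlear lengths differ between specimens.
* **Mean values:** Welch's unequal-variance $t$-test (Welch–Satterthwaite
  degrees of freedom, two-sided), for per-cochlea summaries such as
  segment counts or peak rates. Segment counts default to three
  equal-length segments, matching the base/mid/apex vocabulary; segments
  are half-open $[kL/n, (k+1)L/n)$ with the apex point included in the
  last.

Peak summaries report the per-type maximum of the profile and its location
(first grid point on ties); collections of peaks across cochleas reduce to
mean ± SEM. No multiple-testing correction is applied.

## The synthetic-cochlea generator

Because the pipeline's accuracy cannot be judged on manual annotations
without ground truth, the generator produces complete datasets with known
truth:

* **Geometry:** an Archimedean spiral (constant radial pitch, default two
  turns, inner radius 200 µm and pitch 300 µm before rescaling) scaled to a
  target arc length of 5700 µm — a typical neonatal mouse cochlear length.
  The emitted axis polyline samples the spiral every 50 µm, mimicking an
  operator's clicks.
* **Cells:** one row per cell type at a small lateral offset from the axis
  (IHC medial at −10 µm; OHC1–3 lateral at 8, 16, 24 µm), placed along arc
  length either equally spaced at the type's density or as a homogeneous
  Poisson process, with isotropic Gaussian positional jitter (default
  2 µm, enough to be realistic while keeping rows distinct).
  Supporting-cell rows can be added with user-supplied densities; the test
  suite uses a pillar-cell-like 13 per 100 µm, a synthetic-only value.
* **Transduction:** each cell is independently Bernoulli-transduced with
  probability $p(s)$ from a named family — `constant`, `linear`,
  `logistic` (basal-peaked decline, the shape typical of embryonic
  injections; mirrored parameters give an apical-rising profile) and
  `gaussian_bump` (mid-cochlea maximum). Families are parameterized in
  relative position and clipped to $[0, 1]$.
* **Output:** only transduced cells are written as annotations, mirroring
  real data where untransduced cells are never clicked; the full truth
  (every cell, its generative pre-jitter arc-length position, its
  transduction flag, its fragment) is returned separately. Identical spec
  and seed reproduce all files byte-identically.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: annotation errors (missed or double-clicked
cells, mistyped rows), operator variability in delineating the axis,
nonuniform true cell densities (the reference densities in real tissue
vary somewhat along the cochlea and between animals), row curvature
irregularities at the extreme base/apex hooks, and any imaging artefacts.
The generator validates the *computation*, not the annotation process.

## Validation performed by the test-suite and acceptance script

Problem sizes were chosen to exercise the estimator at realistic scale
while keeping a full run in the order of a minute: full pipelines on
5700 µm cochleas with ~670–800 cells per row (10–20 seeds × 4 profile
families), 1000-point projection oracles at 0.25 µm brute-force
resolution, and 500-replicate null calibrations of both tests. The checks
are: count conservation of the corrected cochleogram; projection against
brute-force nearest-point search and analytic arc lengths; recovery of
every profile family to a mean absolute error below 0.05 in the interior;
full-transduction calibration (p ≡ 1 reads out 1.00 in the interior);
fragment-combination equivalence; KS/Welch type-I error within binomial
tolerance of 5 % and KS power distinguishing basal-peaked from
apical-rising samples; and byte-level reproducibility.

## Design choices on genuinely open points

* The spline is interpolating by default (the operator's polyline is
  treated as authoritative); a smoothing option exists but deviations from
  control points beyond 2 µm trigger a warning.
* The Gaussian window is normalized to unit mass, not unit peak — the
  alternative rescales every profile by $\sigma\sqrt{2\pi}$ and makes the
  reference-density conversion dimensionally inconsistent.
* The KS test operates on raw coordinates rather than binned or resampled
  profiles (see Statistics above).
* Calibration (µm per pixel) is a required explicit input: annotation
  files may be in image coordinates, and a 250 µm window is only
  meaningful in physical units.

## Known limitations

* The pipeline is two-dimensional, appropriate for maximum-intensity
  projections of whole-mounts; strongly non-planar preparations would need
  a 3D axis.
* Transduction rates inherit any error in the reference densities; these
  are treated as externally measured constants.
* Near the cut position of fragmented cochleas (±2σ), profiles are
  smoothed within fragments only and should not be over-interpreted.
* The KS comparison pools cells across hair-cell types by default;
  per-type comparisons need the per-type coordinate subsets (supported,
  but with correspondingly fewer cells per test).
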