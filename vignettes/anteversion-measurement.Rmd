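---
title: "Measuring femoral stem anteversion from proximal-femur geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral stem anteversion from proximal-femur geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemversion)
```

## The measurement problem

In total hip arthroplasty (THA) for developmental dysplasia of the hip
(DDH), the anteversion of the implanted femoral stem (PSA) largely
determines whether the combined cup-plus-stem anteversion lands in the safe
zone.  With the femur-first technique the surgeon needs a *preoperative*
prediction of where the stem will end up.  Three landmark-based predictors
are in clinical use, all measured as signed angles against the posterior
condylar axis (PCA) in the axial plane:

* **AM-CT** — the midcortical line (the angular bisector of lines fitted to
  the anterior and posterior cortical walls) on an axial CT slice taken 5 or
  10 mm proximal to the lesser-trochanter apex;
* **AM-3D** — the line connecting the centers of circles fitted to the two
  margins of the simulated neck-osteotomy surface on a 3D bone model;
* **AT-3D** — the T-line, from the trochanteric fossa to the point where the
  osteotomy-plane midcortical line crosses the inferior contour margin (the
  IMI point).

This package implements all three measurements plus PSA itself (the stem
neck axis against the PCA), the cohort statistics used to compare them
(mean differences, t-tests, Pearson correlations, intraclass correlation
coefficients), and a constructive synthetic femur generator with exact
ground truth, so the whole pipeline can be validated end to end without
patient data.

## Coordinate frame and sign conventions

The anatomical frame is built from eight named landmarks
(`build_femoral_frame()`):

* **SI** is the unit vector from the epicondyle midpoint to the femoral head
  center (superior positive);
* **ML** is the component of the lateral-to-medial posterior-condyle vector
  orthogonal to SI (medial positive);
* **AP** is `ML x SI` (anterior positive), making `(SI, AP, ML)` a
  right-handed triad.

All angles are computed by `axial_projected_angle()`: both vectors are
projected into the axial plane and the signed angle is the two-argument
arctangent in the 2D `(ML, AP)` coordinates.  A consequence of the
right-handed triad above is that `ML x AP = -SI`, i.e. the positive sense of
these 2D coordinates is rotation about *minus* SI; we define the angle in
the 2D chart precisely so that anteversion — the medial end of a line tipped
anteriorly — is positive on a right hip, matching how anteversion is
reported clinically.  Left hips are mirrored through their own sagittal
plane on load (`canonicalize_side()`), so a single sign convention covers
both sides; mirroring is an exact involution and mirror twins measure
identically (this is asserted by the test suite to 1e-6 degrees).

## The axial-slice measurement (AM-CT)

`am_ct()` composes five stages:

1. `extract_cross_section()` cuts the surface mesh with the axial plane at
   `height_mm` above the lesser-trochanter apex.  Intersection points are
   interpolated along mesh edges and chained into closed loops through
   shared-edge adjacency; the largest-area loop is the femoral section
   (smaller loops, e.g. a partially attached lesser trochanter, are dropped
   with a warning).  Contours are oriented counter-clockwise in `(ML, AP)`.
2. `classify_cortex_arcs()` selects the anterior and posterior cortical
   walls: the contiguous contour runs whose outward normals lie within a
   ±40° window of the two window centers, with at least 5 points each.
3. `fit_cortex_line()` fits each wall by total least squares (the principal
   direction of the centered points) — there is no natural dependent
   variable on a contour, so orthogonal regression is the right model.
   Near-isotropic point sets (principal-axis ratio < 1.05) are rejected.
4. `midcortical_line()` bisects the two walls: directions are co-oriented,
   summed and normalized; the anchor is the midpoint of the two anchors.
5. The bisector is measured against the PCA with
   `axial_projected_angle()`.

**Where the cortex windows point.**  The conventional description centers
the two normal windows on ±AP.  That rule cannot follow a strongly
anteverted neck: the selected arc is then always centered where the contour
normal is anterior, so its tangent — and hence the fitted wall — is pulled
toward the ML axis regardless of how far the section is actually rotated.
On rotated elliptical sections the resulting bisector underestimates a 60°
anteversion by tens of degrees, for any window width and any eccentricity.
We therefore re-center the windows by default on the section's own
principal axis (window centers at the principal direction ±90°), which is
what a human reader effectively does when tracing the cortical walls of a
rotated section; for a rotated ellipse this recovers the major axis exactly,
by symmetry.  Sections too round to have a meaningful principal axis
(ratio < 1.05) fall back to the AP-referenced windows.  Both the window
width and the reference are arguments (`window`, `reference`), so the pure
±AP convention remains available.

`slice_from_image()` provides the same section from a voxel image (a
pseudo-CT): the nearest grid plane is binarized and the 0.5-level
iso-contour extracted with `grDevices::contourLines()`.  On the synthetic
femur, mesh slicing and image slicing at CT-like spacing
(0.98 × 0.98 × 1 mm) agree on AM-CT to within 2°.

## The 3D-model measurements (AM-3D, AT-3D)

`build_osteotomy_plane()` simulates the neck cut: the plane through the
center of the piriformis fossa and the *calcar point* (the most medial point
of the axial section at the cutting height).  Two points do not fix a
plane; as the third constraint we require the plane to contain the AP
direction, which makes the simulated cut anterior–posterior symmetric, as a
surgical neck cut is intended to be.  The normal is oriented proximally.

`plane_contour()` returns the cut surface outline with an orthonormal
in-plane chart: `v` is the in-plane projection of SI (superior positive)
and `u` completes the chart.  Because the plane contains AP, `u` is exactly
±AP — the cut has no independent "in-plane medial" axis; the in-plane
projection of ML is anti-parallel to `v`.  Consequently the medial and the
inferior margins of this cut coincide at the inferomedial (calcar) corner.
`am_3d()` therefore fits its two margin circles (`fit_margin_circle()`,
Kåsa algebraic fit refined by Gauss–Newton geometric least squares on
60°-wide arcs) at the two ends of the cut: the wedge of contour around the
direction from the contour centroid to the calcar anchor (the
inferomedial/medial margin), and the wedge around the opposite direction
(the superolateral end).  For a symmetric neck these are exactly the −v and
+v extremes and the measurement is exactly zero at zero anteversion; at
higher anteversion the calcar anchor rotates with the bone, so the arcs
track the neck.  The midcortical line is the 3D line through the two circle
centers, measured against the PCA in the axial plane.

`imi_point()` intersects that midline with the contour polygon and keeps
the crossing with the smaller `v` (ties break to the more medial crossing,
by 3D ML coordinate).  `at_3d()` connects the trochanteric fossa landmark
to the IMI point and measures that T-line against the PCA.  Because the
trochanteric fossa is posterior, the T-line systematically reads higher
than the midcortical measures — the synthetic DDH femur reproduces this
ordering, as does the published cohort.

**Known limitation.**  Above roughly 55° of true anteversion the
AP-containing cut becomes nearly perpendicular to the neck axis, the cut
outline approaches a circle, and the two margin-circle centers converge;
the midline direction is then ill-conditioned (the pipeline reports a
degenerate-midline error, and `measure_subject()` records `NA` with a
warning).  This mirrors the clinical observation that the 3D-model measures
are the less reliable predictors; extreme DDH anteversion is exactly where
the simulated-osteotomy landmarks stop being trustworthy.

## The synthetic femur

`generate_femur()` is constructive solid geometry swept along the SI axis:
every horizontal section is an analytic ellipse (or a union with the head
sphere), so landmarks and ground truth are exact by construction rather
than annotated.  The zones are:

* distal shaft — a circle of radius `shaft_radius` (default 14 mm);
* calcar zone, from 5 mm below to 14 mm above the lesser-trochanter apex —
  a fixed ellipse elongated along the neck azimuth (semi-axes
  `neck_radii[2]/sin(nsa - 90°)` ≈ 20 mm by 13 mm for the defaults).
  Holding this zone z-invariant makes the 5 mm and 10 mm measurement levels
  see identical geometry, and makes AM-CT exactly invariant under uniform
  scaling of the bone;
* neck — horizontal sections of an elliptical cylinder tilted by the
  neck-shaft angle (default 130°) and rotated about SI by the native
  anteversion `nfa_deg`;
* head — a 22 mm sphere centered on the neck axis.

The azimuthal triangulation alternates quad diagonals by column parity so
that a zero-anteversion bone is a mirror-symmetric *mesh*, not just a
mirror-symmetric surface — the symmetry assertions in the test suite are
exact because of this.  The trochanteric fossa is placed posterior of the
lateral extreme by `fossa_posterior_offset` (default 6 mm) of surface arc,
emulating the DDH-typical posteriorized fossa; the piriformis fossa sits
8 mm of arc posterior of the lateral extreme at 20 mm height.  Condylar and
epicondylar landmarks are emitted 380 mm distally with the epicondyle
midpoint exactly under the head center; `condylar_torsion_deg` rotates the
PCA so frame construction and measurement stay decoupled from the neck.

`generate_stem()` anchors the stem neck axis at the neck-base canal center
with a configurable inclination (default 40° out of the axial plane) and an
azimuth set directly from the requested stem anteversion, so
`psa_from_stem()` round-trips the truth to numerical precision.

Two cohort generators emulate a study population:

* **geometric** (`generate_geometric_cohort()`): native anteversion drawn
  from a normal with the cohort PSA moments (mean 29.8°, SD 17.7°),
  truncated to [−10°, 70°] to span Crowe I–IV-like deformity; per-subject
  sizes jittered by 3% relative SD; stem anteversion = native anteversion
  plus N(0, 5°) noise, standing in for the intraoperative press-fit
  deviation.  Every subject carries its mesh, landmarks, stem axis and
  truth.
* **statistical** (`generate_statistical_cohort()`): per hip, PSA is drawn
  from N(29.8, 17.7²) and each method angle from the bivariate normal
  implied by the shipped calibration table
  (`inst/extdata/table2_reference.csv`: per-method mean, SD and correlation
  with PSA), via the conditional-normal construction.  The implied
  difference SDs then emerge on their own and match the published ones to
  within rounding, which is a useful internal-consistency check of the
  calibration.

What the generator does *not* emulate: real cortical texture, Crowe-specific
shape deformity beyond parameter ranges, CT intensity (the pseudo-CT is
binary occupancy), metal artifact, or segmentation error.  Passing tests on
synthetic bones therefore demonstrate the geometric correctness and the
statistical behaviour of the pipeline, not its accuracy on real scans.

## Statistics layer

`summarize_cohort()` renders one row per (method, height): angle mean ± SD,
mean difference versus PSA (MD = method − PSA) with its SD, a t-test
p-value, and the Pearson correlation with PSA with its p-value, computed on
pairwise-complete hips.  The default t-test is the paired test on per-hip
differences (the hips are the same); the two-sample equal-variance form is
available via `t_test = "two_sample"` — worth noting because published
tables of this kind are sometimes computed with the unpaired form, which is
reproducible here from the group means and SDs alone.  `pearson_with_p()`
uses the exact t transform on n − 2 degrees of freedom.
`icc_absolute_agreement()` implements single-rater ICC(2,1) (two-way
random, absolute agreement) from the two-way ANOVA mean squares, with
ICC(3,1) by flag; absolute agreement is the standard choice for
method-reliability questions.  P-values below numerical resolution render
as "0.000" in the printed table while the exact values stay in the data
frame.

## Numerical choices and problem sizes

* Mesh–plane intersection nudges near-coplanar vertices by a relative
  tolerance (1e-9 of the distance spread) so that rigid motions of meshes
  with exactly coplanar vertex rings are handled identically; consecutive
  duplicate intersection points are merged.
* Circle fitting starts from the closed-form Kåsa solution and runs at most
  50 Gauss–Newton steps to a 1e-12 step tolerance.
* Default mesh resolution is 72 azimuthal segments (5° steps, even so the
  alternating triangulation closes); the resolution-doubling test bounds the
  AM-CT change at 0.5°.
* The validation suite uses cohorts of 3–200 bones and statistical cohorts
  of up to 10,000 hips; these sizes recover configured moments to within 2%
  and correlations to within 0.03, and run in well under a minute.
* Replicate analyses at the study size use 100 cohorts of n = 28.  At that
  size the sampling SD of a correlation's Fisher z is about 0.2, so
  adjacent method correlations (e.g. 0.92 vs 0.86) exchange ranks in a
  substantial minority of replicates; the mean correlations over replicates
  reproduce the calibrated ordering even though any single 28-hip cohort
  need not.

## Worked example

```{r example, eval = FALSE}
library(stemversion)

fem <- generate_femur(femur_spec(nfa_deg = 30))
frame <- build_femoral_frame(fem$landmarks)
am_ct(fem$mesh, frame, fem$landmarks, height_mm = 10)
#> AM-CT @ 10 mm: 30.0 deg

cohort <- generate_statistical_cohort(
  cohort_spec(n = 28, mode = "statistical", seed = 42))
summarize_cohort(cohort)
```
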