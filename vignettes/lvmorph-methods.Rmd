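---
title: "Quantifying post-infarction remodelling in light-sheet imaged hearts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-infarction remodelling in light-sheet imaged hearts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmorph)
```

## The measurement problem

Whole cleared mouse hearts imaged by light-sheet fluorescence microscopy
yield two channels on a common anisotropic voxel grid: an autofluorescence
(structure) channel showing the myocardium, and a lectin channel labelling
perfused blood vessels. After coronary-artery ligation the left ventricle
(LV) remodels: the chamber dilates, the apical wall thins into scar, and
microvessel density drops in and around the infarct. `lvmorph` turns a pair
of such volumes into the quantitative endpoints of that remodelling process:

* diastolic LV chamber volume and a diastole quality filter,
* the **apical conicity index** and apex volume (chamber-shape dilation),
* the surface **mean-curvature distribution** of the apical chamber
  (papillary/trabecular imprint loss and outward bulging),
* per-voxel **local wall thickness** by maximal inscribed spheres, the
  thin-wall (infarct) volume, and the three-zone partition of the wall
  (infarct < 300 µm, border 300–500 µm, remote > 500 µm),
* **zone-stratified vascular density** from a multiscale tubularity filter,
* group statistics: one-way ANOVA with Tukey–Kramer post hoc comparisons,
  two-tailed t-tests, Pearson correlation and percent-change summaries.

All internal lengths are micrometres; volumes are converted to mm³ only at
the reporting boundary. Arrays use the fixed axis order (z, y, x) with
voxel-centre coordinates `(index − 1) × spacing`.

## Synthetic phantoms are the test substrate

No public imaging data accompanies the method, so every stage is validated
against seeded synthetic phantoms with exact voxel-level ground truth.

`generate_heart_phantom()` builds a whole-heart phantom: an analytic chamber
solid (cone, capped cone, or prolate ellipsoid — the cone is the calibration
anchor for which the conicity index must be 1), a myocardial shell whose
thickness follows a configurable sector profile, an optional open valve
plane at the base, and noisy rendered channels. Defaults emulate the
diastolic regime of a cleared mouse heart: a chamber of roughly 12–16 mm³
(cleared hearts shrink, so this sits at the lower end of in vivo values),
wall thickness spanning 250–600 µm, Gaussian readout noise, and 40 µm
isotropic voxels. That spacing is an analysis-scale choice: it resolves
every chamber-shape and wall-thickness endpoint while keeping a whole heart
near 150³ voxels. The microscope's native sampling (7 µm optical sections,
~1.6 µm in plane) would put a whole heart beyond 10⁹ voxels, which buys
nothing for geometry tests; anisotropic handling is instead verified
explicitly (the distance transform and Gaussian derivatives work in
physical units on any spacing).

Capillary-size vessels (lumen diameter < 10 µm) cannot exist on a 40 µm
grid, so vascular endpoints use a second generator.
`generate_zone_phantom()` builds stacked tissue slabs at 4 µm spacing whose
thicknesses realise the three wall zones exactly (250/400/600 µm; slabs
span the full lateral grid, which makes the designed thickness equal the
maximal-sphere local thickness at every voxel), and fills each slab with
seeded random vessel tubes until the zone's target volume fraction is met —
the final tube is truncated so the achieved fraction lands within ±0.5
percentage points of target, typically exactly on it. The default fractions
(7 / 18.9 / 21.9 % of tissue volume in infarct / border / remote) encode the
vehicle-group regime of the post-infarction study the pipeline addresses.
Tubes are straight capsules with isotropic random directions: sufficient
for density and tubularity-filter testing; branching topology, light-sheet
stripe artifacts and optical attenuation are deliberately not modelled, so
passing tests demonstrate correct measurement of the stated geometry, not
robustness to every acquisition artifact of real data.

Both generators are deterministic given (spec, seed).

```{r phantom, eval = FALSE}
spec <- phantom_spec(chamber_shape = "capped_cone",
                     wall_profile = wall_profile_infarct(),
                     base_opening = TRUE, aperture_radius_um = 400,
                     seed = 11)
ph <- generate_heart_phantom(spec)
ph
```

## Chamber segmentation and diastole QC

`tissue_mask()` reproduces the classical pre-segmentation: global Otsu
threshold, one-voxel opening, largest 26-connected component, filling of
small enclosed cavities (the chamber itself, being large, survives). The
published workflow used a learned (U-net) chamber segmenter; no annotations
are distributable, so `segment_chamber()` provides a classical segmenter
honouring the same mask contract, and externally produced chamber masks can
be passed straight into the morphometry. The basal valve opening is capped
by morphological closing with a Euclidean ball (default 1 mm diameter,
chosen to exceed the open valve plane); the chamber is the largest enclosed
cavity (6-connected background component not touching the grid boundary).
Because closing also fills narrow cavity recesses — it would truncate the
sharp apex of a conical chamber — the cavity is then geodesically
reconstructed over the original complement, excluding everything connected
to the outside, which restores the apex while keeping the base sealed.
Ties in "largest component" break deterministically by scan order.

`diastole_qc()` applies the diastole filter with strict inequalities:
volume strictly above 10 mm³ and long-axis length (chamber extent along the
first principal axis) strictly above 4 mm, both configurable. The
thresholds are applied to cleared-tissue volumes, matching the workflow in
which they were defined.

## Chamber morphometry

`principal_axes()` orders the eigenvectors of the voxel-coordinate
covariance by descending eigenvalue; the apex is the chamber extreme
farther from the centroid along axis 1. Signs and near-ties are resolved
deterministically (largest-magnitude component positive; a full eigenvalue
tie falls back to the grid axes).

The two-chamber view is the OR-silhouette of the chamber along the third
principal axis (`project_silhouette()`), not a mid-plane section: a
silhouette is deterministic and robust to slice choice. Pixels are
isotropic at the minimum voxel spacing, and the base line `u = 0` through
the projected centroid falls on a pixel boundary.

`conicity_index()` fits the cone in projection as the triangle spanned by
the two endpoints of the silhouette's intersection with the base line and
the apical extreme, the minimal construction for which a conical chamber
scores exactly 1. The index is the apical silhouette area over the triangle
area; apical dilation raises it above 1. `apex_volume()` uses the same
centroid base plane (voxels exactly on the plane count half to each side,
so symmetric chambers halve exactly).

## Surface mesh and mean curvature

`chamber_mesh()` extracts the 0.5 isosurface of the (lightly smoothed,
sigma = 1 voxel) chamber mask by marching tetrahedra on the Freudenthal
6-tetrahedron grid decomposition — translation-consistent across cubes, so
interior surfaces are closed and manifold — followed by volume-preserving
Taubin smoothing. Meshes export to binary PLY with an optional per-vertex
curvature attribute loadable in standard viewers.

Per-vertex signed mean curvature (`mean_curvature()`, 1/mm; positive =
convex chamber surface, negative = concave indentations such as papillary
imprints) defaults to a multi-radius **integral-invariant** estimator: the
solid volume inside probe balls of radii 6, 9 and 12 voxels is compared
with the half-space value, and surface offset and curvature are solved
jointly by least squares across radii, which cancels vertex placement error
to first order. Volume counting averages voxelization noise over thousands
of voxels; this matters because one-ring discrete operators (including the
classical cotangent Laplacian, available as `method = "cotan"`) are
noise-dominated per-vertex on mask-derived isosurfaces even though their
area-weighted means are accurate. A resolution limit applies to any
estimator: where the surface runs tangent to a lattice plane, voxelization
genuinely flattens it over a terrace of radius sqrt(2 r h) (≈ 400 µm for a
2 mm sphere at 40 µm voxels), so per-vertex accuracy claims are made in
distributional form (on a sphere, the area-weighted mean and median land
within 5 % of 1/r and ≥ 85 % of vertices do individually).

`apical_curvature_histogram()` isolates the apical half of the mesh
(centroid plane of the axis frame) and reports an **area-weighted**
frequency histogram (64 bins over ±1 mm⁻¹ by default, outliers clipped into
the end bins, frequencies summing to 1) plus the area-weighted mean.
Area weighting avoids the orientation-dependent vertex-density bias of
isosurface meshes. The sign convention above is fixed package-wide; group
comparisons must be run under one convention consistently.

## Local wall thickness and zones

`local_thickness()` implements maximal-sphere (Hildebrand–Rüegsegger)
thickness: the diameter of the largest sphere fully inside the tissue that
contains the voxel. The inscribed radius at a voxel is its anisotropic
Euclidean distance to the nearest background voxel centre minus half a
voxel (the centre-to-centre distance overshoots the physical boundary by
half a voxel; without the correction a 300 µm slab reads 300 µm + h and
every zone boundary shifts by one voxel), while sphere coverage keeps the
centre-to-centre reach so rim voxels stay covered. Radii are processed in
descending order with one distance transform per radius level — exact when
the level count covers all distinct radii (the default for test-sized
volumes), and conservatively floored onto a uniform level grid above
`max_levels` (sub-voxel error at the 48–128 levels used for large
volumes). Anisotropic grids are handled in physical units directly; no
resampling. On thickness ramps the maximal sphere can sit toward the
thicker side, so designed phantom profiles use gentle slopes (< ~0.3)
where designed and measured thickness must agree.

`lv_wall_mask()` restricts analysis to the LV free wall: a user-supplied
mask passes through unchanged (the faithful route when a manual septum/RV
delineation exists — how that delineation was done in the original workflow
is not stated), or a geometric default excludes an angular sector about a
user-marked septal azimuth and tissue beyond a distance bound from the
chamber. The azimuth is measured in a grid-anchored transverse frame
because the PCA transverse axes are arbitrary for near-axisymmetric
chambers.

`thin_wall_volume()` (strict `< 400 µm`, the thickness below which
consistent cardiomyocyte loss marks infarcted wall) and `zone_partition()`
(infarct < 300, border 300–500 closed interval, remote > 500; boundary
values at exactly 300 or 500 µm are border) complete the wall endpoints.
The diameter (not radius) convention is deliberate: a radius reading would
halve every threshold and contradict the 400 µm cardiomyocyte-loss
observation.

## Vessel enhancement and density

`vesselness()` is a multiscale Hessian tubularity filter of the Frangi
family with bright-tube polarity: scale-normalized Gaussian-derivative
Hessians (per-axis sigmas in physical µm, so anisotropic spacing is
honoured), eigenvalue response with standard sensitivity constants
(alpha = beta = 0.5), maximum over scales 2, 3.5 and 5 µm — covering lumen
diameters below 10 µm. The structureness constant defaults to half the
maximal Hessian norm per scale but is floored at `noise_mult` (default 8)
times the median absolute deviation of the Hessian norm: without the floor
a vessel-free volume has its noise rescaled into signal.

`segment_vessels()` thresholds inside the tissue mask in three steps.
First a vessel-presence check: Otsu's separability measure (eta) of the
positive responses is stably ≈ 0.66 for the filter's noise-only null
regardless of noise level, while any genuine vessel population down to 3 %
volume fraction scores ≥ 0.79; below 0.72 the volume is declared
vessel-free. (Plain Otsu as the default rule was measured against the
phantom ground truth and rejected: on the zero-inflated vesselness
histogram its split lands far above the vessel knee, and on vessel-free
volumes it happily thresholds noise.) Second, the threshold itself: the
response is scale-normalized to [0, 1], so the default is an absolute cut
at 0.03, with triangle, Otsu and fixed rules available — the fixed rule
reproduces any chosen cutoff exactly. Third, connected components smaller
than 1000 µm³ are removed; perfused vessels are elongated, isolated
supra-threshold specks are noise. At these defaults the phantom ground
truth gives Dice 0.92 (noiseless) and 0.91 (vessel contrast / noise = 5),
with zero false-positive voxels on vessel-free phantoms.

`zone_vascular_density()` reports, per zone, vessel volume as a percentage
of the zone's tissue volume (vessel voxels count toward the tissue
denominator, matching the "% of total tissue volume" convention), plus a
whole-wall row that equals the zone-volume-weighted mean exactly. Empty
zones report `NA`, never 0.

## Study statistics

`group_compare()` runs one-way ANOVA followed by Tukey–Kramer
honestly-significant-difference comparisons (the unequal-n form, via the
studentized range distribution; base R's `TukeyHSD()` implements exactly
this and is cross-checked in the tests against a from-first-principles
oracle), with group summaries as mean ± s.e.m. and optional pre-specified
two-tailed t-tests. No additional correction is applied across endpoints.
`pearson_cor()` gives the sample correlation with a t-distribution p-value
on n − 2 degrees of freedom. `percent_change()` uses the week-0
(baseline) denominator by default — the procedural definition — with the
follow-up-denominator variant that appears in some figure legends available
behind a flag; the ratio-change asymmetry this implies is documented rather
than hidden. `build_report()` assembles per-subject results into tidy CSVs
and a JSON study summary; `tidy()`/`glance()` methods and `autoplot()`
figures cover the comparison objects.

```{r stats, eval = FALSE}
cohort |>
  group_compare("border_density", "group") |>
  tidy()
```

## Numerical choices and degenerate inputs

* Connectivity: 26 for tissue, 6 for cavities; component ties break by
  lowest linear voxel index.
* Eigenvalue ties in the axis frame fall back to grid axes; eigenvector
  signs are fixed by the largest-magnitude component, the apex direction
  by the farther chamber extreme.
* Strict inequalities throughout the QC; closed interval for the border
  zone; thin-wall cutoff strict.
* Zero-variance groups, constant correlation inputs, empty masks, missing
  cavities and infeasible vessel fractions (> 0.4 for tube packing) raise
  errors rather than returning defaults.
* Phantom grids in examples and tests use odd extents so shape centres
  fall on voxel centres; this keeps voxelization symmetric (an even grid
  shifts a cone tip by half a voxel and costs ~1 % conicity accuracy,
  still within tolerance).

## Problem sizes

Whole-heart phantoms in the test-suite run at 40–60 µm spacing on grids of
roughly 120³–180³ voxels; capillary-scale slab phantoms at 2.5–4 µm on
~0.5–2 million voxels; oracle comparisons run exhaustively on ≤ 64³ crops;
the statistical calibration uses 2000 null simulations and the cohort
recovery 18 phantoms plus 20 ordering replicates. These sizes resolve every
endpoint the pipeline defines while keeping the full suite reproducible on
a laptop-class machine.

## Known limitations

* The segmenter is classical; hearts whose chamber is not the largest
  enclosed cavity (severe rupture, imaging dropout) need an external mask.
* Per-vertex curvature at lattice-tangent facets is scale-limited (see
  above); distributional curvature endpoints are the reliable ones.
* The vessel model in phantoms is non-branching; the density endpoints do
  not depend on topology, but centerline or branching analyses are out of
  scope.
* The tubularity filter's exact published variant and threshold are not
  recoverable from the source description ("tuned to enhance bright
  vessels"); only the lumen-scale tuning is reproducible, and the fixed
  threshold rule exists to replicate any specific cutoff.
* Whether the projection in the original workflow was a silhouette or a
  mid-plane section is not stated; the silhouette was chosen for
  determinism and is fixed package-wide.
* The histogram peak position reported for curvature in the source work
  has no stated units or sign convention; this package fixes both
  explicitly (1/mm, convex positive) and all comparisons are internal to
  that convention.
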