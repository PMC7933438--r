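# lvmorph

Automated 3D morphometry of light-sheet imaged infarcted mouse hearts.

After coronary-artery (LAD) ligation the mouse left ventricle remodels: the
chamber dilates, the apical wall thins into fibrotic scar, and microvessel
density falls in and around the infarct. Whole cleared hearts imaged by
light-sheet fluorescence microscopy capture all of this in two 3D channels —
autofluorescence (structure) and lectin-labelled perfused vessels — but
turning those volumes into numbers requires a dedicated pipeline. `lvmorph`
is that pipeline, for imaging scientists and preclinical cardiovascular
researchers:

* **Chamber segmentation + diastole QC** — tissue pre-segmentation, LV
  chamber extraction as the enclosed cavity of the capped tissue mask
  (externally produced chamber masks are accepted too), and the diastole
  filter: volume > 10 mm³ and long-axis length > 4 mm, both strict.
* **Chamber morphometry** — principal axes; the 2-chamber-view silhouette
  projected along the third principal axis; the **apical conicity index**
  (apical silhouette area over the fitted triangle: exactly 1 for a conical
  apex, > 1 with apical dilation); apex volume below the centroid plane;
  surface mesh (marching tetrahedra, PLY export) and the area-weighted
  apical **mean-curvature** distribution (1/mm; convex positive).
* **Wall thickness** — per-voxel local thickness by maximal inscribed
  spheres (anisotropic, physical units), thin-wall infarct volume
  (< 400 µm), and the zone partition: infarct < 300 µm, border 300–500 µm,
  remote > 500 µm.
* **Vasculature** — multiscale Hessian (Frangi-type) enhancement of bright
  tubes with lumen diameter below 10 µm, thresholding inside tissue, and
  zone-stratified vascular density (% of zone tissue volume).
* **Statistics** — one-way ANOVA with Tukey–Kramer post hoc, two-tailed
  t-tests, Pearson correlation, percent-change summaries, tidy
  `tidy()`/`glance()` output and `autoplot()` figures.
* **Synthetic phantoms** — seeded generators with exact voxel ground truth
  (`generate_heart_phantom()`, `generate_zone_phantom()`), so every stage
  is testable without animal data.

## Worked example

A synthetic infarcted heart, end to end:

```r
library(lvmorph)

spec <- phantom_spec(grid_shape = c(151, 131, 131), voxel_spacing_um = 40,
                     chamber_shape = "capped_cone",
                     chamber_semi_axes_um = c(2600, 1400, 1400),
                     base_opening = TRUE, aperture_radius_um = 400,
                     wall_profile = wall_profile_infarct(),
                     septal_azimuth_deg = 180, seed = 11)
ph <- generate_heart_phantom(spec)

tm  <- tissue_mask(ph$image)
ch  <- segment_chamber(tm)
diastole_qc(ch)
#> # A tibble: 1 x 4
#>   volume_mm3 long_axis_mm pass  reasons
#>        <dbl>        <dbl> <lgl> <list>
#> 1       15.9         4.68 TRUE  <chr [0]>

fr   <- principal_axes(ch)
wall <- lv_wall_mask(tm, ch, fr, septal_azimuth_deg = 180, max_dist_um = Inf)
th   <- local_thickness(tm, max_levels = 128)
thin_wall_volume(th, wall)      # infarcted wall volume below 400 um, mm^3
#> [1] 2.457
```

The QC passes (15.9 mm³ > 10 mm³, 4.68 mm > 4 mm: the phantom heart is
fully diastolic), and the thin-wall volume agrees with the phantom's
designed infarct sector to 0.4 %. Vascular density on a capillary-scale
phantom built at the vehicle-group regime:

```r
zp    <- generate_zone_phantom(seed = 7)   # designed 7 / 18.9 / 21.9 %
vm    <- segment_vessels(vesselness(zp$vessel_image), zp$truth_tissue)
zones <- zone_partition(local_thickness(zp$truth_tissue, max_levels = 64),
                        zp$truth_lv_wall)
zone_vascular_density(vm, zones)
#> # A tibble: 4 x 4
#>   zone       zone_volume_mm3 vessel_volume_mm3 density_pct
#>   <chr>                <dbl>             <dbl>       <dbl>
#> 1 infarct            0.00992          0.000703        7.09
#> 2 border             0.016            0.00297        18.6
#> 3 remote             0.024            0.00514        21.4
#> 4 whole_wall         0.0499           0.00882        17.7
```

The full pipeline (enhancement, thresholding, thickness zoning) recovers
the designed densities to within half a percentage point and preserves the
infarct < border < remote ordering.

A command-line front end over the same functions ships in
`inst/cli/lvmorph` (`phantom`, `segment`, `qc`, `morphometry`, `thickness`,
`vessels`, `report` subcommands).

## Documentation

The methods vignette (`vignettes/lvmorph-methods.Rmd`) describes the models
and estimators, the phantom generators and what they do and do not emulate,
all numerical conventions (units, connectivity, tie-breaks, strictness of
thresholds), and known limitations.
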