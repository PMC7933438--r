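test_that("voxelized chamber solids match analytic volumes", {
  cone <- phantom_spec(grid_shape = c(171, 171, 171), voxel_spacing_um = 40,
                       chamber_shape = "cone",
                       chamber_semi_axes_um = c(3000, 3000, 3000))
  v <- mask_volume_mm3(generate_chamber_solid(cone))
  expect_lt(abs(v / (pi / 3 * 3^2 * 6) - 1), 0.02)

  ell <- phantom_spec(grid_shape = c(171, 101, 101), voxel_spacing_um = 40,
                      chamber_shape = "prolate_ellipsoid",
                      chamber_semi_axes_um = c(3000, 1500, 1500))
  v2 <- mask_volume_mm3(generate_chamber_solid(ell))
  expect_lt(abs(v2 / (4 / 3 * pi * 3 * 1.5 * 1.5) - 1), 0.02)
})

test_that("degenerate and oversized chamber specs are rejected", {
  expect_error(phantom_spec(chamber_semi_axes_um = c(0, 1200, 1200)),
               "positive")
  expect_error(phantom_spec(grid_shape = c(60, 60, 60),
                            voxel_spacing_um = 40,
                            chamber_semi_axes_um = c(2000, 1500, 1500)),
               "fit inside")
  # passes the coarse spec check but the voxelized solid touches the grid
  big <- phantom_spec(grid_shape = c(60, 160, 160), voxel_spacing_um = 40,
                      chamber_semi_axes_um = c(2000, 900, 900))
  expect_error(generate_chamber_solid(big), "exceeds the grid")
})

test_that("phantom generation is bit-identical for identical spec and seed", {
  spec <- phantom_spec(grid_shape = c(81, 71, 71), voxel_spacing_um = 60,
                       chamber_semi_axes_um = c(1600, 900, 900), seed = 9)
  a <- generate_heart_phantom(spec)
  b <- generate_heart_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$vessel_image$data, b$vessel_image$data)
  expect_identical(a$truth_vessels$data, b$truth_vessels$data)

  za <- generate_zone_phantom(slab_lateral_um = c(120, 120), seed = 4)
  zb <- generate_zone_phantom(slab_lateral_um = c(120, 120), seed = 4)
  expect_identical(za$image$data, zb$image$data)
  expect_identical(za$truth_vessels$data, zb$truth_vessels$data)
})

test_that("phantom masks satisfy the bundle invariants", {
  spec <- phantom_spec(grid_shape = c(81, 71, 71), voxel_spacing_um = 60,
                       chamber_semi_axes_um = c(1600, 900, 900),
                       septal_azimuth_deg = 180, seed = 9)
  ph <- generate_heart_phantom(spec)
  expect_false(any(ph$truth_chamber$data & ph$truth_tissue$data))
  expect_true(all(ph$truth_vessels$data[ph$truth_vessels$data] %in% TRUE))
  expect_true(all(!ph$truth_vessels$data | ph$truth_tissue$data))
  expect_true(all(!ph$truth_lv_wall$data | ph$truth_tissue$data))
  expect_identical(dim(ph$image$data), dim(ph$truth_tissue$data))
})

test_that("achieved vessel fractions land within half a percentage point", {
  zp <- generate_zone_phantom(
    slab_thickness_um = 600, slab_lateral_um = c(200, 200),
    vessel_fraction_by_zone = c(infarct = 0.20), seed = 5)
  frac <- sum(zp$truth_vessels$data) / sum(zp$truth_tissue$data)
  expect_gte(frac, 0.195)
  expect_lte(frac, 0.205)

  zp3 <- generate_zone_phantom(slab_lateral_um = c(150, 150), seed = 6)
  lab <- zp3$truth_zone_labels
  target <- c(0.07, 0.189, 0.219)
  for (z in 1:3) {
    achieved <- sum(zp3$truth_vessels$data[lab == z]) / sum(lab == z)
    expect_lt(abs(achieved - target[z]), 0.005)
  }
})

test_that("zero vessel fraction yields an empty vessel channel", {
  spec <- phantom_spec(grid_shape = c(81, 71, 71), voxel_spacing_um = 60,
                       chamber_semi_axes_um = c(1600, 900, 900),
                       intensity_model = list(background = 0.05, tissue = 0.6,
                                              vessel = 0.9, noise_sd = 0),
                       seed = 2)
  ph <- generate_heart_phantom(spec)
  expect_equal(sum(ph$truth_vessels$data), 0)
  # vessel channel = background plus the faint tissue level only
  expect_lte(max(ph$vessel_image$data), 0.1 + 1e-9)
})

test_that("infeasible vessel fractions are rejected", {
  expect_error(phantom_spec(vessel_fraction_by_zone = c(infarct = 0.5)),
               "0.4")
  expect_error(lay_vessel_tubes(array(TRUE, c(10, 10, 10)), 4, 0.6),
               "infeasible")
  expect_error(phantom_spec(vessel_radius_range_um = c(4, 9)), "capillary")
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(grid_shape = c(81, 71, 71), voxel_spacing_um = 60,
                       chamber_shape = "capped_cone",
                       chamber_semi_axes_um = c(1600, 900, 900),
                       wall_profile = wall_profile_infarct(), seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$chamber_semi_axes_um, spec$chamber_semi_axes_um)
  expect_equal(back$seed, spec$seed)
  expect_equal(back$wall_profile$thickness_um, spec$wall_profile$thickness_um)
  # and the round-tripped spec generates the identical phantom
  expect_identical(generate_heart_phantom(back)$image$data,
                   generate_heart_phantom(spec)$image$data)
})

test_that("designed wall thickness equals measured local thickness in constant sectors", {
  # shell sector crop at fine spacing, checked against the exhaustive oracle
  zp <- generate_zone_phantom(slab_thickness_um = c(120, 200),
                              slab_lateral_um = c(80, 80),
                              voxel_spacing_um = 10,
                              vessel_fraction_by_zone = c(infarct = 0),
                              seed = 3)
  crop <- zp$truth_tissue$data
  th <- local_thickness(zp$truth_tissue)
  tt <- zp$truth_thickness$data
  expect_true(all(abs(th$data[crop] - tt[crop]) <= 10 + 1e-9))
})
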