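test_that("local thickness is exact on slabs and spheres", {
  slab <- slab_mask(300, 4, c(90, 40, 40))
  th <- local_thickness(slab)
  expect_true(all(abs(th$data[slab$data] - 300) <= 4 + 1e-9))
  expect_true(all(th$data[!slab$data] == 0))

  sph <- sphere_mask(250, spacing_um = 5)
  th2 <- local_thickness(sph)
  expect_true(all(abs(th2$data[sph$data] - 500) <= 5 + 1e-9))
})

test_that("a 300 um slab reads the same along coarse and fine axes", {
  # light-sheet style anisotropy: 7 um optical sections, 1.6 um in plane
  sp <- c(7, 1.6, 1.6)
  coarse <- slab_mask(300, sp, c(90, 50, 50), axis = 1)
  fine <- slab_mask(300, sp, c(20, 50, 240), axis = 3)
  t1 <- local_thickness(coarse)$data[45, 25, 25]
  t2 <- local_thickness(fine)$data[10, 25, 120]
  expect_lt(abs(t1 - 300), 7 + 1e-9)
  expect_lt(abs(t2 - 300), 7 + 1e-9)
  expect_lt(abs(t1 - t2), 7 + 1e-9)
})

test_that("local thickness equals the exhaustive maximal-sphere oracle", {
  # a wedge ramping across the crop plus seeded random blob masks
  wedge <- array(FALSE, c(32, 16, 16))
  for (k in seq_len(16)) {
    n <- round(2 + (k - 1) * 1.3)
    wedge[5 + seq_len(n) - 1, , k] <- TRUE
  }
  masks <- c(list(volume_mask(wedge, 20)),
             lapply(1:5, function(s)
               random_blob_mask(c(20, 18, 16), 25, n_balls = 3, seed = s)))
  for (m in masks) {
    got <- local_thickness(m)$data
    want <- brute_force_thickness(m, m$spacing_um)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("dilating a mask never decreases local thickness", {
  m <- random_blob_mask(c(24, 24, 24), 20, n_balls = 3, seed = 11)
  th0 <- local_thickness(m)$data
  dil <- volume_mask(dist_to_set(m$data, m$spacing_um) <= 40, m$spacing_um)
  th1 <- local_thickness(dil)$data
  expect_true(all(th1[m$data] >= th0[m$data] - 1e-9))
})

test_that("LV wall restriction excludes the septal sector", {
  spec <- phantom_spec(grid_shape = c(121, 101, 101), voxel_spacing_um = 50,
                       chamber_semi_axes_um = c(2200, 1200, 1200),
                       septal_azimuth_deg = 135, seed = 5)
  ph <- generate_heart_phantom(spec)
  tm <- tissue_mask(ph$image)
  ch <- segment_chamber(tm)
  fr <- principal_axes(ch)
  wall <- lv_wall_mask(tm, ch, fr, septal_azimuth_deg = 135,
                       max_dist_um = Inf)
  septum <- ph$truth_tissue$data & !ph$truth_lv_wall$data
  expect_gte(1 - sum(wall$data & septum) / sum(septum), 0.99)

  # full sector equals tissue within the distance bound
  wall_all <- lv_wall_mask(tm, ch, fr, max_dist_um = 1000)
  within <- tm$data & dist_to_set(ch$data, tm$spacing_um) <= 1000
  expect_identical(wall_all$data, within)

  # user-supplied masks pass through unchanged
  user <- random_blob_mask(dim(tm$data), 50, seed = 3)
  expect_identical(lv_wall_mask(tm, user_mask = user)$data, user$data)
})

test_that("thin-wall volume applies a strict sub-cutoff rule", {
  slab600 <- slab_mask(600, 4, c(170, 30, 30))
  th600 <- local_thickness(slab600)
  expect_equal(thin_wall_volume(th600, slab600), 0)

  slab300 <- slab_mask(300, 4, c(90, 30, 30))
  th300 <- local_thickness(slab300)
  expect_equal(thin_wall_volume(th300, slab300),
               sum(slab300$data) * 4^3 / 1e9)
})

test_that("thin-wall infarct volume is recovered within 5 percent on a heart phantom", {
  spec <- phantom_spec(grid_shape = c(151, 131, 131), voxel_spacing_um = 40,
                       chamber_shape = "capped_cone",
                       chamber_semi_axes_um = c(2600, 1400, 1400),
                       wall_profile = wall_profile_infarct(),
                       septal_azimuth_deg = 180, seed = 11)
  ph <- generate_heart_phantom(spec)
  tm <- tissue_mask(ph$image)
  ch <- segment_chamber(tm)
  wall <- lv_wall_mask(tm, ch, principal_axes(ch),
                       septal_azimuth_deg = 180, max_dist_um = Inf)
  th <- local_thickness(tm, max_levels = 128)
  got <- thin_wall_volume(th, wall)
  tt <- ph$truth_thickness$data
  designed <- sum(ph$truth_lv_wall$data & tt > 0 & tt < 400 & wall$data) *
    prod(spec$voxel_spacing_um) / 1e9
  expect_lt(abs(got / designed - 1), 0.05)
})

test_that("zone partition labels exactly, sums to the wall, and is closed on 300-500", {
  zp <- generate_zone_phantom(slab_lateral_um = c(120, 120),
                              vessel_fraction_by_zone = c(infarct = 0),
                              seed = 2)
  th <- local_thickness(zp$truth_tissue, max_levels = 64)
  zones <- zone_partition(th, zp$truth_lv_wall)
  lab <- zp$truth_zone_labels
  # slab zones recovered exactly (slabs are 250/400/600 um)
  expect_identical(zones$labels[lab > 0], lab[lab > 0])
  # partition property
  expect_equal(sum(zones$labels > 0), sum(zp$truth_lv_wall$data))

  # boundary values 300 and 500 fall in the border zone (closed interval)
  thb <- volume_image(array(c(300, 500, 299.9, 500.1, 0, 0, 0, 0),
                            c(2, 2, 2)), 10)
  wallb <- volume_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)), 10)
  zb <- zone_partition(thb, wallb)
  expect_equal(as.vector(zb$labels)[1:4], c(2L, 2L, 1L, 3L))
})
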