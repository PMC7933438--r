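tube_image <- function(radius_um = 4, spacing_um = 2.5, dims = c(40, 40, 80),
                       level = 1, background = 0) {
  sp <- rep(spacing_um, 3)
  ctr <- (dims[1:2] - 1) / 2 * spacing_um
  zz <- ((seq_len(dims[1]) - 1) * spacing_um - ctr[1])^2
  yy <- ((seq_len(dims[2]) - 1) * spacing_um - ctr[2])^2
  img <- array(background, dims)
  tube <- outer(zz, yy, `+`) <= radius_um^2
  img[rep(tube, times = dims[3])] <- level
  volume_image(array(img, dims), sp)
}

test_that("the tubularity filter responds to tubes, not blobs or flat fields", {
  img <- tube_image()
  v <- vesselness(img, noise_mult = 0)
  d <- dim(v$data)
  centre <- v$data[(d[1] + 1) / 2, (d[2] + 1) / 2, d[3] / 2]
  bgresp <- v$data[5, 5, d[3] / 2]
  expect_gt(centre, 10 * max(bgresp, 1e-6))

  # equal-intensity blob: centreline response of the tube beats the blob core
  sp <- 2.5
  dims <- c(40, 40, 40)
  ctr <- (dims - 1) / 2 * sp
  zz <- ((seq_len(dims[1]) - 1) * sp - ctr[1])^2
  blob <- array(outer(outer(zz, zz, `+`), zz, `+`) <= 12^2, dims)
  blob_img <- volume_image(array(as.numeric(blob), dims), sp)
  vb <- vesselness(blob_img, noise_mult = 0)
  expect_gt(centre, vb$data[(dims[1] + 1) / 2, (dims[2] + 1) / 2,
                            (dims[3] + 1) / 2])

  # uniform image: no response
  flat <- volume_image(array(0.5, c(30, 30, 30)), sp)
  expect_lt(max(vesselness(flat, noise_mult = 0)$data), 1e-6)

  expect_error(vesselness(volume_image(array(0.5, c(10, 10, 10)), 2),
                          scales_um = 50), "extent")
})

test_that("vessel segmentation meets the phantom Dice and false-positive bounds", {
  mk <- function(f, noise_sd, seed) generate_zone_phantom(
    slab_thickness_um = 200, slab_lateral_um = c(160, 160),
    voxel_spacing_um = 2.5, vessel_fraction_by_zone = c(infarct = f),
    intensity_model = list(background = 0.05, tissue = 0.35, vessel = 0.9,
                           noise_sd = noise_sd),
    seed = seed)

  clean <- mk(0.15, 0, 3)
  vm <- segment_vessels(vesselness(clean$vessel_image), clean$truth_tissue)
  expect_gte(dice(vm, clean$truth_vessels), 0.90)
  expect_true(all(!vm$data | clean$truth_tissue$data)) # vessels in tissue

  noisy <- mk(0.15, 0.17, 3) # vessel contrast / noise sd = 5
  vm2 <- segment_vessels(vesselness(noisy$vessel_image), noisy$truth_tissue)
  expect_gte(dice(vm2, noisy$truth_vessels), 0.80)

  for (s in 1:2) {
    empty <- mk(0, c(0.02, 0.17)[s], 4 + s)
    vm3 <- segment_vessels(vesselness(empty$vessel_image), empty$truth_tissue)
    expect_lt(sum(vm3$data) / sum(empty$truth_tissue$data), 0.005)
  }
})

test_that("the fixed threshold rule reproduces an exact cutoff", {
  zp <- generate_zone_phantom(slab_thickness_um = 200,
                              slab_lateral_um = c(120, 120),
                              voxel_spacing_um = 2.5,
                              vessel_fraction_by_zone = c(infarct = 0.1),
                              seed = 8)
  v <- vesselness(zp$vessel_image)
  vm <- segment_vessels(v, zp$truth_tissue, rule = "fixed", threshold = 0.2,
                        min_component_um3 = 0)
  expect_identical(vm$data, array(v$data > 0.2 & zp$truth_tissue$data,
                                  dim(v$data)))
})

test_that("zone densities recover designed fractions and close the bookkeeping", {
  zp <- generate_zone_phantom(slab_lateral_um = c(150, 150), seed = 17)
  th <- local_thickness(zp$truth_tissue, max_levels = 64)
  zones <- zone_partition(th, zp$truth_lv_wall)
  dens <- zone_vascular_density(zp$truth_vessels, zones)
  target <- c(infarct = 7, border = 18.9, remote = 21.9)
  for (z in names(target)) {
    got <- dens$density_pct[dens$zone == z]
    expect_lt(abs(got - target[[z]]), 1.5)
  }
  # whole-wall density is the zone-volume-weighted mean, exactly
  zd <- dens[dens$zone != "whole_wall", ]
  expect_equal(dens$density_pct[dens$zone == "whole_wall"],
               sum(zd$density_pct * zd$zone_volume_mm3) /
                 sum(zd$zone_volume_mm3))

  # no vessels -> 0 % everywhere; vessels = zone -> 100 %
  none <- volume_mask(array(FALSE, dim(zp$truth_tissue$data)),
                      zp$truth_tissue$spacing_um)
  d0 <- zone_vascular_density(none, zones)
  expect_true(all(d0$density_pct == 0))
  all_v <- volume_mask(zones$labels == 1L, zp$truth_tissue$spacing_um)
  d1 <- zone_vascular_density(all_v, zones)
  expect_equal(d1$density_pct[d1$zone == "infarct"], 100)

  # an empty zone reports NA, not 0
  th2 <- volume_image(array(600, c(4, 4, 4)), 10)
  w2 <- volume_mask(array(TRUE, c(4, 4, 4)), 10)
  z2 <- zone_partition(th2, w2)
  d2 <- zone_vascular_density(volume_mask(array(FALSE, c(4, 4, 4)), 10), z2)
  expect_true(is.na(d2$density_pct[d2$zone == "infarct"]))
  expect_equal(d2$density_pct[d2$zone == "remote"], 0)
})
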