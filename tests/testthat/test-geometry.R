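# Voxel volume construction: skin with cylindrical vessels, two-layer
# phantom.

test_that("phantom volume layering matches its specification", {
  v0 <- build_phantom_volume(phantom_spec(0), c(1, 1, 1), 0.02)
  expect_true(all(v0$labels == 2L))                 # homogeneous bottom
  v <- build_phantom_volume(phantom_spec(0.20), c(1, 1, 1), 0.02)
  expect_equal(sum(apply(v$labels == 1L, 3, any)), 10)  # 10 top planes
  v2 <- build_phantom_volume(phantom_spec(0.20), c(1, 1, 1), 0.02)
  expect_identical(v$labels, v2$labels)             # deterministic
  expect_error(build_phantom_volume(phantom_spec(1), c(1, 1, 1), 0.02),
               "thick")
})

test_that("vessel count equals density times full perpendicular cross-section", {
  spec <- skin_spec(epidermal_um = 100, vessel_diameter_um = 117,
                    vessel_density_mm2 = 33.75, placement_seed = 3)
  ctr <- vessel_centers(spec, c(2, 4.7, 1.1))
  expect_equal(nrow(ctr), round(33.75 * 2 * 1.1))   # 74 cylinders in X-Z
  # zero density -> no vessels anywhere in the volume
  none <- skin_spec(vessel_density_mm2 = 0)
  v <- build_skin_volume(none, c(1, 1, 1.1), 0.02)
  expect_equal(sum(v$labels == 3L), 0)
})

test_that("every voxel carries exactly one medium and counts close", {
  ts <- tiny_skin(seed = 11)
  counts <- medium_counts(ts$volume)
  expect_equal(sum(counts), length(ts$volume$labels))
  expect_true(all(ts$volume$labels %in% 1:3))
  # epidermis slab thickness in voxel planes
  epi_planes <- apply(ts$volume$labels == 1L, 3, any)
  expect_equal(sum(epi_planes), 10)  # 100 um at 10 um voxels
})

test_that("vessel placement is seed-reproducible and seed-sensitive", {
  a <- tiny_skin(seed = 5)$volume
  b <- tiny_skin(seed = 5)$volume
  c <- tiny_skin(seed = 6)$volume
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
})

test_that("voxelized vessel volume fraction approaches the analytic value", {
  # cylinders of known count/diameter: compare blood voxel fraction with
  # N * pi r^2 / A over the cross-section, at voxel = diameter/10
  spec <- skin_spec(epidermal_um = 100, vessel_diameter_um = 117,
                    vessel_density_mm2 = 33.75, placement_seed = 7)
  ext <- c(1, 0.3, 1.1)
  v <- build_skin_volume(spec, ext, voxel_mm = 0.0117)
  n_vessel <- nrow(vessel_centers(spec, ext))
  analytic <- n_vessel * pi * (0.117 / 2)^2 / (ext[1] * ext[3])
  measured <- mean(v$labels == 3L)  # extruded along y, so the 3-D mean
                                    # equals the cross-section fraction
  expect_lt(abs(measured / analytic - 1), 0.10)
})

test_that("dilation preserves centers and scales blood volume by the area ratio", {
  dia <- skin_spec(epidermal_um = 100, vessel_diameter_um = 117,
                   placement_seed = 2)
  sys <- dilate_vessels(dia, 75)
  expect_equal(sys$vessel_diameter_um, 75)
  ext <- c(1, 0.3, 1.1)
  expect_equal(vessel_centers(sys, ext), vessel_centers(dia, ext))
  expect_identical(dilate_vessels(dia, 117), dia)     # identity
  vd <- build_skin_volume(dia, ext, 0.005)
  vs <- build_skin_volume(sys, ext, 0.005)
  ratio <- sum(vd$labels == 3L) / sum(vs$labels == 3L)
  expect_lt(abs(ratio / (117 / 75)^2 - 1), 0.05)      # voxelization error
  expect_error(dilate_vessels(dia, 200), "max_diameter_um")
})

test_that("vessel depths are uniform over the permitted band", {
  # many small vessels -> chi-square on the depth histogram
  spec <- skin_spec(epidermal_um = 50, vessel_diameter_um = 10,
                    vessel_density_mm2 = 400, max_diameter_um = 10,
                    depth_band_um = c(200, 800), placement_seed = 9)
  ctr <- vessel_centers(spec, c(5, 5, 1.1))
  expect_gte(nrow(ctr), 2000)
  h <- hist(ctr[, 2], breaks = seq(0.2, 0.81, length.out = 11),
            plot = FALSE)$counts
  p <- suppressWarnings(chisq.test(h)$p.value)
  expect_gt(p, 0.001)
})

test_that("construction errors fire for impossible geometries", {
  expect_error(build_skin_volume(skin_spec(), c(2, 2, 1.1), voxel_mm = 0.05),
               "voxel")
  expect_error(
    vessel_centers(skin_spec(depth_band_um = c(1000, 1090)), c(1, 1, 1.1)),
    "band")
  expect_error(skin_spec(vessel_diameter_um = 130, max_diameter_um = 117),
               "max_diameter")
})
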