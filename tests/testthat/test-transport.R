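# Monte Carlo transport engine: elementary sampling operations, weight
# accounting, conservation, ballistic and statistical oracles.

test_that("Henyey-Greenstein sampling has the analytic mean and median", {
  expect_equal(sample_hg(0, 0.5), 0)
  expect_equal(sample_hg(0, 0), -1)
  expect_equal(sample_hg(0, 1), 1)
  set.seed(1)
  u <- runif(1e6)
  for (g in c(0, 0.5, 0.9)) {
    cth <- sample_hg(g, u)
    se <- sd(cth) / sqrt(length(u))
    expect_lt(abs(mean(cth) - g), 3 * se)
    expect_true(all(cth >= -1 & cth <= 1))
  }
  expect_error(sample_hg(1, 0.5), "g must")
})

test_that("Fresnel reflectance matches the closed form, TIR, and matched boundary", {
  expect_equal(fresnel_reflectance(1, 1.4, 1.0), ((1.4 - 1) / (1.4 + 1))^2)
  expect_equal(fresnel_reflectance(1, 1.0, 1.0), 0)
  # beyond the critical angle: always reflect
  cos_crit <- sqrt(1 - (1.0 / 1.4)^2)
  expect_equal(fresnel_reflectance(cos_crit * 0.9, 1.4, 1.0), 1)
  out <- fresnel_interaction(cos_crit * 0.9, 1.4, 1.0, u = 0.999999)
  expect_equal(out$action, "reflect")
  # matched boundary: always transmit, direction unchanged
  out <- fresnel_interaction(0.3, 1.4, 1.4, u = 0)
  expect_equal(out$action, "transmit")
  expect_equal(out$cos_t, 0.3)
  expect_error(fresnel_interaction(0, 1.4, 1.0, 0.5), "cos_i")
})

test_that("Russian roulette preserves expectation and leaves big weights alone", {
  expect_equal(roulette(0.5, threshold = 1e-4, survival_p = 0.1, u = 0.99),
               0.5)
  expect_equal(roulette(1e-5, survival_p = 1, u = 0.5), 1e-5)
  set.seed(2)
  w <- 1e-5
  out <- roulette(rep(w, 2e5), survival_p = 0.1, u = runif(2e5))
  expect_true(all(out %in% c(0, w / 0.1)))
  se <- sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - w), 3 * se)
})

test_that("an absorption-free index-matched medium conserves weight exactly", {
  hs <- homog_setup(mua = 0, musp = 1, g = 0, extent = c(20, 20, 10))
  r <- simulate_photons(hs$volume, hs$media, source_spec(0), NULL, 550,
                        2e4, seed = 7)
  led <- r$ledger
  expect_identical(unname(led["absorbed"]), 0)
  expect_equal(unname(led["escaped_top"] + led["escaped_sides_bottom"] +
                        led["detected"] + led["roulette_killed"]),
               r$launched, tolerance = 1e-12)
})

test_that("ballistic transmission through a pure absorber is Beer-Lambert exact", {
  slab <- absorbing_slab(mua = 0.3, depth_mm = 5)
  r <- simulate_photons(slab$volume, slab$media, source_spec(0), NULL, 550,
                        1000, seed = 1, record_transmission = TRUE)
  expect_equal(unname(r$ledger["escaped_sides_bottom"]) / r$launched,
               exp(-0.3 * 5), tolerance = 1e-12)
  # every transmitted record crossed exactly the slab thickness
  expect_equal(unname(r$records[, "total_l"]), rep(5, nrow(r$records)))
  expect_equal(abs(sum(r$ledger) - r$launched) / r$launched, 0,
               tolerance = 1e-9)
})

test_that("identical seed and configuration reproduce the run bitwise", {
  ts <- tiny_skin(seed = 3)
  med <- skin_media()
  det <- ring_detectors(0.6, 0.4)
  a <- simulate_photons(ts$volume, med, source_spec(0.4), det, 523, 5e3,
                        seed = 99)
  b <- simulate_photons(ts$volume, med, source_spec(0.4), det, 523, 5e3,
                        seed = 99)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$records, b$records)
  c <- simulate_photons(ts$volume, med, source_spec(0.4), det, 523, 5e3,
                        seed = 100)
  expect_false(identical(a$ledger, c$ledger))
})

test_that("weight ledger closes on heterogeneous mismatched-boundary runs", {
  ts <- tiny_skin(seed = 4)
  med <- skin_media()          # n = 1.4 against ambient air
  det <- ring_detectors(0.6, 0.4)
  for (wl in c(523, 945)) {
    r <- simulate_photons(ts$volume, med, source_spec(0.4), det, wl, 2e4,
                          seed = 21)
    expect_lt(abs(sum(r$ledger) - r$launched) / r$launched, 1e-9)
    expect_true(all(r$records[, "weight"] > 0))
  }
})

test_that("partial pathlengths add up to the independently tracked total", {
  ts <- tiny_skin(seed = 8)
  med <- skin_media()
  det <- ring_detectors(0.6, 0.4)
  r <- simulate_photons(ts$volume, med, source_spec(0.4), det, 523, 2e4,
                        seed = 13)
  expect_gt(nrow(r$records), 100)
  lcols <- grep("^l_", colnames(r$records))
  expect_equal(rowSums(r$records[, lcols]), unname(r$records[, "total_l"]),
               tolerance = 1e-6)
})

test_that("detected weight is non-increasing in absorption (coupled seeds)", {
  det <- ring_detectors(1.0, 0.8)
  w <- sapply(c(0.01, 0.05, 0.2), function(mua) {
    hs <- homog_setup(mua, musp = 1.5, g = 0.9, extent = c(10, 10, 8))
    r <- simulate_photons(hs$volume, hs$media, source_spec(0.2), det, 550,
                          5e4, seed = 31)
    unname(r$ledger["detected"])
  })
  expect_true(all(diff(w) < 0))
})

test_that("absorbed energy in blood voxels grows with vessel dilation (fluence)", {
  med <- skin_media()
  runs <- lapply(c(75, 117), function(d) {
    ts <- tiny_skin(diameter_um = d, seed = 6, extent = c(2, 2, 1.1))
    r <- simulate_photons(ts$volume, med, source_spec(0.4), NULL, 523, 2e4,
                          seed = 17, fluence = TRUE)
    sum(r$fluence[ts$volume$labels == 3L])
  })
  expect_gt(runs[[2]], runs[[1]])
})

test_that("source validation rejects impossible configurations", {
  hs <- homog_setup(0.01, 1, 0.9, extent = c(10, 10, 5))
  expect_error(simulate_photons(hs$volume, hs$media,
                                source_spec(0.4, center_mm = c(50, 5)),
                                NULL, 550, 10), "source center")
  expect_error(simulate_photons(hs$volume, hs$media, source_spec(0.4),
                                ring_detectors(8, 1), 550, 10),
               "detector")
  bad <- medium_table(medium("m", 0.01, 1, 0.9, 1.4))
  ts <- tiny_skin(seed = 2)
  expect_error(simulate_photons(ts$volume, bad, source_spec(0.4), NULL,
                                550, 10), "absent")
})
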