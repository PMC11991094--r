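# PPG analysis layer: DRS, AC/DC, mean optical pathlength, waveforms.

test_that("measured-mode DRS applies the reference reflectance factor", {
  expect_equal(drs_from_counts(800, 1000), 0.792)
  expect_equal(drs_from_counts(1000, 1000, 1), 1)
  expect_error(drs_from_counts(800, 0), "reference")
})

test_that("AC/DC matches hand-worked evaluations and is symmetric", {
  # -log DRS pair 0.5 / 0.4 -> 100 * 0.1 / 0.4 = 25%
  expect_equal(ac_dc(exp(-0.5), exp(-0.4)), 25)
  # DRS pair (e^-1, e^-1.1) -> 100 * 0.1 / 1.0 = 10%
  expect_equal(ac_dc(exp(-1), exp(-1.1)), 10)
  expect_equal(ac_dc(0.37, 0.37), 0)
  expect_equal(ac_dc(0.2, 0.6), ac_dc(0.6, 0.2))
  expect_error(ac_dc(1.0, 0.5), "denominator")
  expect_error(ac_dc(-0.1, 0.5), "DRS")
  expect_error(ac_dc(0.5, 1.5), "DRS")
})

test_that("AC/DC is sensitive to a common multiplicative reference error", {
  # Eq-style ratio is NOT invariant to rescaling both DRS values: a shared
  # calibration factor k shifts both -log values by -log k and changes the
  # denominator. Documented sensitivity, asserted as such.
  a <- ac_dc(0.30, 0.25)
  b <- ac_dc(0.30 * 0.9, 0.25 * 0.9)
  expect_false(isTRUE(all.equal(a, b)))
  expect_lt(b, a)  # dimmer reference -> larger baseline -> smaller ratio
})

test_that("mean optical pathlength is the detected-weight average", {
  expect_equal(mop(fake_records(w = 1, l = 3)), 3)
  expect_equal(mop(fake_records(w = c(1, 3), l = c(2, 4))), 3.5)
  expect_equal(mop(fake_records(w = c(2, 6), l = c(2, 4))), 3.5)  # scale-free
  # brute-force oracle on random records
  set.seed(5)
  w <- runif(500); l <- runif(500, 0, 10)
  expect_equal(mop(fake_records(w, l)), sum(w * l) / sum(w),
               tolerance = 1e-12)
  # media subset: partial pathlengths (fixture splits l evenly over 2 media)
  expect_equal(mop(fake_records(c(1, 3), c(2, 4)), media = "a"), 3.5 / 2)
  expect_error(mop(fake_records(numeric(0), numeric(0))), "records")
  expect_error(mop(fake_records(c(0, 0), c(1, 2))), "zero")
})

test_that("waveforms are the negative log of the DRS series", {
  drs <- c(0.5, 0.4, 0.3, 0.4, 0.5)
  wf <- waveform_from_series(drs, 540)
  expect_equal(wf$neg_log_drs, -log(drs))
  expect_equal(waveform_acdc(wf), ac_dc(min(drs), max(drs)))
  # two-point series reduces exactly to ac_dc
  expect_equal(waveform_acdc(waveform_from_series(c(0.5, 0.4))),
               ac_dc(0.5, 0.4))
  flat <- waveform_from_series(rep(0.3, 4))
  expect_equal(waveform_acdc(flat), 0)
  expect_error(waveform_from_series(0.5), "length")
  expect_error(waveform_from_series(c(0.5, 0)), "finite")
})

test_that("simulated DRS is detected weight over launched weight per SDD group", {
  hs <- homog_setup(0.01, 1.5, 0.9, extent = c(12, 12, 6))
  det <- ring_detectors(c(0.8, 1.6), 0.6)
  r <- simulate_photons(hs$volume, hs$media, source_spec(0.2), det, 550,
                        3e4, seed = 3)
  d <- compute_drs(r)
  for (i in seq_len(nrow(d))) {
    ids <- r$detectors$id[r$detectors$sdd_mm == d$sdd_mm[i]]
    w <- sum(r$records[r$records[, "detector"] %in% ids, "weight"])
    expect_equal(d$drs[i], w / r$launched)
  }
  expect_true(all(d$drs > 0 & d$drs <= 1))
})

test_that("empty detection is flagged, not silently zero", {
  slab <- absorbing_slab(mua = 5, depth_mm = 2)   # opaque, no scatter
  det <- ring_detectors(1, 0.5)
  r <- simulate_photons(slab$volume, slab$media, source_spec(0), det, 550,
                        100, seed = 1)
  d <- compute_drs(r)
  expect_true(d$empty)
  expect_true(is.na(d$drs))
})

test_that("pulse metrics behave like a pulse: symmetry, zero self-contrast, blood monotonicity", {
  med <- skin_media()
  det <- ring_detectors(0.6, 0.5)
  dia <- tiny_skin(diameter_um = 117, seed = 12)
  sys_spec <- dilate_vessels(dia$spec, 75)
  sys <- list(volume = build_skin_volume(sys_spec, c(2, 2, 1.1), 0.01))
  rs <- simulate_photons(sys$volume, med, source_spec(0.4), det, 523, 4e4,
                         seed = 55)
  rd <- simulate_photons(dia$volume, med, source_spec(0.4), det, 523, 4e4,
                         seed = 55)
  # identical runs in both slots -> zero AC/DC
  self <- pulse_metrics(rd, rd, 0.6)
  expect_equal(self$ac_dc_percent, 0)
  pm <- pulse_metrics(rs, rd, 0.6, boot_seed = 9)
  # dilated vessels absorb more: diastolic DRS below systolic
  expect_lt(compute_drs(rd)$drs, compute_drs(rs)$drs)
  expect_gt(pm$ac_dc_percent, 0)
  expect_true(is.finite(pm$ac_dc_se) && pm$ac_dc_se > 0)
  expect_gt(pm$mop_mm, 0)
  # AC/DC part is invariant to the order of the two phases
  pm_swap <- pulse_metrics(rd, rs, 0.6, boot_seed = 9,
                           mop_phase = "pooled")
  expect_equal(pm_swap$ac_dc_percent, pm$ac_dc_percent)
  # MOP defaults to the diastole records
  expect_equal(pm$mop_mm, mop(rd, 0.6))
})
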