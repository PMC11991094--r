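# Synthetic phantom-series generator: forward model, noise, emulated
# measurement sets.

test_that("series constructor enforces the pulse-shaped arc", {
  s <- phantom_series()
  expect_equal(length(s$hb_mg_ml), 7)
  expect_equal(range(s$hb_mg_ml), c(2.0, 3.1))
  expect_error(phantom_series(hb_mg_ml = c(2, 3, 2, 3)), "arc")
  expect_error(phantom_series(hb_mg_ml = c(-1, 2, 1)), "positive")
})

test_that("forward DRS decreases with hemoglobin and honors Beer-Lambert limits", {
  ser <- phantom_series(d_mm = 0)
  g <- forward_drs(ser)
  expect_true(all(g > 0 & g <= 1))
  at <- function(wl) g[, as.character(wl)]
  # strictly decreasing over the rising half of the arc wherever Hb absorbs
  for (wl in c(450, 540, 580)) expect_true(all(diff(at(wl)[1:4]) < 0))
  # doubling the bottom-layer absorber never increases DRS at any wavelength
  ser2 <- phantom_series(hb_mg_ml = 2 * ser$hb_mg_ml, d_mm = 0)
  expect_true(all(forward_drs(ser2) <= g))
  # -log DRS at 540 is pulse-shaped: rises to the 3.1 mg/mL apex, returns
  p <- -log(at(540))
  expect_equal(unname(which.max(p)), 4)
  expect_true(all(diff(p[1:4]) > 0) && all(diff(p[4:7]) < 0))
})

test_that("an ink top layer darkens short wavelengths preferentially", {
  ser0 <- phantom_series(d_mm = 0)
  ser2 <- phantom_series(d_mm = 0.20)
  g0 <- forward_drs(ser0); g2 <- forward_drs(ser2)
  drop <- 1 - g2 / g0
  expect_gt(mean(drop[, "450"]), mean(drop[, "900"]))
  expect_identical(attr(g2, "approximation"), "two-layer")
})

test_that("noise model is seeded, multiplicative, and unbiased in the mean", {
  ser <- phantom_series(d_mm = 0, wavelength_nm = seq(500, 600, 10))
  g <- forward_drs(ser)
  expect_equal(add_noise(g, noise_model(sd = 0))[, , 1], g,
               ignore_attr = TRUE)
  n1 <- add_noise(g, noise_model(sd = 0.01, seed = 42), replicates = 2)
  n2 <- add_noise(g, noise_model(sd = 0.01, seed = 42), replicates = 2)
  expect_identical(n1, n2)
  n3 <- add_noise(g, noise_model(sd = 0.01, seed = 43), replicates = 2)
  expect_false(identical(n1, n3))
  # law of large numbers: replicate mean converges to truth (1% tolerance)
  big <- add_noise(g[1, , drop = FALSE], noise_model(sd = 0.05, seed = 7),
                   replicates = 1e4)
  expect_lt(max(abs(apply(big, 2, mean) / g[1, ] - 1)), 0.01)
})

test_that("emulated measurement sets round-trip through the pipeline", {
  ser <- phantom_series(d_mm = 0, wavelength_nm = seq(450, 900, 10),
                        replicates = 3)
  dir <- withr::local_tempdir()
  man <- emulate_measurement_set(ser, noise_model(sd = 0), dir)
  files <- list.files(dir)
  expect_length(grep("^phantom", files), 21)       # 7 phantoms x 3 reps
  expect_true("reference.txt" %in% files)
  out <- run_phantom_pipeline(phantom_config(man,
                                             waveform_wavelengths_nm = 540))
  g <- forward_drs(ser)
  # noiseless pipeline reproduces the forward model exactly
  d1 <- out$drs[out$drs$phantom == 1, ]
  expect_equal(d1$drs_mean, unname(g[1, ]), tolerance = 1e-9)
  expect_equal(max(out$drs$drs_sd), 0, tolerance = 1e-12)
  a540 <- out$acdc$ac_dc_percent[out$acdc$wavelength_nm == 540]
  expect_equal(a540, waveform_acdc(waveform_from_series(g[, "540"])),
               tolerance = 1e-9)
})

test_that("noisy pipeline AC/DC stays within three replicate SDs of truth", {
  ser <- phantom_series(d_mm = 0, wavelength_nm = seq(500, 600, 20),
                        replicates = 6)
  dir <- withr::local_tempdir()
  man <- emulate_measurement_set(ser, noise_model(sd = 0.01, seed = 11), dir)
  out <- run_phantom_pipeline(phantom_config(man,
                                             waveform_wavelengths_nm = 540))
  g <- forward_drs(ser)
  truth <- waveform_acdc(waveform_from_series(g[, "540"]))
  row <- out$acdc[out$acdc$wavelength_nm == 540, ]
  expect_lt(abs(row$ac_dc_percent - truth), 3 * row$ac_dc_sd)
})
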