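# Chromophore spectra and optical-property assembly.

test_that("Beer-Lambert extraction matches hand-worked values and rejects bad input", {
  expect_equal(beer_lambert_mua(1.0, 10), 0)
  expect_equal(beer_lambert_mua(exp(-1), 1), 1.0)
  expect_equal(beer_lambert_mua(0.25, 2), log(4) / 2)
  expect_error(beer_lambert_mua(0, 1), "transmission")
  expect_error(beer_lambert_mua(1.2, 1), "transmission")
  expect_error(beer_lambert_mua(0.5, 0), "pathlength")
  expect_error(beer_lambert_mua(0.5, -2), "pathlength")
})

test_that("Beer-Lambert round-trips mu_a over the working range", {
  mu <- c(0, 1e-3, 0.1, 1, 5, 10)
  for (L in c(0.1, 1, 10)) {
    expect_equal(beer_lambert_mua(exp(-mu * L), L), mu, tolerance = 1e-12)
  }
})

test_that("concentration scaling is linear and handles edge cases", {
  base <- spectrum(c(450, 600, 900), c(0.5, 0.5, 0.5))
  expect_equal(scale_concentration(base, 2, 2)$value, base$value)
  expect_equal(scale_concentration(base, 2, 0)$value, rep(0, 3))
  expect_equal(scale_concentration(base, 2.0, 3.1)$value, rep(0.775, 3))
  # composition: scale by c1 then by c2/c1 equals scaling by c2
  s1 <- scale_concentration(base, 2, 1.3)
  s2 <- scale_concentration(s1, 1.3, 2.9)
  expect_equal(s2$value, scale_concentration(base, 2, 2.9)$value,
               tolerance = 1e-12)
  expect_error(scale_concentration(base, 0, 1), "base_conc")
})

test_that("similarity relation recovers mu_s from mu_s'", {
  expect_equal(mus_from_reduced(1.0, 0.0), 1.0)
  expect_equal(mus_from_reduced(1.0, 0.9), 10.0)
  expect_equal(mus_from_reduced(0.0, 0.9), 0.0)
  expect_error(mus_from_reduced(1.0, 1.0), "g must")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(500, 500), c(1, 1)), "increasing")
  expect_error(spectrum(c(300, 500), c(1, 1)), "400")
  expect_error(spectrum(500, -1), "non-negative")
  expect_error(spectrum(500, NaN), "finite")
  expect_error(interp_spectrum(spectrum(c(500, 600), c(1, 2)), 700),
               "outside")
  expect_equal(interp_spectrum(spectrum(c(500, 600), c(1, 2)), 550), 1.5)
})

test_that("default chromophore spectra are non-negative with hemoglobin band structure", {
  wl <- default_wavelengths()
  hb <- hb_mua(wl, 2.0)
  ink <- ink_mua(wl)
  il <- intralipid_musp(wl)
  expect_true(all(hb$value >= 0))
  expect_true(all(ink$value >= 0))
  expect_true(all(il$value >= 0))
  at <- function(s, w) s$value[s$wavelength_nm == w]
  # alpha/beta Hb bands: 540 above 560, 580 above 600
  expect_gt(at(hb, 540), at(hb, 560))
  expect_gt(at(hb, 580), at(hb, 600))
  # ink/melanin and lipid scattering decay monotonically with wavelength
  expect_true(all(diff(ink$value) < 0))
  expect_true(all(diff(il$value) < 0))
})

test_that("medium tables resolve per-wavelength engine properties", {
  mt <- phantom_media(hb_mg_ml = 2.0)
  p <- resolve_media(mt, 540)
  expect_equal(rownames(p), c("top_ink", "bottom_hb"))
  expect_equal(unname(p["bottom_hb", "mua"]),
               interp_spectrum(hb_mua(conc_mg_ml = 2), 540))
  # mu_s' recoverable as mus * (1 - g)
  expect_equal(unname(p["bottom_hb", "mus"] * (1 - p["bottom_hb", "g"])),
               interp_spectrum(intralipid_musp(), 540), tolerance = 1e-12)
  expect_error(resolve_media(mt, c(500, 600)))
})

test_that("spectrum files round-trip through the two-column text format", {
  sp <- hb_mua(seq(450, 900, 50), 2.5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, f, comment = "test spectrum")
  back <- read_spectrum(f)
  expect_equal(back$wavelength_nm, sp$wavelength_nm)
  expect_equal(back$value, sp$value, tolerance = 1e-12)
})
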