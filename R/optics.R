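# Chromophore spectra, Beer-Lambert extraction, per-medium optical
# properties on a wavelength grid.

#' Default wavelength grid
#'
#' The instrument band used throughout: 450--900 nm in 2 nm steps.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(450, 900, by = 2)

#' Construct a spectrum
#'
#' A spectrum is a data frame with columns `wavelength_nm` (strictly
#' increasing, within 400--1000 nm) and `value` (finite; non-negative when
#' `coefficient = TRUE`). Units of `value` depend on context: mm^-1 for
#' absorption/scattering coefficients, dimensionless for transmission.
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param value Per-wavelength values, same length.
#' @param coefficient If `TRUE` (default), values must be non-negative.
#' @return A `ppg_spectrum` data frame.
#' @export
spectrum <- function(wavelength_nm, value, coefficient = TRUE) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength_nm and value must have the same length")
  if (length(wavelength_nm) < 1L) stop("empty spectrum")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(wavelength_nm < 400 | wavelength_nm > 1000))
    stop("wavelengths must lie within [400, 1000] nm")
  if (any(!is.finite(value))) stop("spectrum values must be finite")
  if (coefficient && any(value < 0))
    stop("coefficient spectra must be non-negative")
  structure(data.frame(wavelength_nm = wavelength_nm, value = value),
            class = c("ppg_spectrum", "data.frame"))
}

#' Interpolate a spectrum at new wavelengths
#'
#' Linear interpolation; querying outside the tabulated range is an error
#' (no extrapolation).
#'
#' @param spec A `ppg_spectrum`.
#' @param wavelength_nm Query wavelengths in nm.
#' @return Numeric vector of interpolated values.
#' @export
interp_spectrum <- function(spec, wavelength_nm) {
  rng <- range(spec$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  stats::approx(spec$wavelength_nm, spec$value, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' Absorption coefficient from measured transmission (Beer-Lambert)
#'
#' mu_a = -ln(T) / L for collimated transmission T through pathlength L.
#'
#' @param transmission Transmission in (0, 1]; may be a vector.
#' @param pathlength_mm Cuvette pathlength in mm, > 0.
#' @return Absorption coefficient(s) in mm^-1, >= 0.
#' @examples
#' beer_lambert_mua(exp(-1), 1)   # 1 mm^-1
#' beer_lambert_mua(0.25, 2)      # log(4)/2
#' @export
beer_lambert_mua <- function(transmission, pathlength_mm) {
  if (any(!is.finite(transmission)) || any(transmission <= 0) ||
      any(transmission > 1))
    stop("transmission must lie in (0, 1]")
  if (any(!is.finite(pathlength_mm)) || any(pathlength_mm <= 0))
    stop("pathlength must be > 0")
  -log(transmission) / pathlength_mm
}

#' Scale an absorption spectrum to a new chromophore concentration
#'
#' Beer-Lambert linearity: mu_a scales with concentration.
#'
#' @param base A `ppg_spectrum` of mu_a at concentration `base_conc`.
#' @param base_conc Reference concentration (mg/mL), > 0.
#' @param target_conc Target concentration (mg/mL), >= 0.
#' @return A `ppg_spectrum` with scaled values.
#' @export
scale_concentration <- function(base, base_conc, target_conc) {
  if (!is.finite(base_conc) || base_conc <= 0)
    stop("base_conc must be > 0")
  if (!is.finite(target_conc) || target_conc < 0)
    stop("target_conc must be >= 0")
  spectrum(base$wavelength_nm, base$value * target_conc / base_conc)
}

#' Scattering coefficient from the reduced scattering coefficient
#'
#' Similarity relation mu_s = mu_s' / (1 - g).
#'
#' @param mus_prime Reduced scattering coefficient(s), mm^-1, >= 0.
#' @param g Scattering anisotropy in (-1, 1).
#' @return mu_s in mm^-1.
#' @export
mus_from_reduced <- function(mus_prime, g) {
  if (any(!is.finite(g)) || any(g >= 1) || any(g <= -1))
    stop("g must lie in (-1, 1)")
  if (any(mus_prime < 0)) stop("mus_prime must be >= 0")
  mus_prime / (1 - g)
}

# Oxyhemoglobin-like molar shape anchors (mm^-1 per mg/mL of Hb), derived
# from tabulated HbO2 extinction via mu_a = ln(10) * eps * C / MW with
# MW 64500 g/mol. Shape only is load-bearing (alpha/beta bands at 577/540 nm,
# deep red-NIR trough, mild NIR rise); these are shipped defaults, not the
# source study's (unpublished) spectra.
.hb_anchor <- function() {
  list(
    wl = c(400, 440, 450, 460, 480, 500, 510, 520, 530, 540, 548, 556, 562,
           570, 577, 585, 590, 600, 620, 650, 700, 750, 800, 850, 900, 945,
           1000),
    v = c(1.20, 0.43, 0.22, 0.12, 0.093, 0.072, 0.080, 0.100, 0.143, 0.203,
          0.172, 0.124, 0.118, 0.170, 0.207, 0.125, 0.061, 0.0114, 0.0036,
          0.0014, 0.00125, 0.0019, 0.0029, 0.0037, 0.0043, 0.0045, 0.0039))
}

#' Default hemoglobin absorption spectrum
#'
#' Oxyhemoglobin-like mu_a spectrum scaled linearly with concentration.
#' Exhibits the alpha/beta band local maxima near 577 and 540 nm and the
#' steep drop beyond 600 nm that drive the green-versus-NIR PPG contrast.
#' Whole blood corresponds to roughly 150 mg/mL.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param conc_mg_ml Hemoglobin concentration in mg/mL.
#' @return A `ppg_spectrum` of mu_a in mm^-1.
#' @export
hb_mua <- function(wavelength_nm = default_wavelengths(), conc_mg_ml = 1) {
  a <- .hb_anchor()
  base <- spectrum(a$wl, a$v)
  spectrum(wavelength_nm, interp_spectrum(base, wavelength_nm) * conc_mg_ml)
}

#' Default India-ink (melanin-like) absorption spectrum
#'
#' Monotone power-law decay, mu_a(lambda) = a0 * (lambda/500)^-3, mimicking
#' the epidermal melanin spectral shape. `dilution = 1` corresponds to the
#' 1% v/v working dilution (a0 = 2 mm^-1 at 500 nm by default).
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param dilution Multiplicative concentration factor (1 = 1% v/v).
#' @param a0 mu_a at 500 nm for dilution 1, mm^-1.
#' @return A `ppg_spectrum` of mu_a in mm^-1.
#' @export
ink_mua <- function(wavelength_nm = default_wavelengths(), dilution = 1,
                    a0 = 2.0) {
  spectrum(wavelength_nm, dilution * a0 * (wavelength_nm / 500)^-3)
}

#' Default Intralipid reduced scattering spectrum
#'
#' Power-law mu_s'(lambda) = b0 * (lambda/500)^-2.4 for a 1% w/v lipid
#' emulsion (b0 = 2.5 mm^-1 at 500 nm), scaled linearly with concentration.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param conc_pct Lipid concentration in % w/v.
#' @param b0 mu_s' at 500 nm for 1% w/v, mm^-1.
#' @return A `ppg_spectrum` of mu_s' in mm^-1.
#' @export
intralipid_musp <- function(wavelength_nm = default_wavelengths(),
                            conc_pct = 1, b0 = 2.5) {
  spectrum(wavelength_nm, conc_pct * b0 * (wavelength_nm / 500)^-2.4)
}

#' Default melanin-pigmented epidermis absorption spectrum
#'
#' mu_a(lambda) = scale * (lambda/500)^-3 mm^-1 for a moderately-to-heavily
#' pigmented epidermis.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param scale mu_a at 500 nm, mm^-1.
#' @return A `ppg_spectrum` of mu_a in mm^-1.
#' @export
epidermis_mua <- function(wavelength_nm = default_wavelengths(), scale = 4) {
  spectrum(wavelength_nm, scale * (wavelength_nm / 500)^-3)
}

#' Default skin reduced scattering spectrum
#'
#' mu_s'(lambda) = 4.6 * (lambda/500)^-1.42 mm^-1 (generic soft-tissue
#' power law), used for both epidermis and dermis.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @return A `ppg_spectrum` of mu_s' in mm^-1.
#' @export
skin_musp <- function(wavelength_nm = default_wavelengths()) {
  spectrum(wavelength_nm, 4.6 * (wavelength_nm / 500)^-1.42)
}

#' Construct per-wavelength optical properties
#'
#' @param mua Absorption coefficient, mm^-1, >= 0.
#' @param mus Scattering coefficient, mm^-1, >= 0.
#' @param g Anisotropy in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return A named list of class `optical_properties`.
#' @export
optical_properties <- function(mua, mus, g, n) {
  if (any(!is.finite(c(mua, mus, g, n)))) stop("properties must be finite")
  if (mua < 0 || mus < 0) stop("mua and mus must be >= 0")
  if (abs(g) >= 1) stop("g must lie in (-1, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n),
            class = "optical_properties")
}

#' Define a medium by its spectra
#'
#' `mua` and `musp` may be `ppg_spectrum` objects or single constants
#' (interpreted as wavelength-independent).
#'
#' @param name Medium name.
#' @param mua Absorption spectrum (mm^-1) or constant.
#' @param musp Reduced scattering spectrum (mm^-1) or constant.
#' @param g Anisotropy in (-1, 1).
#' @param n Refractive index >= 1.
#' @return A `ppg_medium` list.
#' @export
medium <- function(name, mua, musp, g, n) {
  stopifnot(is.character(name), length(name) == 1)
  if (abs(g) >= 1) stop("g must lie in (-1, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(list(name = name, mua = mua, musp = musp, g = g, n = n),
            class = "ppg_medium")
}

#' Assemble a medium table
#'
#' Media are assigned integer ids 1, 2, ... in the order given; id 0 is
#' reserved for the ambient (non-tissue) medium, described only by its
#' refractive index.
#'
#' @param ... `medium()` objects, in id order.
#' @param n_ambient Ambient refractive index (default 1, air).
#' @return A `medium_table` list.
#' @export
medium_table <- function(..., n_ambient = 1.0) {
  media <- list(...)
  if (length(media) == 1 && is.list(media[[1]]) &&
      !inherits(media[[1]], "ppg_medium"))
    media <- media[[1]]
  if (!length(media)) stop("at least one medium required")
  for (m in media)
    if (!inherits(m, "ppg_medium")) stop("all entries must be media")
  if (n_ambient < 1) stop("n_ambient must be >= 1")
  structure(list(media = media, n_ambient = n_ambient),
            class = "medium_table")
}

.eval_spec <- function(x, wavelength_nm) {
  if (inherits(x, "ppg_spectrum")) interp_spectrum(x, wavelength_nm)
  else if (is.numeric(x) && length(x) == 1) rep(x, length(wavelength_nm))
  else stop("expected a spectrum or a single constant")
}

#' Resolve a medium table at one wavelength
#'
#' @param table A `medium_table`.
#' @param wavelength_nm Single wavelength in nm.
#' @return Matrix with one row per medium id (1..M) and columns
#'   `mua`, `mus`, `g`, `n`; mu_s is derived via the similarity relation.
#' @export
resolve_media <- function(table, wavelength_nm) {
  stopifnot(inherits(table, "medium_table"), length(wavelength_nm) == 1)
  M <- length(table$media)
  out <- matrix(0, M, 4, dimnames = list(
    vapply(table$media, `[[`, "", "name"), c("mua", "mus", "g", "n")))
  for (i in seq_len(M)) {
    m <- table$media[[i]]
    musp <- .eval_spec(m$musp, wavelength_nm)
    out[i, ] <- c(.eval_spec(m$mua, wavelength_nm),
                  mus_from_reduced(musp, m$g), m$g, m$n)
  }
  out
}

#' Default skin medium table
#'
#' Media: 1 = epidermis, 2 = dermis, 3 = vessel blood. Defaults: melanin-like
#' epidermal absorption, a low dermal baseline, generic soft-tissue
#' scattering, and a vessel-blood compartment with oxyhemoglobin spectral
#' shape scaled by `blood_hb_mg_ml` (default 15 mg/mL, one tenth of whole
#' blood -- see the methods vignette for why the magnitude, which the
#' underlying trends do not depend on, is kept moderate). g and n are not
#' chromophore properties and default to standard tissue values.
#'
#' @param blood_hb_mg_ml Hemoglobin concentration of the vessel compartment.
#' @param melanin_scale Epidermal mu_a at 500 nm, mm^-1.
#' @param g Anisotropy for all skin media.
#' @param n Refractive index for all skin media.
#' @return A `medium_table` (ambient n = 1).
#' @export
skin_media <- function(blood_hb_mg_ml = 15, melanin_scale = 4,
                       g = 0.9, n = 1.40) {
  wl <- seq(400, 1000, by = 2)  # covers both PPG bands incl. 945 nm
  derm_mua <- spectrum(wl, 0.25 * (wl / 500)^-1.5 + 0.03)
  blood_musp <- spectrum(wl, 2.0 * (wl / 500)^-1)
  medium_table(
    medium("epidermis", epidermis_mua(wl, melanin_scale), skin_musp(wl), g, n),
    medium("dermis", derm_mua, skin_musp(wl), g, n),
    medium("blood", hb_mua(wl, blood_hb_mg_ml), blood_musp, g, n),
    n_ambient = 1.0)
}

#' Default two-layer phantom medium table
#'
#' Media: 1 = top layer (ink + lipid + gel), 2 = bottom layer
#' (hemoglobin + lipid + gel). Gel-phantom defaults g = 0.75, n = 1.33.
#'
#' @param hb_mg_ml Bottom-layer hemoglobin concentration, mg/mL.
#' @param ink_dilution Top-layer ink factor (1 = 1% v/v).
#' @param lipid_pct Lipid concentration, % w/v, both layers.
#' @param g Anisotropy.
#' @param n Refractive index.
#' @return A `medium_table` (ambient n = 1).
#' @export
phantom_media <- function(hb_mg_ml = 2.0, ink_dilution = 1, lipid_pct = 1,
                          g = 0.75, n = 1.33) {
  wl <- seq(400, 1000, by = 2)
  musp <- intralipid_musp(wl, lipid_pct)
  medium_table(
    medium("top_ink", ink_mua(wl, ink_dilution), musp, g, n),
    medium("bottom_hb", hb_mua(wl, hb_mg_ml), musp, g, n),
    n_ambient = 1.0)
}

#' Read a spectrum from two-column delimited text
#'
#' Format: whitespace- or comma-delimited `wavelength_nm value` rows;
#' lines starting with `#` are comments.
#'
#' @param path File path.
#' @param coefficient Passed to [spectrum()].
#' @return A `ppg_spectrum`.
#' @export
read_spectrum <- function(path, coefficient = TRUE) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         sep = "", col.names = c("wavelength_nm", "value"))
  spectrum(d$wavelength_nm, d$value, coefficient = coefficient)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spec A `ppg_spectrum`.
#' @param path File path.
#' @param comment Optional comment line (written with a `#` prefix).
#' @export
write_spectrum <- function(spec, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.table(spec[, c("wavelength_nm", "value")], con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
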