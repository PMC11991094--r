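# Synthetic stand-in for the seven-phantom pulse measurement: forward
# model of diffuse reflectance spectra across the hemoglobin arc, a
# wavelength-correlated multiplicative noise model, and an emulated
# measurement set on disk (sample + reference spectra + manifest).

#' Specify a phantom pulse series
#'
#' Bottom-layer hemoglobin concentrations tracing one cardiac pulse: the
#' default seven-point arc rises from 2.0 to 3.1 mg/mL and returns (the
#' printed endpoints of the measured series; the intermediate points are
#' package defaults).
#'
#' @param hb_mg_ml Positive concentrations, pulse-shaped (rising then
#'   falling).
#' @param d_mm Top (ink) layer thickness, mm (0 or 0.20 in the source
#'   study).
#' @param wavelength_nm Wavelength grid.
#' @param replicates Number of phantom sets (default 3).
#' @return A `phantom_series` list.
#' @export
phantom_series <- function(hb_mg_ml = c(2.0, 2.4, 2.8, 3.1, 2.8, 2.4, 2.0),
                           d_mm = 0,
                           wavelength_nm = default_wavelengths(),
                           replicates = 3) {
  if (any(hb_mg_ml <= 0)) stop("concentrations must be positive")
  if (d_mm < 0) stop("top thickness must be >= 0")
  if (replicates < 1) stop("at least one replicate")
  k <- which.max(hb_mg_ml)
  if ((k > 1 && any(diff(hb_mg_ml[1:k]) < 0)) ||
      (k < length(hb_mg_ml) && any(diff(hb_mg_ml[k:length(hb_mg_ml)]) > 0)))
    stop("concentration arc must rise to its apex and then fall")
  structure(list(hb_mg_ml = hb_mg_ml, d_mm = d_mm,
                 wavelength_nm = wavelength_nm,
                 replicates = as.integer(replicates)),
            class = "phantom_series")
}

#' Specify the measurement noise model
#'
#' Multiplicative log-normal noise, correlated along wavelength with a
#' Gaussian kernel length-scale (plausible spectrometer behavior; the
#' magnitudes are configurable because the source study reports only
#' replicate error bars, not a noise law).
#'
#' @param sd Relative standard deviation (default 1%).
#' @param lscale_nm Correlation length along wavelength, nm.
#' @param seed Integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sd = 0.01, lscale_nm = 20, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (lscale_nm < 0) stop("length-scale must be >= 0")
  structure(list(sd = sd, lscale_nm = lscale_nm, seed = as.integer(seed)),
            class = "noise_model")
}

#' Forward-model DRS spectra for a phantom series
#'
#' For each phantom of the series, the diffuse reflectance at the probe
#' SDD (default 0.5 mm). Engines:
#' * `"diffusion"`: closed-form semi-infinite diffusion reflectance of the
#'   bottom layer, with the documented approximate Beer-Lambert correction
#'   for a non-zero ink top layer ([two_layer_reflectance()]); DRS is the
#'   reflectance integrated over the collection area. Fast and analytic.
#' * `"mc"`: full voxel Monte Carlo on the two-layer phantom volume with a
#'   ring detector at the probe SDD (slow; intended for a few wavelengths).
#'
#' @param series A `phantom_series`.
#' @param engine `"diffusion"` or `"mc"`.
#' @param sdd_mm Probe source-detector distance, mm.
#' @param ink_dilution,lipid_pct Top-layer ink factor and lipid
#'   concentration passed to [phantom_media()].
#' @param collection_area_mm2 Collection area converting R(rho) to a
#'   dimensionless DRS (diffusion engine).
#' @param path_factor Top-layer pathlength factor (diffusion engine).
#' @param n_photons,seed,voxel_mm Monte Carlo engine controls.
#' @return Matrix (phantom x wavelength) of DRS values with attributes
#'   `series`, `engine`, and `provenance` (`"synthetic"`); the diffusion
#'   engine with `d_mm > 0` additionally carries
#'   `approximation = "two-layer"`.
#' @export
forward_drs <- function(series, engine = c("diffusion", "mc"), sdd_mm = 0.5,
                        ink_dilution = 1, lipid_pct = 1,
                        collection_area_mm2 = pi * 0.2^2, path_factor = 4,
                        n_photons = 2e5, seed = 1L, voxel_mm = 0.02) {
  stopifnot(inherits(series, "phantom_series"))
  engine <- match.arg(engine)
  wl <- series$wavelength_nm
  out <- matrix(NA_real_, length(series$hb_mg_ml), length(wl),
                dimnames = list(paste0("phantom", seq_along(series$hb_mg_ml)),
                                as.character(wl)))
  if (engine == "diffusion") {
    mua_top <- ink_mua(wl, ink_dilution)$value
    musp <- intralipid_musp(wl, lipid_pct)$value
    hb1 <- hb_mua(wl, 1)$value
    for (i in seq_along(series$hb_mg_ml)) {
      r <- vapply(seq_along(wl), function(k)
        two_layer_reflectance(sdd_mm, mua_top[k], series$d_mm,
                              hb1[k] * series$hb_mg_ml[i], musp[k],
                              n_rel = 1.33, path_factor = path_factor),
        numeric(1))
      out[i, ] <- pmin(1, r * collection_area_mm2)
    }
    if (series$d_mm > 0) attr(out, "approximation") <- "two-layer"
  } else {
    depth <- max(5, series$d_mm + 5)
    lateral <- 2 * (sdd_mm + 2)
    vol <- build_phantom_volume(phantom_spec(series$d_mm),
                                extent_mm = c(lateral, lateral, depth),
                                voxel_mm = voxel_mm)
    det <- ring_detectors(sdd_mm, width_mm = min(0.4, 2 * sdd_mm * 0.8))
    for (i in seq_along(series$hb_mg_ml)) {
      med <- phantom_media(hb_mg_ml = series$hb_mg_ml[i],
                           ink_dilution = ink_dilution,
                           lipid_pct = lipid_pct)
      for (k in seq_along(wl)) {
        res <- simulate_photons(vol, med, source_spec(0.2), det,
                                wavelength_nm = wl[k],
                                n_photons = n_photons, seed = seed)
        out[i, k] <- compute_drs(res, sdd_mm)$drs
      }
    }
  }
  attr(out, "series") <- series
  attr(out, "engine") <- engine
  attr(out, "provenance") <- "synthetic"
  out
}

# Wavelength-correlated standard normal field on grid wl (unit marginal sd).
.correlated_z <- function(n_wl, wl, lscale) {
  z <- stats::rnorm(n_wl)
  if (lscale <= 0 || n_wl < 3) return(z)
  dwl <- if (n_wl > 1) wl[2] - wl[1] else 1
  half <- max(1, ceiling(3 * lscale / dwl))
  kern <- exp(-0.5 * ((-half:half) * dwl / lscale)^2)
  kern <- kern / sqrt(sum(kern^2))   # unit variance after convolution
  zs <- stats::convolve(c(rep(0, half), z, rep(0, half)), rev(kern),
                        type = "filter")
  # edge effects leave sd slightly below 1 near the boundary; acceptable
  zs[seq_len(n_wl)]
}

#' Add measurement noise to a DRS grid
#'
#' Seeded multiplicative log-normal perturbation, correlated along
#' wavelength, independently for each phantom and replicate.
#'
#' @param drs_grid Matrix (phantom x wavelength) from [forward_drs()].
#' @param noise A `noise_model`.
#' @param replicates Number of noisy replicates (default: the series').
#' @return 3-D array (phantom x wavelength x replicate).
#' @export
add_noise <- function(drs_grid, noise, replicates = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  series <- attr(drs_grid, "series")
  if (is.null(replicates))
    replicates <- if (!is.null(series)) series$replicates else 1L
  wl <- as.numeric(colnames(drs_grid))
  np <- nrow(drs_grid); nw <- ncol(drs_grid)
  out <- array(NA_real_, c(np, nw, replicates),
               dimnames = c(dimnames(drs_grid), list(NULL)))
  restore <- .restore_seed()
  on.exit(restore())
  set.seed(noise$seed)
  for (r in seq_len(replicates))
    for (i in seq_len(np)) {
      fac <- if (noise$sd == 0) rep(1, nw)
      else exp(noise$sd * .correlated_z(nw, wl, noise$lscale_nm))
      out[i, , r] <- drs_grid[i, ] * fac
    }
  attr(out, "series") <- series
  attr(out, "provenance") <- "synthetic"
  out
}

# Smooth lamp-like reference intensity profile (arbitrary counts).
.reference_counts <- function(wl) {
  10000 * exp(-0.5 * ((wl - 750) / 320)^2)
}

#' Write an emulated measurement set to disk
#'
#' One two-column sample spectrum file (wavelength_nm, intensity_counts)
#' per phantom per replicate, plus one reference (99%-reflectance-standard)
#' file, plus a JSON manifest mapping files to roles. Sample counts are
#' constructed so that the measured-mode pipeline
#' (sample/reference x 0.99) recovers the (noisy) forward-model DRS
#' exactly.
#'
#' @param series A `phantom_series`.
#' @param noise A `noise_model`.
#' @param dir Output directory (created if needed).
#' @param engine,... Passed to [forward_drs()].
#' @return Invisibly, the manifest path.
#' @export
emulate_measurement_set <- function(series, noise, dir,
                                    engine = "diffusion", ...) {
  stopifnot(inherits(series, "phantom_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- forward_drs(series, engine = engine, ...)
  noisy <- add_noise(grid, noise)
  wl <- series$wavelength_nm
  ref <- .reference_counts(wl)
  ref_file <- "reference.txt"
  write_spectrum(spectrum(wl, ref, coefficient = FALSE),
                 file.path(dir, ref_file),
                 comment = "synthetic 99%-reflectance reference, counts")
  files <- list(list(file = ref_file, role = "reference"))
  for (i in seq_along(series$hb_mg_ml))
    for (r in seq_len(series$replicates)) {
      fn <- sprintf("phantom%02d_rep%d.txt", i, r)
      counts <- noisy[i, , r] / 0.99 * ref
      write_spectrum(spectrum(wl, counts, coefficient = FALSE),
                     file.path(dir, fn),
                     comment = sprintf(
                       "synthetic phantom %d (Hb %.2f mg/mL), replicate %d",
                       i, series$hb_mg_ml[i], r))
      files <- c(files, list(list(file = fn, role = "sample", phantom = i,
                                  replicate = r,
                                  hb_mg_ml = series$hb_mg_ml[i])))
    }
  manifest <- list(kind = "ppgmc_measurement_set", provenance = "synthetic",
                   d_mm = series$d_mm,
                   reference_reflectance = 0.99,
                   noise_sd = noise$sd, noise_seed = noise$seed,
                   package_version = as.character(
                     utils::packageVersion("ppgmc")),
                   files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}
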