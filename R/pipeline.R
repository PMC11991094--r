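# Configuration-driven entry points: the skin sweep (geometry -> transport
# -> pulse metrics table) and the phantom measurement pipeline
# (spectra files -> DRS -> waveforms -> AC/DC spectra), with seeds and
# provenance embedded in every output.

# Rolling polynomial hash over the serialized config; short hex
# provenance tag (stable across sessions for identical configs).
.config_hash <- function(config) {
  raw <- as.numeric(serialize(config, NULL, ascii = TRUE))
  h <- 0
  p <- 2147483647
  for (b in raw) h <- (h * 31 + b) %% p
  sprintf("%08x", as.integer(h))
}

#' Validate a skin-sweep run configuration
#'
#' @param epidermal_um Epidermal thicknesses to sweep, um.
#' @param sdd_mm Source-detector distances, mm.
#' @param wavelength_nm Wavelengths, nm.
#' @param n_photons Photons launched per run (scalar, or named by
#'   wavelength).
#' @param seed Integer base seed.
#' @param extent_mm Volume extent (X, Y, Z), mm.
#' @param voxel_mm Voxel size, mm.
#' @param systole_um,diastole_um Vessel diameters of the two cardiac
#'   phases, um.
#' @param vessel_density_mm2 Cross-sectional vessel density.
#' @param detector `"ring"` (annular, pooled azimuths) or `"disc"`
#'   (three 0.3 mm discs per SDD).
#' @param ring_width_mm Ring width when `detector = "ring"`.
#' @param media A `medium_table` (default [skin_media()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A validated `run_config` list.
#' @export
sweep_config <- function(epidermal_um = c(50, 100, 150),
                         sdd_mm = c(1, 2),
                         wavelength_nm = c(523, 945),
                         n_photons = 2e5, seed = 1L,
                         extent_mm = c(6.6, 6.6, 1.1), voxel_mm = 0.01,
                         systole_um = 75, diastole_um = 117,
                         vessel_density_mm2 = 33.75,
                         detector = c("ring", "disc"), ring_width_mm = 1.0,
                         media = NULL, out_dir = NULL) {
  detector <- match.arg(detector)
  stopifnot(all(epidermal_um > 0), all(sdd_mm > 0), all(wavelength_nm > 0),
            all(n_photons >= 1), voxel_mm > 0, length(extent_mm) == 3)
  if (max(sdd_mm) + ring_width_mm / 2 >= min(extent_mm[1:2]) / 2)
    stop("volume too small for the largest SDD detector")
  if (!is.null(media)) stopifnot(inherits(media, "medium_table"))
  structure(list(experiment = "skin_sweep", epidermal_um = epidermal_um,
                 sdd_mm = sdd_mm, wavelength_nm = wavelength_nm,
                 n_photons = n_photons, seed = as.integer(seed),
                 extent_mm = extent_mm, voxel_mm = voxel_mm,
                 systole_um = systole_um, diastole_um = diastole_um,
                 vessel_density_mm2 = vessel_density_mm2,
                 detector = detector, ring_width_mm = ring_width_mm,
                 media = media, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level field `experiment` selects the validator (`skin_sweep` or
#' `phantom_pipeline`); remaining fields are passed to [sweep_config()]
#' or [phantom_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$experiment)) stop("config must name an experiment")
  exp <- y$experiment
  y$experiment <- NULL
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  switch(exp,
         skin_sweep = do.call(sweep_config, y),
         phantom_pipeline = do.call(phantom_config, y),
         stop("unknown experiment: ", exp))
}

.photons_for <- function(n_photons, wl) {
  if (!is.null(names(n_photons)) && as.character(wl) %in% names(n_photons))
    n_photons[[as.character(wl)]]
  else unname(n_photons[1])
}

#' Run the skin sweep
#'
#' For every (epidermal thickness, wavelength) a coupled systole/diastole
#' pair of Monte Carlo runs is performed (shared seed, shared launch
#' streams), and [pulse_metrics()] is evaluated at every SDD. A failed
#' cell is reported as an NA row and the sweep continues.
#'
#' @param config A `run_config` from [sweep_config()].
#' @param progress Print per-cell timing.
#' @return Data frame with columns `wavelength_nm`, `sdd_mm`, `D_um`,
#'   `ac_dc_percent`, `ac_dc_se`, `mop_mm`, `n_detected`,
#'   `n_detected_total`, `seed`, plus
#'   provenance attributes (`config_hash`, `package_version`). Written to
#'   `out_dir` as TSV and JSON when configured.
#' @export
run_skin_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"),
            config$experiment == "skin_sweep")
  media <- if (is.null(config$media)) skin_media() else config$media
  det <- if (config$detector == "ring")
    ring_detectors(config$sdd_mm, config$ring_width_mm)
  else disc_detectors(config$sdd_mm)
  na_rows <- function(D, wl) {
    data.frame(wavelength_nm = wl, sdd_mm = config$sdd_mm,
               ac_dc_percent = NA_real_, ac_dc_se = NA_real_,
               mop_mm = NA_real_, n_detected = 0L, n_detected_total = 0L,
               seed = config$seed, D_um = D)
  }
  rows <- list()
  for (D in config$epidermal_um) {
    vols <- tryCatch({
      spec_dia <- skin_spec(epidermal_um = D,
                            vessel_diameter_um = config$diastole_um,
                            vessel_density_mm2 = config$vessel_density_mm2,
                            max_diameter_um = max(config$systole_um,
                                                  config$diastole_um),
                            placement_seed = config$seed)
      spec_sys <- dilate_vessels(spec_dia, config$systole_um)
      list(dia = build_skin_volume(spec_dia, config$extent_mm,
                                   config$voxel_mm),
           sys = build_skin_volume(spec_sys, config$extent_mm,
                                   config$voxel_mm))
    }, error = function(e) {
      warning(sprintf("geometry for D=%g um failed: %s", D,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(vols)) {
      rows <- c(rows, lapply(config$wavelength_nm,
                             function(wl) na_rows(D, wl)))
      next
    }
    vol_dia <- vols$dia
    vol_sys <- vols$sys
    for (wl in config$wavelength_nm) {
      np <- .photons_for(config$n_photons, wl)
      cell <- tryCatch({
        t0 <- proc.time()[3]
        res_s <- simulate_photons(vol_sys, media, source_spec(0.4), det,
                                  wavelength_nm = wl, n_photons = np,
                                  seed = config$seed)
        res_d <- simulate_photons(vol_dia, media, source_spec(0.4), det,
                                  wavelength_nm = wl, n_photons = np,
                                  seed = config$seed)
        pm <- do.call(rbind, lapply(config$sdd_mm, function(s)
          pulse_metrics(res_s, res_d, s, boot_seed = config$seed)))
        pm$D_um <- D
        if (progress)
          message(sprintf("D=%g um, %g nm: %.1f s, detected %s",
                          D, wl, proc.time()[3] - t0,
                          paste(pm$n_detected, collapse = "/")))
        pm
      }, error = function(e) {
        warning(sprintf("cell D=%g um, %g nm failed: %s", D, wl,
                        conditionMessage(e)), call. = FALSE)
        na_rows(D, wl)
      })
      rows <- c(rows, list(cell))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("wavelength_nm", "sdd_mm", "D_um", "ac_dc_percent",
                 "ac_dc_se", "mop_mm", "n_detected", "n_detected_total",
                 "seed")]
  attr(out, "config_hash") <- .config_hash(config)
  attr(out, "package_version") <- as.character(utils::packageVersion("ppgmc"))
  if (!is.null(config$out_dir)) .write_outputs(out, config, "skin_sweep")
  out
}

.write_outputs <- function(table, config, stem) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# config_hash=%s seed=%d ppgmc=%s",
                  attr(table, "config_hash"), config$seed,
                  attr(table, "package_version"))
  tsv <- file.path(config$out_dir, paste0(stem, "_metrics.tsv"))
  con <- file(tsv, "w")
  writeLines(prov, con)
  suppressWarnings(utils::write.table(table, con, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  close(con)
  jsonlite::write_json(
    list(provenance = list(config_hash = attr(table, "config_hash"),
                           seed = config$seed,
                           package_version = attr(table, "package_version")),
         metrics = table),
    file.path(config$out_dir, paste0(stem, "_metrics.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(tsv)
}

#' Validate a phantom-pipeline configuration
#'
#' @param manifest Path to a measurement-set manifest
#'   (see [emulate_measurement_set()]).
#' @param waveform_wavelengths_nm Wavelengths at which -log DRS waveforms
#'   are extracted.
#' @param seed Integer seed (bookkeeping only; the pipeline is
#'   deterministic).
#' @param out_dir Output directory or `NULL`.
#' @return A validated `run_config`.
#' @export
phantom_config <- function(manifest,
                           waveform_wavelengths_nm = c(450, 540, 580, 900),
                           seed = 1L, out_dir = NULL) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  structure(list(experiment = "phantom_pipeline", manifest = manifest,
                 waveform_wavelengths_nm = waveform_wavelengths_nm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the phantom measurement pipeline
#'
#' Reads a measurement set (real or emulated), normalizes every sample
#' spectrum against the reference (x 0.99 reflectance factor), and
#' produces the study's phantom outputs: DRS versus wavelength per
#' phantom (replicate mean and sd), -log DRS waveforms at the selected
#' wavelengths, and the AC/DC spectrum with replicate error bars.
#'
#' @param config A `run_config` from [phantom_config()] (or a manifest
#'   path, which is wrapped via [phantom_config()]).
#' @return List with data frames `drs` (phantom x wavelength, mean/sd over
#'   replicates), `waveforms` (phase-ordered -log DRS at the selected
#'   wavelengths), and `acdc` (per wavelength: mean and sd of the AC/DC
#'   over replicates); provenance attributes attached.
#' @export
run_phantom_pipeline <- function(config) {
  if (is.character(config)) config <- phantom_config(config)
  stopifnot(inherits(config, "run_config"),
            config$experiment == "phantom_pipeline")
  man <- jsonlite::read_json(config$manifest, simplifyVector = FALSE)
  if (is.null(man$files) || !length(man$files))
    stop("manifest lists no files")
  dir <- dirname(config$manifest)
  roles <- vapply(man$files, `[[`, "", "role")
  if (!any(roles == "reference"))
    stop("measurement set has no reference file; cannot normalize")
  ref_entry <- man$files[[which(roles == "reference")[1]]]
  ref_path <- file.path(dir, ref_entry$file)
  if (!file.exists(ref_path)) stop("reference file missing: ", ref_path)
  ref <- read_spectrum(ref_path, coefficient = FALSE)
  rr <- if (!is.null(man$reference_reflectance))
    man$reference_reflectance else 0.99
  samples <- man$files[roles == "sample"]
  if (!length(samples)) stop("measurement set has no sample files")

  long <- do.call(rbind, lapply(samples, function(s) {
    sp <- read_spectrum(file.path(dir, s$file), coefficient = FALSE)
    if (!isTRUE(all.equal(sp$wavelength_nm, ref$wavelength_nm)))
      stop("sample and reference wavelength grids differ: ", s$file)
    data.frame(phantom = s$phantom, replicate = s$replicate,
               hb_mg_ml = s$hb_mg_ml, wavelength_nm = sp$wavelength_nm,
               drs = drs_from_counts(sp$value, ref$value, rr))
  }))

  agg <- function(v, idx) tapply(v, idx, mean)
  key <- interaction(long$phantom, long$wavelength_nm)
  drs_df <- do.call(rbind, lapply(split(long, key), function(d)
    data.frame(phantom = d$phantom[1], hb_mg_ml = d$hb_mg_ml[1],
               wavelength_nm = d$wavelength_nm[1],
               drs_mean = mean(d$drs),
               drs_sd = if (nrow(d) > 1) stats::sd(d$drs) else 0)))
  drs_df <- drs_df[order(drs_df$phantom, drs_df$wavelength_nm), ]
  rownames(drs_df) <- NULL

  wls <- config$waveform_wavelengths_nm
  wf <- do.call(rbind, lapply(wls, function(wl) {
    d <- drs_df[abs(drs_df$wavelength_nm - wl) ==
                  min(abs(drs_df$wavelength_nm - wl)), ]
    d <- d[order(d$phantom), ]
    w <- waveform_from_series(d$drs_mean, wavelength_nm = d$wavelength_nm[1])
    data.frame(wavelength_nm = d$wavelength_nm[1], phase = w$phase,
               hb_mg_ml = d$hb_mg_ml, neg_log_drs = w$neg_log_drs)
  }))

  acdc_df <- do.call(rbind, lapply(split(long, long$wavelength_nm),
                                   function(d) {
    per_rep <- vapply(split(d, d$replicate), function(r) {
      r <- r[order(r$phantom), ]
      waveform_acdc(waveform_from_series(r$drs))
    }, numeric(1))
    data.frame(wavelength_nm = d$wavelength_nm[1],
               ac_dc_percent = mean(per_rep),
               ac_dc_sd = if (length(per_rep) > 1) stats::sd(per_rep) else 0,
               n_replicates = length(per_rep))
  }))
  acdc_df <- acdc_df[order(acdc_df$wavelength_nm), ]
  rownames(acdc_df) <- NULL

  out <- list(drs = drs_df, waveforms = wf, acdc = acdc_df)
  attr(out, "config_hash") <- .config_hash(config)
  attr(out, "package_version") <- as.character(utils::packageVersion("ppgmc"))
  attr(out, "seed") <- config$seed
  if (!is.null(config$out_dir)) {
    cfg2 <- config
    acdc_out <- acdc_df
    attr(acdc_out, "config_hash") <- attr(out, "config_hash")
    attr(acdc_out, "package_version") <- attr(out, "package_version")
    .write_outputs(acdc_out, cfg2, "phantom_acdc")
  }
  out
}
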