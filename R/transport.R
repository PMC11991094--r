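# R-level surface of the Monte Carlo transport engine: sources, detectors,
# the simulate call, and the elementary sampling operations (exposed for
# direct use and for oracle testing).

#' Specify a surface source
#'
#' Gaussian beam at normal incidence. Beam diameter convention: diameter =
#' 2 sigma of the radial Gaussian (so `beam_diameter_mm = 0.4` means
#' sigma = 0.2 mm). A diameter of 0 gives a pencil beam.
#'
#' @param beam_diameter_mm Gaussian beam diameter (2 sigma), >= 0.
#' @param center_mm Length-2 (x, y) position on the surface in mm, or
#'   `NULL` for the lateral center of the volume.
#' @return A `source_spec` list.
#' @export
source_spec <- function(beam_diameter_mm = 0.4, center_mm = NULL) {
  if (beam_diameter_mm < 0) stop("beam diameter must be >= 0")
  if (!is.null(center_mm)) stopifnot(length(center_mm) == 2)
  structure(list(beam_diameter_mm = beam_diameter_mm, center_mm = center_mm),
            class = "source_spec")
}

#' Disc detectors at given source-detector distances
#'
#' At each SDD, `n_per_sdd` circular detectors are placed at equally spaced
#' azimuths around the source (starting along +y); all discs at one SDD
#' form one detector group whose records are pooled, matching the
#' one-AC/DC-per-SDD reporting convention.
#'
#' @param sdd_mm Vector of center-to-center source-detector distances, mm.
#' @param radius_mm Disc radius, mm (> 0).
#' @param n_per_sdd Number of azimuthal copies per SDD.
#' @param start_deg Azimuth of the first disc, degrees from +y.
#' @return A `detector_set`.
#' @export
disc_detectors <- function(sdd_mm, radius_mm = 0.3, n_per_sdd = 3,
                           start_deg = 0) {
  if (radius_mm <= 0) stop("detector radius must be > 0")
  if (any(sdd_mm <= 0)) stop("sdd must be > 0")
  rows <- do.call(rbind, lapply(sdd_mm, function(s) {
    ang <- (start_deg +
              seq(0, 360, length.out = n_per_sdd + 1)[seq_len(n_per_sdd)]) *
      pi / 180
    data.frame(sdd_mm = s, dx = s * sin(ang), dy = s * cos(ang),
               radius_mm = radius_mm)
  }))
  structure(list(type = "disc", table = rows), class = "detector_set")
}

#' Annular ring detectors at given source-detector distances
#'
#' A full annulus centered on the source at each SDD; pools all azimuths,
#' which is the enlarged-detector configuration used for desk-scale runs.
#'
#' @param sdd_mm Vector of ring center radii (SDD), mm.
#' @param width_mm Radial width of each ring, mm.
#' @return A `detector_set`.
#' @export
ring_detectors <- function(sdd_mm, width_mm = 0.6) {
  if (any(sdd_mm <= 0) || any(width_mm <= 0)) stop("sdd and width must be > 0")
  width_mm <- rep(width_mm, length.out = length(sdd_mm))
  tab <- data.frame(sdd_mm = sdd_mm, r_in = pmax(0, sdd_mm - width_mm / 2),
                    r_out = sdd_mm + width_mm / 2)
  structure(list(type = "ring", table = tab), class = "detector_set")
}

.volume_extent <- function(volume) {
  if (length(volume$labels) == 1) volume$extent_mm
  else dim(volume$labels) * volume$voxel_mm
}

#' Run the Monte Carlo photon transport simulation
#'
#' Launches `n_photons` weight-1 photons with a Gaussian lateral profile at
#' normal incidence, transports them through the labeled volume
#' (Henyey-Greenstein scattering, continuous Beer-Lambert weight
#' attenuation, Fresnel reflection/refraction at the z = 0 surface, Russian
#' roulette), and records exit weight and per-medium partial pathlengths
#' for every photon leaving through a detector. Lateral and bottom faces
#' terminate photons as escaped.
#'
#' Identical `(seed, configuration)` gives a bitwise-identical result;
#' two runs differing only in geometry (e.g. systole/diastole vessel
#' diameters) share per-photon random streams when given the same seed
#' (coupled-seed variance reduction).
#'
#' @param volume A `tissue_volume`.
#' @param media A `medium_table` consistent with the volume labels.
#' @param source A `source_spec`.
#' @param detectors A `detector_set`, or `NULL` for none.
#' @param wavelength_nm Single wavelength at which media are resolved.
#' @param n_photons Number of photons to launch, >= 1.
#' @param seed Integer random seed.
#' @param rr_threshold,rr_survival Russian roulette weight threshold and
#'   survival probability.
#' @param acceptance_cos Minimum exit-direction cosine accepted by the
#'   detectors (0 = full hemisphere).
#' @param record_transmission Also record photons exiting the bottom face
#'   (detector id 0), for transmission oracles.
#' @param fluence Accumulate a 3-D map of absorbed weight per voxel
#'   (slower; off by default).
#' @param max_steps Safety cap on propagation steps per photon.
#' @return An `mc_result` list: `launched`, `ledger` (detected, absorbed,
#'   escaped_top, escaped_sides_bottom, roulette_killed), `records` matrix
#'   (detector, weight, total_l, exit_x, exit_y, one partial-pathlength
#'   column per medium), `detectors` table, `wavelength_nm`, `seed`,
#'   optionally `fluence`.
#' @export
simulate_photons <- function(volume, media, source = source_spec(),
                             detectors = NULL, wavelength_nm, n_photons,
                             seed = 1L, rr_threshold = 1e-4,
                             rr_survival = 0.1, acceptance_cos = 0,
                             record_transmission = FALSE, fluence = FALSE,
                             max_steps = 1e7) {
  stopifnot(inherits(volume, "tissue_volume"), inherits(media, "medium_table"),
            inherits(source, "source_spec"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  props <- resolve_media(media, wavelength_nm)
  M <- nrow(props)
  lab_max <- max(volume$labels)
  if (lab_max > M) stop("volume references media absent from the table")
  if (min(volume$labels) < 1) stop("interior voxels must be tissue (label >= 1)")
  ext <- .volume_extent(volume)
  ctr <- source$center_mm
  if (is.null(ctr)) ctr <- ext[1:2] / 2
  if (ctr[1] < 0 || ctr[1] > ext[1] || ctr[2] < 0 || ctr[2] > ext[2])
    stop("source center outside the surface")

  discs <- matrix(numeric(0), 0, 3)
  rings <- matrix(numeric(0), 0, 2)
  det_tab <- NULL
  if (!is.null(detectors)) {
    stopifnot(inherits(detectors, "detector_set"))
    if (detectors$type == "disc") {
      t <- detectors$table
      cx <- ctr[1] + t$dx
      cy <- ctr[2] + t$dy
      if (any(cx - t$radius_mm < 0) || any(cx + t$radius_mm > ext[1]) ||
          any(cy - t$radius_mm < 0) || any(cy + t$radius_mm > ext[2]))
        stop("detector outside the surface")
      discs <- cbind(cx, cy, t$radius_mm)
      det_tab <- data.frame(id = seq_len(nrow(t)), sdd_mm = t$sdd_mm)
    } else {
      t <- detectors$table
      if (any(ctr[1] - t$r_out < 0) || any(ctr[1] + t$r_out > ext[1]) ||
          any(ctr[2] - t$r_out < 0) || any(ctr[2] + t$r_out > ext[2]))
        stop("detector outside the surface")
      rings <- cbind(t$r_in, t$r_out)
      det_tab <- data.frame(id = seq_len(nrow(t)), sdd_mm = t$sdd_mm)
    }
  }

  homog <- length(volume$labels) == 1
  dims <- if (homog) c(1L, 1L, 1L) else dim(volume$labels)
  voxel <- if (homog) ext else rep(volume$voxel_mm, 3)

  res <- mc_run_cpp(as.integer(volume$labels), as.integer(dims),
                    as.numeric(voxel), unname(props[, , drop = FALSE]),
                    media$n_ambient, ctr[1], ctr[2],
                    source$beam_diameter_mm / 2, discs, rings,
                    acceptance_cos, as.double(n_photons), as.double(seed),
                    rr_threshold, rr_survival, record_transmission, fluence,
                    max_steps)
  med_names <- vapply(media$media, `[[`, "", "name")
  colnames(res$records) <- c("detector", "weight", "total_l", "exit_x",
                             "exit_y", paste0("l_", med_names))
  out <- list(launched = res$launched, ledger = res$ledger,
              records = res$records, detectors = det_tab,
              wavelength_nm = wavelength_nm, seed = as.integer(seed),
              media = props, n_ambient = media$n_ambient)
  if (fluence) out$fluence <- res$fluence
  structure(out, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %s photons @ %g nm (seed %d)\n",
              format(x$launched, big.mark = ","), x$wavelength_nm, x$seed))
  led <- x$ledger
  for (k in names(led))
    cat(sprintf("  %-22s %12.6g (%.3f%%)\n", k, led[k],
                100 * led[k] / x$launched))
  cat(sprintf("  detected records: %d\n", nrow(x$records)))
  invisible(x)
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Standard inverse-CDF sampling; for g = 0 the result is the isotropic
#' 2u - 1. The empirical mean of cos(theta) equals g.
#'
#' @param g Anisotropy in (-1, 1).
#' @param u Uniform(0,1) variate(s).
#' @return cos(theta) in [-1, 1], same length as `u`.
#' @export
sample_hg <- function(g, u) {
  if (any(abs(g) >= 1)) stop("g must lie in (-1, 1)")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (abs(g) < 1e-8) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Unpolarized Fresnel reflectance
#'
#' @param cos_i Incidence cosine in (0, 1].
#' @param n_in,n_out Refractive indices of the incidence and transmission
#'   media.
#' @return Reflectance in [0, 1] (1 beyond the critical angle).
#' @export
fresnel_reflectance <- function(cos_i, n_in, n_out) {
  if (any(cos_i <= 0 | cos_i > 1)) stop("cos_i must lie in (0, 1]")
  if (n_in == n_out) return(rep(0, length(cos_i)))  # matched boundary
  s2 <- (n_in / n_out)^2 * (1 - cos_i^2)
  out <- rep(1, length(s2))
  ok <- s2 < 1
  if (any(ok)) {
    ct <- sqrt(1 - s2[ok])
    ci <- rep(cos_i, length.out = length(s2))[ok]
    rs <- (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct)
    rp <- (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci)
    out[ok] <- 0.5 * (rs^2 + rp^2)
  }
  out
}

#' Stochastic Fresnel boundary interaction
#'
#' Decides reflect versus transmit by comparing a uniform variate with the
#' unpolarized Fresnel reflectance; beyond the critical angle the photon
#' always reflects. On transmission the refracted direction cosine is
#' returned.
#'
#' @param cos_i Incidence cosine in (0, 1].
#' @param n_in,n_out Refractive indices.
#' @param u Uniform(0,1) variate.
#' @return List with `action` ("reflect" or "transmit"), `reflectance`,
#'   and `cos_t` (refracted cosine, `NA` on reflection).
#' @export
fresnel_interaction <- function(cos_i, n_in, n_out, u) {
  if (cos_i <= 0 || cos_i > 1) stop("cos_i must lie in (0, 1]")
  R <- fresnel_reflectance(cos_i, n_in, n_out)
  if (u < R) return(list(action = "reflect", reflectance = R, cos_t = NA_real_))
  s2 <- (n_in / n_out)^2 * (1 - cos_i^2)
  list(action = "transmit", reflectance = R, cos_t = sqrt(1 - s2))
}

#' Russian roulette
#'
#' Below the threshold the photon survives with probability `survival_p`
#' at weight `w / survival_p`, else is terminated; expectation preserved.
#' At or above the threshold the weight is returned unchanged.
#'
#' @param w Photon weight(s).
#' @param threshold Roulette weight threshold.
#' @param survival_p Survival probability in (0, 1].
#' @param u Uniform(0,1) variate(s), recycled to the length of `w`.
#' @return Updated weight(s): unchanged, boosted, or 0.
#' @export
roulette <- function(w, threshold = 1e-4, survival_p = 0.1, u) {
  if (survival_p <= 0 || survival_p > 1) stop("survival_p must lie in (0, 1]")
  u <- rep(u, length.out = length(w))
  out <- w
  low <- w < threshold
  out[low] <- ifelse(u[low] < survival_p, w[low] / survival_p, 0)
  out
}
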