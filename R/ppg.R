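# PPG analysis layer: diffuse reflectance, -log(DRS) waveform, AC/DC
# pulse-quality ratio, and mean optical pathlength from detection records.

.restore_seed <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

.records_for_sdd <- function(result, sdd_mm) {
  if (is.null(result$detectors)) stop("result has no detectors")
  ids <- result$detectors$id[abs(result$detectors$sdd_mm - sdd_mm) < 1e-9]
  if (!length(ids)) stop(sprintf("no detector at SDD = %g mm", sdd_mm))
  result$records[result$records[, "detector"] %in% ids, , drop = FALSE]
}

#' Simulated diffuse reflectance signal
#'
#' DRS at a detector group = (sum of detected exit weights) / (launched
#' weight), i.e. absolute reflectance. The 99%-reflectance reference of the
#' measured pipeline maps to this scale through [drs_from_counts()].
#'
#' @param result An `mc_result`.
#' @param sdd_mm SDD group(s) to evaluate; `NULL` (default) for all groups
#'   present. Records of all detectors at one SDD are pooled.
#' @return Data frame with columns `wavelength_nm`, `sdd_mm`, `drs`
#'   (NA with `empty = TRUE` when nothing was detected), `n_records`.
#' @export
compute_drs <- function(result, sdd_mm = NULL) {
  stopifnot(inherits(result, "mc_result"))
  if (is.null(result$detectors)) stop("result has no detectors")
  if (is.null(sdd_mm)) sdd_mm <- unique(result$detectors$sdd_mm)
  rows <- lapply(sdd_mm, function(s) {
    rec <- .records_for_sdd(result, s)
    w <- sum(rec[, "weight"])
    if (nrow(rec) == 0L || w <= 0)
      data.frame(wavelength_nm = result$wavelength_nm, sdd_mm = s,
                 drs = NA_real_, n_records = nrow(rec), empty = TRUE)
    else
      data.frame(wavelength_nm = result$wavelength_nm, sdd_mm = s,
                 drs = w / result$launched, n_records = nrow(rec),
                 empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Measured-mode diffuse reflectance
#'
#' DRS = (sample counts / reference counts) x reference reflectance factor,
#' the normalization against a near-ideal diffuse reflectance standard.
#'
#' @param sample_counts Detected intensity from the sample.
#' @param reference_counts Detected intensity from the reference target.
#' @param reference_reflectance Reflectance factor of the standard
#'   (default 0.99).
#' @return DRS value(s).
#' @export
drs_from_counts <- function(sample_counts, reference_counts,
                            reference_reflectance = 0.99) {
  if (any(reference_counts <= 0)) stop("reference counts must be > 0")
  if (any(sample_counts < 0)) stop("sample counts must be >= 0")
  sample_counts / reference_counts * reference_reflectance
}

#' AC/DC pulse-quality ratio
#'
#' With p = -log(DRS) for the two cardiac phases,
#' AC/DC = 100 x (max(p_a, p_b) - min(p_a, p_b)) / min(p_a, p_b) percent.
#' Symmetric in its arguments; phase labels are metadata only. Natural
#' logarithm (the base cancels in the ratio).
#'
#' @param drs_a,drs_b DRS values in (0, 1), same wavelength and SDD;
#'   vectorized elementwise.
#' @return AC/DC in percent, >= 0.
#' @export
ac_dc <- function(drs_a, drs_b) {
  if (any(!is.finite(drs_a)) || any(!is.finite(drs_b)) ||
      any(drs_a <= 0) || any(drs_b <= 0) || any(drs_a > 1) || any(drs_b > 1))
    stop("DRS values must lie in (0, 1]")
  pa <- -log(drs_a)
  pb <- -log(drs_b)
  pmin_ <- pmin(pa, pb)
  if (any(pmin_ == 0))
    stop("DRS of 1 in the min phase: -log DRS denominator is zero")
  100 * (pmax(pa, pb) - pmin_) / pmin_
}

#' Mean optical pathlength from detection records
#'
#' Detected-weight-averaged pathlength MOP = sum_j(l_j w_j) / sum_j(w_j),
#' where l_j is each detected photon's pathlength summed over the chosen
#' media (all media = total MOP; a subset, e.g. blood only, yields a
#' partial MOP).
#'
#' @param records An `mc_result`, or its `records` matrix.
#' @param sdd_mm When `records` is an `mc_result`: which SDD group.
#' @param media `NULL` for all media (total pathlength), or a character
#'   vector of medium names / integer ids selecting partial pathlengths.
#' @return MOP in mm.
#' @export
mop <- function(records, sdd_mm = NULL, media = NULL) {
  if (inherits(records, "mc_result")) {
    records <- if (is.null(sdd_mm)) records$records
    else .records_for_sdd(records, sdd_mm)
  }
  if (nrow(records) == 0L) stop("no detection records")
  w <- records[, "weight"]
  if (all(w == 0)) stop("all detection weights are zero")
  if (is.null(media)) {
    l <- records[, "total_l"]
  } else {
    lcols <- grep("^l_", colnames(records), value = TRUE)
    sel <- if (is.numeric(media)) lcols[media] else paste0("l_", media)
    if (!all(sel %in% lcols)) stop("unknown media selection")
    l <- rowSums(records[, sel, drop = FALSE])
  }
  sum(l * w) / sum(w)
}

#' Pulse metrics from a systole/diastole run pair
#'
#' Computes the AC/DC ratio from the two phases' DRS, the mean optical
#' pathlength (from the diastole records by default), and a nonparametric
#' bootstrap standard error of AC/DC over detection records.
#'
#' @param systole,diastole `mc_result`s sharing geometry except vessel
#'   diameter, same wavelength and detectors.
#' @param sdd_mm SDD group to evaluate.
#' @param n_boot Bootstrap resamples (default 200).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param mop_phase Which phase's records feed the MOP: "diastole"
#'   (default), "systole", or "pooled".
#' @return One-row data frame: `wavelength_nm`, `sdd_mm`, `ac_dc_percent`,
#'   `ac_dc_se`, `mop_mm`, `n_detected` (min of the two phases),
#'   `n_detected_total` (both phases pooled, the per-condition photon
#'   count), `seed`.
#' @export
pulse_metrics <- function(systole, diastole, sdd_mm, n_boot = 200,
                          boot_seed = 1L,
                          mop_phase = c("diastole", "systole", "pooled")) {
  mop_phase <- match.arg(mop_phase)
  stopifnot(inherits(systole, "mc_result"), inherits(diastole, "mc_result"))
  if (systole$wavelength_nm != diastole$wavelength_nm)
    stop("phases must share a wavelength")
  rec_s <- .records_for_sdd(systole, sdd_mm)
  rec_d <- .records_for_sdd(diastole, sdd_mm)
  if (nrow(rec_s) == 0L || nrow(rec_d) == 0L)
    stop("no detected photons in at least one phase")
  drs_s <- sum(rec_s[, "weight"]) / systole$launched
  drs_d <- sum(rec_d[, "weight"]) / diastole$launched
  acdc <- ac_dc(drs_s, drs_d)
  mop_rec <- switch(mop_phase,
                    diastole = rec_d, systole = rec_s,
                    pooled = rbind(rec_s, rec_d))
  m <- mop(mop_rec)
  restore <- .restore_seed()
  on.exit(restore())
  set.seed(boot_seed)
  bs <- vapply(seq_len(n_boot), function(i) {
    is_ <- sample.int(nrow(rec_s), replace = TRUE)
    id_ <- sample.int(nrow(rec_d), replace = TRUE)
    a <- sum(rec_s[is_, "weight"]) / systole$launched
    b <- sum(rec_d[id_, "weight"]) / diastole$launched
    ac_dc(a, b)
  }, numeric(1))
  data.frame(wavelength_nm = systole$wavelength_nm, sdd_mm = sdd_mm,
             ac_dc_percent = acdc, ac_dc_se = stats::sd(bs), mop_mm = m,
             n_detected = min(nrow(rec_s), nrow(rec_d)),
             n_detected_total = nrow(rec_s) + nrow(rec_d),
             seed = systole$seed)
}

#' PPG waveform from an ordered DRS series
#'
#' The negative logarithm of DRS per phase point of one cardiac pulse;
#' the AC/DC of the waveform is the AC/DC of its extrema.
#'
#' @param drs Ordered DRS values (length >= 2, all in (0, 1]).
#' @param wavelength_nm Optional wavelength carried as metadata.
#' @return A `ppg_waveform` data frame with columns `phase`,
#'   `neg_log_drs`.
#' @export
waveform_from_series <- function(drs, wavelength_nm = NA_real_) {
  if (length(drs) < 2) stop("series must have length >= 2")
  if (any(!is.finite(drs)) || any(drs <= 0))
    stop("all DRS values must be finite and > 0")
  out <- data.frame(phase = seq_along(drs), neg_log_drs = -log(drs))
  attr(out, "wavelength_nm") <- wavelength_nm
  class(out) <- c("ppg_waveform", "data.frame")
  out
}

#' AC/DC of a PPG waveform
#'
#' @param waveform A `ppg_waveform`.
#' @return AC/DC in percent: 100 x (max - min) / min of -log DRS.
#' @export
waveform_acdc <- function(waveform) {
  p <- waveform$neg_log_drs
  if (min(p) == 0) stop("-log DRS of 0 at the baseline: AC/DC undefined")
  100 * (max(p) - min(p)) / min(p)
}
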