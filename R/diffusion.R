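# Steady-state diffusion-theory reflectance: the closed-form oracle for
# the Monte Carlo engine and the fast engine of the synthetic phantom
# generator.

# Internal-reflection parameter A from the relative refractive index
# (Groenhuis/Egan-Hilgeman fit for the effective reflection coefficient).
.diffusion_A <- function(n_rel) {
  if (abs(n_rel - 1) < 1e-12) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

#' Spatially resolved diffuse reflectance (diffusion theory)
#'
#' Steady-state dipole solution for a pencil beam on a semi-infinite
#' homogeneous medium (isotropic point source at one transport mean free
#' path, extrapolated boundary): the radially resolved reflectance
#' R(rho) in mm^-2.
#'
#' @param rho_mm Radial distance(s) from the source, mm.
#' @param mua Absorption coefficient, mm^-1.
#' @param musp Reduced scattering coefficient, mm^-1, > 0.
#' @param n_rel Tissue/ambient relative refractive index (1 =
#'   index-matched).
#' @return R(rho) in mm^-2.
#' @export
diffusion_reflectance <- function(rho_mm, mua, musp, n_rel = 1) {
  if (musp <= 0) stop("musp must be > 0")
  if (mua < 0) stop("mua must be >= 0")
  # z0 and D from mu_s' alone (absorption-independent diffusion
  # coefficient); keeps R strictly decreasing in mu_a at every rho
  z0 <- 1 / musp
  Dd <- 1 / (3 * musp)
  mueff <- sqrt(3 * mua * musp)
  zb <- 2 * .diffusion_A(n_rel) * Dd
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Diffusion-theory weight collected by an annulus
#'
#' Integral of R(rho) over a ring r_in <= rho < r_out: the fraction of
#' launched weight a ring detector collects, for direct comparison with
#' the Monte Carlo ledger.
#'
#' @param r_in,r_out Ring radii, mm.
#' @param mua,musp,n_rel As in [diffusion_reflectance()].
#' @return Dimensionless collected weight fraction.
#' @export
diffusion_ring_weight <- function(r_in, r_out, mua, musp, n_rel = 1) {
  stopifnot(r_out > r_in, r_in >= 0)
  stats::integrate(function(r)
    diffusion_reflectance(r, mua, musp, n_rel) * 2 * pi * r,
    r_in, r_out, rel.tol = 1e-9)$value
}

#' Approximate two-layer diffuse reflectance
#'
#' Semi-infinite diffusion reflectance of the bottom medium multiplied by
#' a Beer-Lambert attenuation for the double transit of a thin superficial
#' absorbing layer: exp(-path_factor * D * mua_top). `path_factor`
#' (default 4) is the mean geometric path through the layer per mm of
#' thickness: two crossings at an effective mean cosine of 0.5. This is a
#' deliberately simple approximation for thin, weakly scattering-contrast
#' top layers; its provenance is flagged on the result.
#'
#' @param rho_mm Radial distance(s), mm.
#' @param mua_top Top-layer absorption, mm^-1.
#' @param d_top_mm Top-layer thickness, mm.
#' @param mua_bottom Bottom-layer absorption, mm^-1.
#' @param musp Reduced scattering coefficient, mm^-1.
#' @param n_rel Relative refractive index.
#' @param path_factor Effective pathlength through the top layer per mm of
#'   thickness.
#' @return R(rho) in mm^-2, with attribute `approximation = "two-layer"`
#'   when `d_top_mm > 0`.
#' @export
two_layer_reflectance <- function(rho_mm, mua_top, d_top_mm, mua_bottom,
                                  musp, n_rel = 1, path_factor = 4) {
  if (d_top_mm < 0) stop("top thickness must be >= 0")
  out <- diffusion_reflectance(rho_mm, mua_bottom, musp, n_rel) *
    exp(-path_factor * d_top_mm * mua_top)
  if (d_top_mm > 0) attr(out, "approximation") <- "two-layer"
  out
}
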