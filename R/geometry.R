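# Labeled voxel volumes: layered skin with cylindrical dermal vessels, and
# the two-layer ink/hemoglobin phantom.
#
# Conventions: voxel indices are 0-based with half-open physical extents
# [k*h, (k+1)*h); the z = 0 face is the air-tissue interface and +Z points
# into the tissue. Vessels are straight cylinders running along one lateral
# axis (default Y, the source-detector axis); their count is
# round(density x full perpendicular cross-section area) while centers are
# confined to a configurable depth band.

#' Specify a skin geometry
#'
#' @param epidermal_um Epidermal thickness D in micrometers (> 0).
#' @param vessel_diameter_um Vessel diameter in micrometers (the cardiac
#'   phases of the source study use 75 um for systole and 117 um for
#'   diastole).
#' @param vessel_density_mm2 Cross-sectional vessel density, vessels/mm^2,
#'   over the full cross-section perpendicular to the vessel axis.
#' @param vessel_axis Lateral axis the cylinders run along, `"y"` (default,
#'   the source-detector axis) or `"x"`.
#' @param depth_band_um Length-2 vector: depth band (below the surface, um)
#'   within which vessel centers are placed. `NULL` (default) means from
#'   `epidermal_um + 50` to the bottom of the volume minus one diameter,
#'   resolved at build time.
#' @param max_diameter_um Largest diameter the placement must accommodate
#'   (default `max(117, vessel_diameter_um)`). Centers are sampled
#'   non-overlapping at this diameter so that [dilate_vessels()] up to it
#'   preserves every center.
#' @param arrangement `"random"` (seeded random sequential adsorption) or
#'   `"grid"` (regular lattice, fully deterministic).
#' @param placement_seed Integer seed for vessel placement.
#' @return A `skin_spec` list.
#' @export
skin_spec <- function(epidermal_um = 100, vessel_diameter_um = 117,
                      vessel_density_mm2 = 33.75, vessel_axis = c("y", "x"),
                      depth_band_um = NULL,
                      max_diameter_um = max(117, vessel_diameter_um),
                      arrangement = c("random", "grid"),
                      placement_seed = 1L) {
  vessel_axis <- match.arg(vessel_axis)
  arrangement <- match.arg(arrangement)
  if (epidermal_um <= 0) stop("epidermal thickness must be > 0")
  if (vessel_diameter_um <= 0) stop("vessel diameter must be > 0")
  if (vessel_density_mm2 < 0) stop("vessel density must be >= 0")
  if (vessel_diameter_um > max_diameter_um)
    stop("vessel_diameter_um exceeds max_diameter_um")
  if (!is.null(depth_band_um)) {
    stopifnot(length(depth_band_um) == 2, depth_band_um[1] < depth_band_um[2])
    if (depth_band_um[1] < epidermal_um)
      stop("vessel depth band must lie below the epidermis")
  }
  structure(list(epidermal_um = epidermal_um,
                 vessel_diameter_um = vessel_diameter_um,
                 vessel_density_mm2 = vessel_density_mm2,
                 vessel_axis = vessel_axis,
                 depth_band_um = depth_band_um,
                 max_diameter_um = max_diameter_um,
                 arrangement = arrangement,
                 placement_seed = as.integer(placement_seed)),
            class = "skin_spec")
}

#' Dilate (or constrict) the vessels of a skin geometry
#'
#' Returns the same specification with a new vessel diameter; vessel count
#' and center positions are preserved (centers depend only on the placement
#' seed and `max_diameter_um`), so a systole/diastole pair built from the
#' two specs differs only in vessel caliber.
#'
#' @param spec A `skin_spec`.
#' @param new_diameter_um New diameter in micrometers, > 0 and at most
#'   `spec$max_diameter_um`.
#' @return A `skin_spec`.
#' @export
dilate_vessels <- function(spec, new_diameter_um) {
  stopifnot(inherits(spec, "skin_spec"))
  if (new_diameter_um <= 0) stop("diameter must be > 0")
  if (new_diameter_um > spec$max_diameter_um)
    stop("dilated diameter exceeds the placement margin (max_diameter_um); ",
         "rebuild the spec with a larger max_diameter_um")
  spec$vessel_diameter_um <- new_diameter_um
  spec
}

# Allowed band for vessel CENTER depths, mm. The configured band (default:
# epidermis + 50 um down to the bottom minus one max diameter) is clipped so
# that a vessel of the placement diameter fits wholly in the dermis and
# wholly inside the volume.
.resolve_band_mm <- function(spec, extent_z_mm) {
  d_mm <- spec$max_diameter_um / 1000
  r <- d_mm / 2
  band <- if (is.null(spec$depth_band_um))
    c(spec$epidermal_um / 1000 + 0.05, extent_z_mm - d_mm)
  else spec$depth_band_um / 1000
  lo <- max(band[1], spec$epidermal_um / 1000 + r)
  hi <- min(band[2] + r, extent_z_mm - r)
  if (hi <= lo) stop("vessel depth band too narrow for the vessel diameter")
  c(lo, hi)
}

#' Vessel center positions for a skin geometry
#'
#' Centers live in the plane perpendicular to the vessel axis: coordinates
#' are (lateral_mm, depth_mm). Deterministic for a fixed placement seed.
#'
#' @param spec A `skin_spec`.
#' @param extent_mm Length-3 volume extent (X, Y, Z) in mm.
#' @return Matrix with columns `lat_mm`, `z_mm`; zero rows if density 0.
#' @export
vessel_centers <- function(spec, extent_mm) {
  stopifnot(inherits(spec, "skin_spec"), length(extent_mm) == 3)
  lat_extent <- if (spec$vessel_axis == "y") extent_mm[1] else extent_mm[2]
  area <- lat_extent * extent_mm[3]
  n <- round(spec$vessel_density_mm2 * area)
  empty <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("lat_mm", "z_mm")))
  if (n == 0) return(empty)
  d <- spec$max_diameter_um / 1000
  r <- d / 2
  zlim <- .resolve_band_mm(spec, extent_mm[3])
  xlim <- c(r, lat_extent - r)
  if (xlim[2] <= xlim[1]) stop("volume too narrow for the vessel diameter")
  if (spec$arrangement == "grid") {
    # near-square lattice filling the band
    nxv <- max(1, round(sqrt(n * diff(xlim) / diff(zlim))))
    nzv <- ceiling(n / nxv)
    gx <- seq(xlim[1], xlim[2], length.out = nxv + 2)[-c(1, nxv + 2)]
    gz <- seq(zlim[1], zlim[2], length.out = nzv + 2)[-c(1, nzv + 2)]
    ctr <- as.matrix(expand.grid(lat_mm = gx, z_mm = gz))[seq_len(n), ,
                                                          drop = FALSE]
    if (nxv > 1 && min(diff(gx)) < d || nzv > 1 && min(diff(gz)) < d)
      stop("vessel placement failed: grid spacing below one diameter")
  } else {
    ctr <- rsa_centers_cpp(n, xlim[1], xlim[2], zlim[1], zlim[2], d,
                           spec$placement_seed, 5e7)
    colnames(ctr) <- c("lat_mm", "z_mm")
  }
  ctr
}

.new_volume <- function(labels, voxel_mm, media_names) {
  structure(list(labels = labels, voxel_mm = voxel_mm,
                 origin = c(0, 0, 0), media_names = media_names),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- dim(x$labels)
  if (is.na(x$voxel_mm)) {
    cat(sprintf("tissue_volume: homogeneous box %g x %g x %g mm ('%s')\n",
                x$extent_mm[1], x$extent_mm[2], x$extent_mm[3],
                x$media_names[1]))
    return(invisible(x))
  }
  cat(sprintf("tissue_volume: %d x %d x %d voxels @ %g um (%g x %g x %g mm)\n",
              d[1], d[2], d[3], x$voxel_mm * 1000,
              d[1] * x$voxel_mm, d[2] * x$voxel_mm, d[3] * x$voxel_mm))
  tab <- tabulate(x$labels, nbins = length(x$media_names))
  for (i in seq_along(x$media_names))
    cat(sprintf("  %d %-10s %10d voxels (%.2f%%)\n", i, x$media_names[i],
                tab[i], 100 * tab[i] / length(x$labels)))
  invisible(x)
}

#' Build a labeled skin volume
#'
#' Epidermis slab over dermis with parallel cylindrical vessels. Labels:
#' 1 = epidermis, 2 = dermis, 3 = blood (matching [skin_media()]).
#' The cross-section perpendicular to the vessel axis is built once and
#' extruded, so the volume is exactly translation-invariant along the
#' vessel axis.
#'
#' @param spec A `skin_spec`.
#' @param extent_mm Volume extent (X, Y, Z) in mm; the source study's
#'   full-scale volume is `c(2, 4.7, 1.1)`.
#' @param voxel_mm Cubic voxel size in mm; must not exceed one fifth of the
#'   vessel diameter.
#' @return A `tissue_volume`.
#' @export
build_skin_volume <- function(spec, extent_mm = c(2, 4.7, 1.1),
                              voxel_mm = 0.010) {
  stopifnot(inherits(spec, "skin_spec"), length(extent_mm) == 3)
  if (any(extent_mm <= 0) || voxel_mm <= 0) stop("extent and voxel must be > 0")
  if (spec$vessel_density_mm2 > 0 &&
      voxel_mm > spec$vessel_diameter_um / 1000 / 5)
    stop("voxel size must be <= vessel_diameter / 5")
  D <- spec$epidermal_um / 1000
  if (D >= extent_mm[3]) stop("epidermis thicker than the volume")
  nx <- round(extent_mm[1] / voxel_mm)
  ny <- round(extent_mm[2] / voxel_mm)
  nz <- round(extent_mm[3] / voxel_mm)
  ctr <- vessel_centers(spec, extent_mm)
  r <- spec$vessel_diameter_um / 1000 / 2
  if (nrow(ctr) > 0) {
    if (any(ctr[, 2] - r < D))
      stop("vessels would protrude into the epidermis")
    if (any(ctr[, 2] + r > extent_mm[3]))
      stop("vessels would protrude out of the volume")
  }
  # 2-D cross-section: lateral axis x depth
  nlat <- if (spec$vessel_axis == "y") nx else ny
  lat <- (seq_len(nlat) - 0.5) * voxel_mm
  dep <- (seq_len(nz) - 0.5) * voxel_mm
  sect <- matrix(2L, nlat, nz)
  sect[, dep < D] <- 1L
  if (nrow(ctr) > 0) {
    r2 <- r * r
    for (i in seq_len(nrow(ctr))) {
      dl <- lat - ctr[i, 1]
      dz <- dep - ctr[i, 2]
      hit <- outer(dl * dl, dz * dz, "+") <= r2
      sect[hit] <- 3L
    }
  }
  labels <- if (spec$vessel_axis == "y") {
    # extrude along y: labels[x, y, z] = sect[x, z]
    aperm(array(sect, dim = c(nlat, nz, ny)), c(1, 3, 2))
  } else {
    # extrude along x: labels[x, y, z] = sect[y, z]
    aperm(array(sect, dim = c(nlat, nz, nx)), c(3, 1, 2))
  }
  v <- .new_volume(labels, voxel_mm, c("epidermis", "dermis", "blood"))
  v$spec <- spec
  v
}

#' Specify a two-layer phantom geometry
#'
#' @param top_mm Top (ink) layer thickness D in mm, >= 0; the source study
#'   uses 0 and 0.20 mm.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(top_mm = 0) {
  if (top_mm < 0) stop("top layer thickness must be >= 0")
  structure(list(top_mm = top_mm), class = "phantom_spec")
}

#' Build a labeled two-layer phantom volume
#'
#' Labels: 1 = top (ink) layer for z in [0, D), 2 = bottom (hemoglobin)
#' layer below (matching [phantom_media()]). D = 0 yields a homogeneous
#' bottom-medium volume.
#'
#' @param spec A `phantom_spec`.
#' @param extent_mm Volume extent (X, Y, Z) in mm.
#' @param voxel_mm Cubic voxel size in mm.
#' @return A `tissue_volume`.
#' @export
build_phantom_volume <- function(spec, extent_mm = c(10, 10, 10),
                                 voxel_mm = 0.02) {
  stopifnot(inherits(spec, "phantom_spec"), length(extent_mm) == 3)
  if (spec$top_mm >= extent_mm[3])
    stop("top layer at least as thick as the volume")
  nx <- round(extent_mm[1] / voxel_mm)
  ny <- round(extent_mm[2] / voxel_mm)
  nz <- round(extent_mm[3] / voxel_mm)
  dep <- (seq_len(nz) - 0.5) * voxel_mm
  zlab <- ifelse(dep < spec$top_mm, 1L, 2L)
  labels <- array(rep(zlab, each = nx * ny), dim = c(nx, ny, nz))
  v <- .new_volume(labels, voxel_mm, c("top_ink", "bottom_hb"))
  v$spec <- spec
  v
}

#' Homogeneous semi-infinite-style volume
#'
#' A single-voxel volume whose one "voxel" spans the whole box: the
#' transport engine then steps analytically between the box faces, which is
#' the fast path for homogeneous-medium oracles (ballistic transmission,
#' diffusion-theory comparison).
#'
#' @param extent_mm Volume extent (X, Y, Z) in mm.
#' @param medium_id Label of the filling medium (default 1).
#' @param name Medium name for display.
#' @return A `tissue_volume` with a length-1 label array.
#' @export
homogeneous_volume <- function(extent_mm = c(60, 60, 30), medium_id = 1L,
                               name = "medium") {
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0))
  v <- structure(list(labels = array(as.integer(medium_id), c(1, 1, 1)),
                      voxel_mm = NA_real_, extent_mm = extent_mm,
                      origin = c(0, 0, 0), media_names = name),
                 class = "tissue_volume")
  v
}

#' Medium voxel counts of a volume
#'
#' @param volume A `tissue_volume`.
#' @return Named integer vector of voxel counts per medium id.
#' @export
medium_counts <- function(volume) {
  tab <- tabulate(volume$labels, nbins = length(volume$media_names))
  names(tab) <- volume$media_names
  tab
}
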