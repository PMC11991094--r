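# Shared in-code fixtures: everything is generated at test time.

# Homogeneous box filled with one medium; optics given directly.
homog_setup <- function(mua, musp, g, n = 1.0, extent = c(40, 40, 20)) {
  list(volume = homogeneous_volume(extent),
       media = medium_table(medium("m", mua, musp, g, n), n_ambient = 1.0))
}

# Purely absorbing two-layer slab for ballistic transmission oracles.
absorbing_slab <- function(mua, depth_mm = 5, voxel_mm = 0.1) {
  list(volume = build_phantom_volume(phantom_spec(0),
                                     extent_mm = c(4, 4, depth_mm),
                                     voxel_mm = voxel_mm),
       media = medium_table(medium("top", mua, 0, 0, 1.0),
                            medium("bottom", mua, 0, 0, 1.0),
                            n_ambient = 1.0))
}

# Small skin volume for fast transport tests (reduced extent, 15 um voxels
# would violate the diameter/5 rule for 75 um vessels, so 10 um is kept).
tiny_skin <- function(epidermal_um = 100, diameter_um = 117, seed = 1,
                      extent = c(2, 2, 1.1), voxel = 0.01, ...) {
  spec <- skin_spec(epidermal_um = epidermal_um,
                    vessel_diameter_um = diameter_um,
                    placement_seed = seed, ...)
  list(spec = spec, volume = build_skin_volume(spec, extent, voxel))
}

# Record matrix in the engine's layout, for ppg-module unit tests.
fake_records <- function(w, l, detector = 1) {
  nm <- c("detector", "weight", "total_l", "exit_x", "exit_y", "l_a", "l_b")
  if (!length(w))
    return(matrix(numeric(0), 0, 7, dimnames = list(NULL, nm)))
  m <- cbind(detector, w, l, 0, 0, l / 2, l / 2)
  colnames(m) <- nm
  m
}
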