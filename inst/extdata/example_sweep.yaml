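# Minimal skin-sweep configuration for read_run_config(); photon budget
# kept small for a quick demonstration run.
experiment: skin_sweep
epidermal_um: [100]
sdd_mm: [1, 2]
wavelength_nm: [523, 945]
n_photons: 200000
seed: 7
extent_mm: [6.6, 6.6, 1.1]
voxel_mm: 0.01
ring_width_mm: 1.2
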