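# ppgmc — Monte Carlo photon transport for reflection-mode PPG

`ppgmc` is an R package for studying why green light outperforms
near-infrared light in reflection-mode photoplethysmography (PPG), the
optical heart-rate signal used by wrist wearables. It provides:

* a **voxel Monte Carlo photon-transport engine** (Rcpp core) for layered
  skin — epidermis over a dermis carrying pulsatile cylindrical blood
  vessels — and for two-layer hemoglobin/ink gel optical phantoms:
  Henyey–Greenstein scattering, continuous Beer–Lambert weight
  attenuation, Fresnel surface reflection/refraction, Russian roulette,
  per-medium partial pathlength recording, and a closed weight ledger;
* the **PPG analysis layer**: diffuse reflectance (DRS), the −log(DRS)
  pulse waveform, the AC/DC pulse-quality ratio, and the mean optical
  pathlength (MOP);
* a **diffusion-theory closed form** (extrapolated-boundary dipole) used
  as an independent oracle for the engine and as the fast forward engine
  of the synthetic phantom generator;
* a **synthetic-data generator** for the seven-phantom cardiac-pulse
  measurement (noisy DRS spectra, replicate sets, a 99%-reflectance
  reference, and a file-backed measurement format with manifest);
* **configuration-driven pipelines**: `run_skin_sweep()` (epidermal
  thickness × SDD × wavelength, coupled systole/diastole pairs) and
  `run_phantom_pipeline()` (spectra files → DRS → waveforms → AC/DC
  spectra), with seeds and provenance embedded in every output.

## The model in brief

A cardiac pulse is represented by two vessel calibers: 75 µm (systole)
and 117 µm (diastole) at a cross-sectional density of 33.75 vessels/mm².
For each phase a Monte Carlo run yields the diffuse reflectance
DRS = (detected weight)/(launched weight) at each source–detector
distance (SDD). With p = −log DRS per phase,

    AC/DC = 100% × (max p − min p) / min p

and the mean optical pathlength over detected photons j with partial
pathlengths l_ij in medium i and exit weights w_j is

    MOP = Σ_i Σ_j l_ij w_j / Σ_j w_j .

Green light reads shallow, blood-rich tissue with strong hemoglobin
contrast; NIR light travels farther (larger MOP) but sees weak blood
absorption. The package's experiments quantify that trade-off across
SDD (1–2 mm at desk scale), epidermal thickness (50–150 µm), and
wavelength (523 vs 945 nm).

## Worked example

A single-thickness sweep (epidermis 100 µm, SDD 1 and 2 mm, both
wavelengths, 10⁶ photons per phase, one seed; ~3 min):

```r
library(ppgmc)
cfg <- sweep_config(epidermal_um = 100, sdd_mm = c(1, 2),
                    wavelength_nm = c(523, 945),
                    n_photons = 1e6, seed = 7, ring_width_mm = 1.2)
tab <- run_skin_sweep(cfg)
print(tab, digits = 4)
#>   wavelength_nm sdd_mm D_um ac_dc_percent ac_dc_se mop_mm n_detected
#> 1           523      1  100        9.1318  0.09561  1.087     297021
#> 2           523      2  100       11.1120  0.18150  3.430      39053
#> 3           945      1  100        3.6519  0.03940  2.214     174708
#> 4           945      2  100        0.8917  0.05710  4.153      56519
#>   n_detected_total seed
#> 1           629184    7
#> 2            82176    7
#> 3           370118    7
#> 4           115839    7
```

Reading the table: at both SDDs green (523 nm) delivers a several-fold
larger AC/DC than NIR (945 nm) even though its MOP is roughly 20–30%
*shorter* (1.1 vs 2.2 mm at SDD 1; 3.4 vs 4.2 mm at SDD 2) — the
green-versus-NIR inversion the package exists to study. Green AC/DC
*rises* with SDD (9.1% → 11.1%), `ac_dc_se` is a bootstrap standard
error over detection records, `n_detected` counts detection records in
the smaller of the two cardiac-phase runs, and `n_detected_total` pools
both phases (the per-condition photon count). Rerunning with the same
seed reproduces the table bitwise.

The phantom side, entirely synthetic and instrument-free:

```r
ser <- phantom_series(d_mm = 0)          # Hb arc 2.0 -> 3.1 -> 2.0 mg/mL
g   <- forward_drs(ser)                  # 7 x 226 DRS grid, SDD 0.5 mm
waveform_acdc(waveform_from_series(g[, "540"]))   # 3.46 % at 540 nm
waveform_acdc(waveform_from_series(g[, "900"]))   # 0.25 % at 900 nm
```

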