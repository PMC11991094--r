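---
title: "Modeling reflection-mode PPG with voxel Monte Carlo photon transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reflection-mode PPG with voxel Monte Carlo photon transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A reflection-mode photoplethysmography (PPG) sensor shines light onto the
skin and watches the diffuse reflectance change over the cardiac cycle:
during systole the dermal vessels are engorged, absorption rises, and the
detected signal dips. Wearables use two bands, green (around 523 nm) and
near-infrared (around 945 nm), and in vivo experience says green wins for
heart-rate extraction even though NIR photons travel farther — the
opposite of the intuition imported from NIR spectroscopy of the brain.
`ppgmc` provides the computational apparatus to study this quantitatively:
a voxel Monte Carlo photon-transport engine for layered skin with
pulsatile cylindrical vessels and for two-layer hemoglobin/ink gel
phantoms, plus the analysis layer that turns simulated or measured
reflectance into PPG quality metrics.

Two quantities summarize a pulse at one wavelength and one source-detector
distance (SDD). With $p = -\log \mathrm{DRS}$ for each cardiac phase,

$$\mathrm{AC/DC} = 100\% \times \frac{\max p - \min p}{\min p},$$

and, from the per-photon partial pathlengths $l_{i,j}$ (medium $i$,
detected photon $j$) and exit weights $w_j$,

$$\mathrm{MOP} = \frac{\sum_i \sum_j l_{i,j}\, w_j}{\sum_j w_j}.$$

The AC/DC ratio is symmetric in the two phases and independent of the
logarithm base; it is *not* invariant to a shared multiplicative
calibration error in the two DRS values (the denominator shifts), which
the test suite asserts as a documented sensitivity rather than an
invariance.

## The transport model

The engine (`simulate_photons()`, C++ core) follows the MCML/MCX lineage:

* **Free paths.** A dimensionless step $s \sim \mathrm{Exp}(1)$ is consumed
  against the per-voxel scattering coefficient $\mu_s$; absorption is
  handled as continuous weight attenuation $e^{-\mu_a l}$ along every
  traversed segment, tracked in log space. Splitting the free path across
  voxel boundaries makes heterogeneous media exact, and a purely absorbing
  slab transmits exactly $e^{-\mu_a L}$ per photon — the ballistic oracle
  in the tests holds to machine precision rather than Monte Carlo
  precision.
* **Scattering.** Henyey–Greenstein deflection with the local medium's
  $g$, standard inverse-CDF sampling.
* **Boundaries.** Unpolarized Fresnel reflection/refraction at the $z = 0$
  air–tissue surface only; internal layer boundaries are index-matched
  (the refractive indices of skin layers and gel layers are nearly equal;
  the surface mismatch dominates). Lateral and bottom faces terminate
  photons and book their weight as escaped, matching a finite simulated
  volume; semi-infinite behavior is achieved by sizing the box.
* **Termination.** Russian roulette below weight $10^{-4}$ with survival
  probability $0.1$, expectation-preserving.
* **Accounting.** The ledger (detected, absorbed, escaped top, escaped
  sides/bottom, net roulette) closes against the launched weight to
  $10^{-9}$ relative on every run, and each detection record carries the
  exit weight, the total pathlength, and one partial pathlength per
  medium; their sum is independently checked against the total.
* **Determinism and coupling.** One private xoroshiro128+ stream per
  photon, seeded from (run seed, photon index). Identical seed and
  configuration reproduce a run bitwise; a systole/diastole pair sharing a
  seed shares launch streams, so the small AC/DC contrast is estimated on
  strongly correlated noise (coupled-seed variance reduction). The AC/DC
  bootstrap SE resamples each phase's records independently and therefore
  *over*-estimates the SE of the coupled contrast — a conservative choice.

The Gaussian source uses the convention beam diameter $= 2\sigma$
(0.4 mm beam means $\sigma = 0.2$ mm); the source convention of the
original instrumentation is not published, and the studied trends are
insensitive to it. Detector acceptance defaults to the full hemisphere
since no fiber NA is published; it is configurable.

## Geometry

`build_skin_volume()` builds an epidermal slab of thickness $D$ over a
dermis carrying straight cylindrical vessels that run along the long
lateral axis (also the source–detector axis), with the printed study
parameters as defaults: cross-sectional density 33.75 vessels/mm²
(count = density × full perpendicular cross-section area), diameters
75 µm (systole) and 117 µm (diastole). Centers are placed by seeded
random sequential adsorption inside a configurable depth band (default:
from $D + 50$ µm down to the bottom minus one diameter), non-overlapping
at the *maximum* pulse diameter so that `dilate_vessels()` preserves
every center and count — the systole/diastole pair differs only in
caliber, never in topology. At the printed density the diastolic packing
reaches roughly half of the random-adsorption jamming limit, which is why
placement is done in compiled code with a cell grid; a regular-grid
arrangement is available for fully deterministic geometries. A
`homogeneous_volume()` spans its whole box with a single "voxel" so the
engine steps analytically between the faces — the fast path for the
homogeneous oracles.

The two-layer phantom volume is an ink+lipid+gel slab of thickness 0 or
0.20 mm over a semi-infinite hemoglobin+lipid+gel bottom layer.

## Optical properties

The study's own per-medium spectra are not published (its skin properties
live in an external reference; its phantom spectra appear only as
figures), and the study itself argues that only the spectral *shapes*
drive the wavelength trends. The package therefore ships
parameterized, literature-shaped defaults, clearly labeled as defaults
and overridable everywhere:

* **Hemoglobin** (`hb_mua()`): oxyhemoglobin-like anchor table with the
  alpha/beta bands at 577/540 nm, the deep trough beyond 600 nm, and the
  mild NIR rise; linear Beer–Lambert scaling with concentration
  (whole blood is about 150 mg/mL). The oxygenation state of the phantom
  hemoglobin is not published; the oxy shape is chosen because the
  540/580 nm features discussed in the source are the HbO₂ bands.
* **India ink / melanin** (`ink_mua()`, `epidermis_mua()`):
  $\propto (\lambda/500)^{-3}$ power law (ink mimics the epidermal
  melanin shape, which is the reason it is used in such phantoms).
* **Intralipid** (`intralipid_musp()`): $\mu_s' \propto
  (\lambda/500)^{-2.4}$, 2.5 mm⁻¹ at 500 nm for 1% w/v.
* **Skin scattering** (`skin_musp()`): $4.6 (\lambda/500)^{-1.42}$ mm⁻¹.
* **$g$ and $n$** are not chromophore properties and are never published
  for these media: defaults $g = 0.9$, $n = 1.40$ for skin, $g = 0.75$,
  $n = 1.33$ for gel phantoms, ambient $n = 1$.

One default deserves emphasis. Taking literature whole-blood absorption
(about 15–17 mm⁻¹ at green wavelengths) together with the printed vessel
density and diastolic diameter yields a ~36% dermal blood volume
fraction, under which green photons could not plausibly reach multi-mm
SDDs at all — yet the source study reports green AC/DC out to
SDD = 4 mm. Its actual blood optical properties are unpublished. The
package's default vessel-blood compartment therefore keeps the
whole-blood spectral *shape* exactly and scales its magnitude to one
tenth (equivalent to ~15 mg/mL hemoglobin, `skin_media(blood_hb_mg_ml =
15)`), a choice made once at design time so that every studied SDD stays
within desk-scale photon budgets. All wavelength orderings studied here
are preserved under this scaling; users reproducing a specific skin type
should supply their own media table.

## The desk-scale study

The full-scale study is not a desk computation: its headline numbers used
up to $28 \times 10^9$ photons per condition on GPUs with 2 µm voxels.
The package's own experiments are scaled-down versions chosen to preserve
the *trends*:

* volume $6.6 \times 6.6 \times 1.1$ mm³ at 10 µm voxels (2 µm remains
  available for convergence checks on smaller boxes);
* annular ring detectors centered on the source (pooling all azimuths is
  the desk-scale analogue of the three pooled 0.3 mm discs per SDD),
  width 1.4 mm, SDD 1 and 2 mm;
* $1$–$2.6 \times 10^6$ photons per run, chosen — in the same spirit as
  the source's launched-to-detected budgeting — so that every cell used
  in an assertion collects at least $10^5$ detection records;
* coupled seeds between the systole and diastole runs.

Under these conditions the test suite asserts the study's four
simulation trends: MOP strictly increases with SDD at both wavelengths;
green AC/DC increases with SDD (asserted at $D = 100$ µm, the epidermal
thickness at which the source presents AC/DC versus SDD — at
$D = 50$ µm the desk-scale green signal is already blood-saturated at
SDD 1 mm and the rise is not resolvable); green AC/DC exceeds NIR AC/DC
at $D = 50$ µm, SDD = 2 mm despite the shorter green MOP; and green
AC/DC collapses as the epidermis thickens from 50 to 150 µm.

## Diffusion oracle

`diffusion_reflectance()` implements the steady-state extrapolated-
boundary dipole solution for a semi-infinite homogeneous medium, with
$z_0 = 1/\mu_s'$ and $D = 1/(3\mu_s')$ (the absorption-independent
diffusion coefficient, which also keeps $R(\rho)$ strictly decreasing in
$\mu_a$ — a Beer–Lambert sanity property the synthetic generator relies
on). The engine is required to agree with this closed form within 10% at
$\rho = 2$–4 mm for $\mu_a = 0.01$ mm⁻¹, $\mu_s' = 1$ mm⁻¹,
index-matched, $10^7$ photons. Anisotropy is not part of that stated
condition; the package uses $g = 0.9$ ($\mu_s = 10$ mm⁻¹). This matters:
at these distances (2–4 transport mean free paths) the radial reflectance
is still phase-function dependent, and isotropic scattering genuinely
sits ~20% below the dipole solution while tissue-like forward-peaked
scattering agrees within a few percent — a behavior we cross-checked
against an independent Monte Carlo implementation during development.
The diffusion limit proper (the invariant the oracle stands for) is the
tissue-like regime the source's engine operates in.

## The synthetic phantom generator

`phantom_series()` + `forward_drs()` + `add_noise()` +
`emulate_measurement_set()` stand in for the raw instrument data, which
were never deposited. The generator emulates: seven phantoms whose
bottom-layer hemoglobin concentrations trace one cardiac pulse
(default arc 2.0, 2.4, 2.8, 3.1, 2.8, 2.4, 2.0 mg/mL — the printed
endpoints are 2.0 and 3.1; the intermediate points are package
defaults), measured at SDD 0.5 mm over 450–900 nm, at top-layer
thicknesses 0 and 0.20 mm, in three replicate phantom sets, normalized
against a 99%-reflectance standard.

The fast forward engine is the diffusion closed form for the bottom
layer; a non-zero ink layer is applied as a Beer–Lambert factor
$e^{-k D \mu_{a,\mathrm{ink}}}$ with pathlength factor $k = 4$ (two
crossings at an effective mean cosine of 0.5). This is a deliberately
crude two-layer treatment — adequate for the *orderings* the generator
must reproduce (DRS decreasing in Hb; green AC/DC above NIR; the ink
layer costing proportionally more AC/DC at 450 than at 900 nm), not for
absolute two-layer reflectance. The `mc` engine runs the same series
through the full transport code for spot checks. Noise is multiplicative
log-normal, 1% relative, correlated along wavelength with a 20 nm
Gaussian length-scale (a plausible spectrometer behavior; the source
reports only replicate error bars, no noise law).

What passing these tests does *not* show: the generator shares its
forward model with nothing in the measured world — real phantom spectra
carry baseline drift, stray light, and chromophore impurities that the
noise model does not emulate, and the absolute phantom AC/DC values here
are not comparable to the instrument's (different collection geometry).
The orderings are the claim, and only the orderings are asserted.

## Numerical choices and degenerate inputs

* Wavelength grids are linearly interpolated; extrapolation is an error.
* DRS of exactly 1 in the baseline phase makes AC/DC undefined (zero
  denominator) and errors; zero detected weight yields a flagged empty
  DRS, never a silent zero.
* Roulette threshold/survival are configurable; the defaults
  ($10^{-4}$, 0.1) sit well below the detected weights of every studied
  configuration.
* Voxel size must not exceed one fifth of the vessel diameter; the
  voxelized cylinder volume converges first-order to $\pi r^2 L$.
* Ties in the AC/DC max/min (identical phases) return exactly 0.

## Known limitations

* Straight, parallel, equal-diameter vessels; no capillary loops,
  branching, or multi-layer dermis.
* Index-matched internal boundaries.
* Steady-state only (no time-of-flight), no polarization, no
  fluorescence, CPU only.
* The two-layer diffusion correction is first-order in the top-layer
  optical thickness.
* Default optical properties are literature-shaped stand-ins, not the
  unpublished spectra of any specific instrument or skin type.
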