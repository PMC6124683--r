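---
title: "Methods: photon transport, Beer-Lambert inversion, and tilt-test statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon transport, Beer-Lambert inversion, and tilt-test statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices taken where the design
was genuinely open, and what the synthetic-data tests do and do not show
about real recordings.

# Photon transport in layered tissue

## Model

`simulate_probe()` implements weighted (implicit-capture) Monte Carlo
photon transport in a stack of homogeneous layers: the classic
hop–drop–spin scheme. Each photon is launched as a collimated pencil beam
at the origin; step lengths are sampled from the free path distribution of
the local total interaction coefficient $\mu_t = \mu_a + \mu_s$; at each
interaction a fraction $\mu_a/\mu_t$ of the photon weight is deposited
(absorbed) and the direction is redrawn from the Henyey–Greenstein phase
function with anisotropy $g$. At every refractive-index boundary —
layer/layer, or tissue/ambient — the unpolarised Fresnel reflectance
decides between specular reflection and refraction by Snell's law,
including total internal reflection beyond the critical angle. Low-weight
photons are terminated by Russian roulette (threshold $10^{-4}$, survival
probability 0.1).

The default tissue is the three-layer calf model: 0.3 mm dermis, 1 mm
subdermis, and semi-infinite muscle. The optical properties per layer and
wavelength are **not** fixed by the probe geometry itself; the shipped
values (`tissue_optics_defaults()`, table version "v1") are
representative mid-range values from published tissue-optics
compilations, chosen once:

| layer     | thickness | $\mu_a$ at 805 nm | $\mu_s$ at 805 nm | $g$ | $n$  |
|-----------|-----------|-------------------|-------------------|-----|------|
| dermis    | 0.3 mm    | 0.025 mm⁻¹        | 20 mm⁻¹           | 0.9 | 1.40 |
| subdermis | 1.0 mm    | 0.010 mm⁻¹        | 12 mm⁻¹           | 0.9 | 1.44 |
| muscle    | ∞         | 0.022 mm⁻¹        | 6.6 mm⁻¹          | 0.9 | 1.37 |

Every entry point accepts overrides, so a user with measured properties
substitutes them directly.

## What is recorded

Beyond the usual reflected/transmitted/absorbed totals and a cylindrical
$(r, z)$ fluence grid (0.1 mm voxels, $r \le 40$ mm, $z \le 20$ mm), the
kernel records a *trajectory summary per detected photon*: exit weight,
exit radius, the maximum depth reached, and the partial path length per
layer. Detection means escaping through the surface inside a circular
aperture (default radius 1.5 mm — a typical photodiode scale, and
configurable) centred at the source–detector separation. These records
are what make the probe-design quantities well-defined:

* `penetration_stats()` — exit-weight-weighted median/mean/95th
  percentile of maximum depth. We take the **weighted median of maximum
  depths** as "the" penetration depth; a maximum-based definition would
  be dominated by rare deep trajectories and a fluence-based one would
  not be detector-specific.
* `mean_pathlength()` — weighted mean total and per-layer path, and the
  differential pathlength factor DPF = mean path / separation, which
  feeds the Beer–Lambert pathlength directly.
* `separation_scan()` — one simulation scored at several apertures
  simultaneously, exposing the signal-versus-depth trade-off that fixes a
  probe geometry. Exactly duplicated separations are permitted (identical
  rows); distinct but overlapping apertures are a validation error.

## Numerical choices

* **Energy ledger.** Russian roulette multiplies surviving weights by
  $1/p$; that renormalisation is folded into the absorbed-weight ledger
  (kills credit their remaining weight, survivals debit the boost), so
  `reflected + transmitted + absorbed = launched` holds to floating-point
  rounding for *every* run, not just in expectation. The fluence grid
  stores only physical deposits and is everywhere non-negative.
* **RNG.** The kernel owns a seedable xoshiro256+ generator: a given seed
  reproduces the simulation bit-identically, independent of R's RNG
  state, across runs and platforms with IEEE doubles.
* **Validation.** The suite checks the transport against an independent
  closed-form oracle: the steady-state diffusion-approximation reflectance
  of a pencil beam on a matched semi-infinite medium (dipole source,
  extrapolated boundary), which the simulation must match within 15% at
  2 cm for scattering-dominated media. Conservation, Fresnel limits,
  determinism, and depth monotonicity in separation are tested as
  properties.
* **Photon budgets.** Characterisation runs use $10^6$ photons (a few
  minutes on one core); unit tests use $10^4$–$5\times10^5$. These sizes
  were chosen to put Monte Carlo error well inside the tolerance of each
  check. With the v1 properties the 2 cm separation yields a median
  detected-photon maximum depth of ≈0.8 cm and a DPF of ≈4.8.

A note on naming: the probe-design literature sometimes speaks of
"modified" Monte Carlo methods without pinning down the modification. The
reading implemented here is standard MCML-style transport *plus*
per-photon trajectory recording at the detectors; no variance-reduction
beyond implicit capture and roulette is used.

# The modified Beer–Lambert inversion

## Model

For each detector and wavelength the baseline intensity $I_0$ is the mean
detected intensity over the supine baseline window (default the first
10 min; configurable). The attenuation change is the decadic optical
density $\Delta A(\lambda, t) = -\log_{10} I(t)/I_0$. We pair the decadic
log with **decadic** molar extinction coefficients (cm⁻¹ mM⁻¹); the
choice of base cancels as long as the two are consistent, and the decadic
pair is the optical-density convention. The shipped coefficient table
(`default_extinction()`) comes from the standard compiled hemoglobin
spectra; at 805 nm the Hb/HbO₂ gap is 8.3%, the smallest of the three
wavelengths, as an isosbestic-adjacent wavelength should have. The table
is a plain TSV and is replaceable.

With $L(\lambda) = \mathrm{DPF}(\lambda) \times \rho$ (default DPF 4.0
for all wavelengths — mid-range for muscle, overridable per wavelength,
e.g. from `mean_pathlength()`), the three wavelengths give three linear
equations in $(\Delta C_{Hb}, \Delta C_{HbO_2})$. The system is solved
per time point by ordinary least squares via the normal equations (the
design is fixed over time, so one pseudoinverse serves the whole series);
the per-time-point residual norm is returned as a fit diagnostic, and a
condition number above $10^8$ (proportional extinction columns) is a
refusal, not a warning. $\Delta\mathrm{Oxy}$ and $\Delta\mathrm{BV}$ are
the element-wise difference and sum; negative $\Delta\mathrm{Oxy}$ is
meaningful (oxygen extracted faster than supplied) and preserved.

Two detectors flank the source; by default their attenuations are
averaged before inversion (halving uncorrelated intensity noise), and
either detector can be selected instead. The whole inversion is linear,
exact on noiseless forward-modelled data (the round trip is tested to
$10^{-9}$), and scale-equivariant.

# Tilt-protocol analysis

* **Segmentation** uses half-open windows $[t_0, t_1)$ partitioning the
  10/30/10-min protocol; the ~5 s posture transition belongs to the
  segment it initiates. A recording shorter than the protocol is refused
  with the missing-sample count.
* **Rates of change** are OLS slopes over the first 10 min after each
  posture change. One caveat documented deliberately: a 10-min window
  *dilutes* a fast early upstroke that plateaus. With the default
  templates the control oxyhemoglobin rise (plateau at ~2 min) has a
  *smaller* 10-min OLS slope than the patient group's slow 10-min ramp,
  even though its initial upstroke is several times steeper; the
  upstroke contrast is recovered with `window_min = 2`. Slope
  comparisons should state their window.
* **AUC** is the trapezoidal integral over the tilt in μM·min. Signals
  are already baseline-referenced changes, so no further subtraction is
  applied. Group-level AUC is reported subject-wise-then-averaged (the
  primary variant) and as the AUC of the group-mean curve; for aligned
  series of equal length the two coincide up to sampling.
* **Group tests** are equal-variance two-tailed Student t-tests on
  per-subject tilt-segment averages, α = 0.01 per signal with no
  multiplicity correction (four signals are reported side by side;
  readers who prefer family-wise control can apply it to the returned
  p-values). Welch's form is available via `var_equal = FALSE`.
  Zero-variance degeneracies return p = 1 (equal means) or a flagged
  p = 0.
* **Cross-device correlation** resamples the reference trace onto the
  device grid by linear interpolation and reports the R² of a simple
  linear regression over the tilt window; the μM-vs-percent unit
  mismatch is absorbed by the fit.
* **Heart-rate criterion**: strict rise thresholds of 40 bpm (age < 18)
  and 30 bpm (adults) between the baseline maximum and tilt maximum. The
  packaged subject table (`read_subjects()`) stores the group-level
  summaries directly; its patient rows rise 47 bpm (criterion true) and
  its control rows 19 bpm (false).

# The synthetic cohort generator

The generator exists so that every stage — raw file reading, inversion,
segmentation, statistics — can be exercised end to end, reproducibly,
with known ground truth.

**Trajectory templates.** Each group × chromophore has a rise-to-plateau
ramp during the tilt and an exponential relaxation in recovery. A ramp
reaching plateau $A$ after $r$ minutes of a 30-min tilt has
$\mathrm{AUC} = A(30 - r/2)$, so plateau amplitudes are *solved* from the
group AUC levels the cohort is designed to exhibit (113/52 μM·min for
deoxyhemoglobin in patients/controls, 42/41 for oxyhemoglobin) rather
than invented. Rise times encode the qualitative group dynamics: Hb keeps
rising for the whole tilt in patients (r = 30) but plateaus early in
controls (r = 4); HbO₂ rises for ~10 min in patients versus a sharp
~2-min upstroke in controls. Recovery time constants are 6 min (patients)
vs 2 min (controls) — slower clearance in the patient group. The
templates are constrained by AUCs, rise times and the significance
pattern, but not uniquely determined; they are one defensible shape
family, not an estimate of any individual's physiology.

**Forward model and noise.** True trajectories are templates scaled by
one lognormal amplitude factor per subject per signal (sdlog 0.1 ≈ 10%
between-subject variability). Attenuations follow the same Beer–Lambert
design used by the inversion; intensities $I = 100 \times 10^{-\Delta A}$
receive multiplicative Gaussian noise (CV 0.5% per sample) independently
per wavelength and detector. With all dispersions at zero the
generator → inversion round trip recovers the templates to $10^{-6}$ μM,
*for any* extinction table and DPF — the forward model cancels, which the
suite verifies with a deliberately different table. The noise defaults
were set so that, at n = 6 per group, the designed significance pattern
(Hb/ΔOxy/ΔBV significant at α = 0.01, HbO₂ not) holds in ≥ 90% of master
seeds; the suite checks this over 100 seeds.

**Heart rate and reference trace.** Heart-rate summaries are two scalars
per subject drawn around the group centres (76→123 bpm patients,
66→85 bpm controls, sd 1.5 bpm) — tight enough that default subjects
fall on the correct side of the strict thresholds essentially always.
The reference oximeter trace is an affine map of the true ΔOxy onto a
percent scale (70 + 4·ΔOxy) plus 0.5% additive noise.

**What the generator does not emulate.** Real recordings contain slow
drifts, motion and contact artifacts, pulsatile and respiratory
components, scattering changes, and subject-specific template shapes —
none of which are modelled. Two consequences matter when reading test
results. First, the cross-device R² ≥ 0.9 property holds for *patient*
subjects, whose ΔOxy excursion (≈6 μM) dominates the measurement noise;
synthetic control subjects have a tiny ΔOxy excursion (≈0.4 μM plateau,
a direct consequence of the near-equal HbO₂/Hb AUC calibration), so
their synthetic R² is low even though real control recordings show high
R² — the generator's control oxygenation dynamic range, not the
pipeline, is the limiting factor. Second, passing the synthetic suite
shows the pipeline is correct and well-conditioned under the designed
signal model, not that any clinical conclusion transfers.

# Problem sizes and runtime

Characterisation targets run at $10^6$ photons (transport) and 100 master
seeds × 12 subjects × 3000 samples (statistics), a few minutes on one
core in total; unit tests use smaller sizes chosen so each check's
tolerance comfortably exceeds its Monte Carlo error.

# Known limitations

* Continuous-wave, differential oximetry only: no absolute StO₂, no
  time-/frequency-domain transport, no scattering-change correction, and
  no additional chromophores (water, lipid, cytochrome oxidase).
* Planar layered geometry; no anatomical curvature or lateral
  heterogeneity.
* The DPF default (4.0, wavelength-independent) is a convention; users
  wanting wavelength-resolved pathlengths should feed
  `mean_pathlength()` output into `pathlength_spec()`.
* Group statistics mirror the fixed-α t-test design; no mixed-effects or
  repeated-measures modelling.
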