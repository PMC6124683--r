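# nirstilt

Computational stack for reflectance near-infrared spectroscopy (NIRS)
muscle oximetry during head-up-tilt (HUT) testing. It is aimed at
biomedical-optics groups building or using continuous-wave multi-wavelength
probes to study orthostatic disorders such as postural orthostatic
tachycardia syndrome (POTS): it covers probe design (how deep does a given
source–detector geometry interrogate?), signal inversion (from detected
intensities to hemoglobin concentration changes), and the group-level
statistics of the tilt protocol — plus a seeded synthetic cohort generator
so the whole pipeline can be exercised and tested without hardware.

## What it computes

**Photon transport (probe design).** A weighted Monte Carlo simulation
(hop–drop–spin with Henyey–Greenstein scattering, Fresnel boundaries,
Russian roulette) of photon trajectories in a layered calf model — 0.3 mm
dermis, 1 mm subdermis, semi-infinite muscle. Photons collected by a
circular detector aperture are recorded individually, giving the
penetration-depth distribution, the mean optical path length per layer and
the differential pathlength factor (DPF), and source–detector separation
scans.

**Modified Beer–Lambert inversion.** With the baseline intensity
*I₀* defined over the supine baseline window, the attenuation change at
each wavelength is

    ΔA(λ, t) = −log₁₀( I(λ, t) / I₀(λ) ) = L(λ) Σᵢ εᵢ(λ) ΔCᵢ(t)

with `L = DPF × separation` the effective optical path. At the three
device wavelengths (735, 805, 850 nm — the Hb and HbO₂ absorption peaks
plus a near-isosbestic wavelength) this is an over-determined linear
system in the two unknowns, solved per time point by least squares:

    ΔOxy = ΔC_HbO₂ − ΔC_Hb        ΔBV = ΔC_HbO₂ + ΔC_Hb

give the oxygenation and blood-volume indices.

**Tilt analysis.** Segmentation of the 10/30/10-min 0°/70°/0° protocol
into half-open windows, segment means ± SE, least-squares rates of change
over the first 10 min after each posture change, trapezoidal areas under
the curve (AUC, μM·min) over the 30-min tilt, equal-variance two-tailed
Student t-tests between groups (α = 0.01 per signal), cross-device R² of
the oxygenation trace against a reference oximeter, and the age-dependent
heart-rate criterion (rise > 40 bpm for children, > 30 bpm for adults,
strict).

**Synthetic cohorts.** Rise-to-plateau trajectory templates whose plateau
amplitudes are solved in closed form from group AUC targets
(`A = AUC / (30 − rise/2)`), a forward optical model producing noisy
three-wavelength, two-detector intensity recordings, heart-rate summaries
and reference-oximeter traces — all reproducible from one master seed.

## Worked example

```r
library(nirstilt)

## generate the default two-group cohort and analyse it end to end
coh <- generate_cohort(cohort_spec(seed = 42))
res <- analyze_cohort(process_cohort(coh))
print(res)
```

```
<cohort_result>
Group-mean tilt AUC (uM*min):
   group     signal auc_uM_min
 control     dBV_uM  92.088682
    POTS     dBV_uM 156.384312
 control   dC_Hb_uM  50.034012
    POTS   dC_Hb_uM 112.898574
 control dC_HbO2_uM  42.054670
    POTS dC_HbO2_uM  43.485738
 control    dOxy_uM  -7.979342
    POTS    dOxy_uM -69.412835
Tilt-average group tests (alpha = 0.01 ):
  dC_Hb_uM   t =  12.964  p = 1.41e-07  *
  dC_HbO2_uM t =   0.559  p = 0.589
  dOxy_uM    t = -14.812  p = 3.95e-08  *
  dBV_uM     t =   9.803  p = 1.91e-06  *
```

Deoxyhemoglobin accumulates about twice the area in the patient group
(≈113 vs ≈50 μM·min) while oxyhemoglobin is statistically
indistinguishable between groups — the patient group differs in Hb, ΔOxy
and ΔBV but not HbO₂.

Probe design with the transport simulator:

```r
m <- default_tissue_model(805)                       # dermis/subdermis/muscle
s <- simulate_probe(m, probe_geometry(2.0), n_photons = 5e5, seed = 7)
penetration_stats(s, 1)    # median 0.78 cm, mean 0.85 cm, 95th pct 1.45 cm
mean_pathlength(s, 1)$dpf  # 4.78: mean photon path is ~4.8x the separation
```

At the 2 cm separation the detected photons' median maximum depth is
≈0.8 cm — the measurement interrogates the muscle layer, consistent with a
penetration depth of up to about 1 cm.

A thin command-line front end over the same functions is installed at
`inst/cli/nirstilt` (subcommands `simulate-probe`, `generate`, `process`,
`analyze`, `run-all`, `show-config`).

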