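# rootEIT

Spectral electrical impedance tomography (sEIT) turns multi-frequency
four-point impedance measurements into images of complex resistivity. Plant
roots polarize in an electric field (their cell membranes act as tiny
capacitors) while water does not, so in a water-filled rhizotron the
*phase* image isolates the root system even though the *magnitude* image
barely sees it. `rootEIT` implements a complete, tested laboratory workflow
for estimating root biomass and surface area from that polarization
signature, for researchers developing electrical root-phenotyping methods:

* **Optimized measurement design** — greedy selection of four-point
  configurations (800 configurations, at most 40 injection dipoles)
  maximizing the rooting-zone-weighted diagonal of the model resolution
  matrix `R = (J'Wd'WdJ + λ Wm'Wm)⁻¹ J'Wd'Wd J` on the tank geometry.
* **Forward modelling** — 2D thin-tank complex-conductivity finite
  elements with adjoint sensitivities and numerically computed geometric
  factors.
* **Tomographic inversion** — per-frequency two-stage Gauss–Newton
  (log-magnitude, then linearized phase) with first-order smoothness,
  error weighting `Δ|Z| = a|Z| + b`, `Δφ = c`, and convergence at
  error-weighted RMS ≈ 1.
* **Debye decomposition** — per-cell fits of
  `ρ*(ω) = ρ₀ (1 − Σ m_k [1 − 1/(1+iωτ_k)])` giving total chargeability
  `m_tot` and mean logarithmic relaxation time, with
  `τ = r²/(2D)` linking relaxation times to polarization length scales.
* **Root traits** — volume-weighted root-zone integration
  `m_rz = V_rz · Σ V_k m_tot,k / Σ V_k` (in cm³) and the power-law
  calibrations `A_surf ≈ 221 · m_rz^0.93` (cm²),
  `M_bio ≈ 0.169 · m_rz^0.94` (g).
* **Synthetic phantoms and plant ensembles** — root-shaped −25 mrad
  anomalies in 105.1 µS/cm tap water and 23-plant trait ensembles, so the
  whole chain runs and validates without laboratory data.

## Worked example

The analysis lives in numbered scripts under `analysis/`; each writes its
tables to `results/`. The central experiment compares the optimized
measurement scheme with a reduced scheme that excludes the central
electrode batch, on a root-shaped phantom with a −25 mrad phase anomaly at
1 kHz, 10 Gaussian-noise realizations per scheme (1% + 0.001 Ω magnitude,
0.5 mrad phase), averaging the 10 inversions per arm:

```sh
Rscript analysis/01_design_scheme.R
Rscript analysis/02_scheme_comparison.R
```

prints

```
optimized scheme: 800 configurations, 40 injection dipoles
reduced scheme (central batch excluded): 151 configurations
ROI-weighted resolution sum: 3.53 -> 48.39 over 41 greedy iterations

     scheme configurations       pcc      ssim   rms_min   rms_max
1 optimized            800 0.9455912 0.2886976 0.9589748 1.0018944
2   reduced            151 0.8847146 0.2617679 0.9299714 0.9888051
optimized scheme dominates reduced on PCC (TRUE) and SSIM (TRUE)
```

The optimized scheme reconstructs the anomaly markedly better (Pearson
correlation 0.95 vs 0.88 against the true phase image), and every
inversion converged to its noise level (RMS ≈ 1). The reduced scheme's
missing central electrodes leave the lower part of the root anomaly
under-resolved. SSIM values are reported under this package's documented
convention (2 mm raster, 11×11 Gaussian window, dynamic range of the true
image) and are comparable only within one convention.

```sh
Rscript analysis/03_length_scales.R
```

```
              quantity frequency_Hz     tau_s length_um
1 upper band frequency    1.000e+03 1.592e-04    0.5642
2 lower band frequency    7.900e-01 2.015e-01   20.0730
3  root-diameter scale    1.273e-03 1.250e+02  500.0000
band maps to 0.56 - 20.07 um; a 0.5 mm scale needs tau = 125 s (f = 1.3 mHz)
```

With a Stern-layer diffusion coefficient of 1e-9 m²/s the 0.79 Hz–1 kHz
band is sensitive to polarization at 0.56–20.07 µm — internal root
structures, far below the ~0.5 mm root diameter, which would require
measuring at 1.3 mHz.

```sh
Rscript analysis/04_ensemble_recovery.R
```

```
recovered exponents 0.905 (area) and 0.915 (biomass) vs generating 0.93 / 0.94
```

On a 23-plant synthetic ensemble with 20% calibration scatter, refitting
the power laws from the chargeability images recovers the generating
exponents well within the scatter-implied uncertainty.

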