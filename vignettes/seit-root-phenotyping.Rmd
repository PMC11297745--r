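---
title: "Quantitative root phenotyping with spectral electrical impedance tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative root phenotyping with spectral electrical impedance tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

A plant root system suspended in a water-filled rhizotron (a thin
transparent tank, here 52 cm x 52 cm x 2.5 cm with 36 Ag/AgCl electrodes)
polarizes under an alternating current: ions in the electrical double
layers of cell membranes and root surfaces are displaced and relax back,
which shows up as a small negative phase shift between injected current and
measured voltage. Water barely polarizes, so the phase image isolates the
roots. Spectral electrical impedance tomography (sEIT) measures four-point
complex impedances `Z* = U*/I*` for many electrode quadrupoles (current
through A,B; voltage across M,N) over a frequency band and inverts them
into images of the complex resistivity `rho* = |rho*| exp(i phi)` per mesh
cell. `rootEIT` implements that whole chain on synthetic data:

1. **Geometry and mesh** (`rhizotron_geometry()`, `build_mesh()`): the tank
   is modelled in 2D over its water-filled cross-section (0.52 m x 0.49 m;
   the water level sits 3 cm below the rim and forms the upper boundary),
   with the 2.5 cm thickness entering as a conductance scale. The mesh is a
   graded tensor-product triangulation: grid lines pass through every
   electrode (electrodes are mesh nodes) and extra lines at a fraction of
   the nearest-electrode spacing refine the cells around them.
2. **Forward model** (`simulate_scheme()`, `sensitivity_matrix()`): linear
   finite elements solve `-div(sigma* t grad u) = I delta` with insulating
   boundaries; one factorization per frequency serves all injection poles.
   Geometric factors are computed numerically from a homogeneous reference
   solve, so apparent resistivity is exact on the homogeneous model by
   construction. Sensitivities (the Jacobian of log apparent resistivity
   with respect to log cell resistivity) come from the adjoint identity --
   a per-cell dot product of the injection and measurement pole gradients.
   Rows of this Jacobian sum to 1; their L1 norm measures how strongly a
   configuration cancels its own sensitivity and therefore amplifies noise
   and intrinsic phase in the apparent quantity.
3. **Measurement design** (`optimize_scheme()`): from a deterministic
   candidate pool, a greedy algorithm assembles the scheme that maximizes
   the rooting-zone-weighted sum of the model resolution matrix diagonal
   `diag R = diag[(J'Wd'WdJ + lambda Wm'Wm)^-1 J'Wd'Wd J]`, adding the
   best `batch` candidates per iteration with exact rank-one
   (Sherman-Morrison) gain evaluation. At most 40 distinct injection
   dipoles are used (an acquisition-time constraint), and the final scheme
   has 800 configurations. The optimization runs on a homogeneous water
   model, real part only, on a coarse design mesh.
4. **Noise and errors** (`error_model()`, `contaminate()`): magnitude
   errors follow `d|Z| = a|Z| + b`, phase errors are a constant `c` mrad;
   the same model generates synthetic Gaussian noise and weighs the
   inversion misfit, and `estimate_phase_error()` sets `c` per frequency to
   half the population standard deviation of the measured phases. The
   water-reference correction interface (`correct_with_water_reference()`)
   rescales magnitudes by modelled/measured homogeneous ratios and
   subtracts the reference phase, confined to one function so the procedure
   can be swapped.
5. **Inversion** (`invert_frequency()`): each frequency is inverted
   separately in two stages. The magnitude stage is a damped Gauss-Newton
   iteration on log resistivity with first-order smoothness, cooling the
   regularization until the error-weighted RMS reaches 1 (discrepancy
   principle). The phase stage solves the linearized phase problem about
   the converged magnitude model under the same smoothness operator. With
   phases below ~30 mrad the linearization is essentially exact (we
   measure worst-case linearization residuals of ~0.005 mrad on the
   default phantom), which is why the two-stage split is adequate.
6. **Spectral analysis** (`fit_debye()`, `decompose_field()`): each cell's
   complex resistivity spectrum is decomposed into Debye relaxation terms
   `rho*(w) = rho0 (1 - sum_k m_k [1 - 1/(1 + i w tau_k)])` on a fixed
   log-spaced relaxation-time grid, giving the total chargeability
   `m_tot = sum m_k` and the mean logarithmic relaxation time. Cells with
   `m_tot < 1e-3` count as non-polarizable background.
7. **Root traits** (`average_chargeability()`, `predict_traits()`): the
   volume-weighted mean chargeability over the root-zone mask times the
   zone volume gives the integrated root-zone chargeability `m_rz` (cm^3),
   which predicts total root surface area as `A_surf ~ 221 m_rz^0.93`
   (cm^2) and dry biomass as `M_bio ~ 0.169 m_rz^0.94` (g).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `a`, `b` | 0.02, 0.01 Ohm | relative / absolute magnitude error (synthetic experiment: 0.01, 0.001) |
| `c` | 0.5 mrad | constant phase error, or data-driven (`std/2`, floored at 0.1 mrad) |
| analysis band | 0.79 Hz - 1 kHz | above 1 kHz the phase accuracy of the instrument degrades |
| `tau` grid | 20 pts/decade over `[1/(2 pi f_max)/10, 10/(2 pi f_min)]` | Debye relaxation-time grid |
| `fit_debye(lambda)` | 0.01 | smoothness of the chargeability spectrum; noiseless round trips recover `m_tot` within 1% across two orders of magnitude of this value |
| `target_size`, `dipole_budget` | 800, 40 | scheme size and injection budget |
| `l1_cap` | 6 | maximum sensitivity-cancellation (noise amplification) of a candidate |
| `D` | 1e-9 m^2/s | Stern-layer ion diffusion coefficient for `relaxation_length()` |

## Numerical choices

* **Gauge and solvability.** The pure-Neumann FEM system is singular up to
  a constant; one node is pinned and solutions are returned in the
  zero-mean gauge. Complex systems are solved as 2x2 real block sparse
  systems.
* **Sign convention.** In a closed tank many quadrupoles have negative
  transfer impedance. The geometric factor carries the sign, so apparent
  resistivity is positive and apparent phase is polarity-corrected
  (`Arg(K Z*)`); phases are reported in mrad, negative for capacitive
  polarization.
* **Regularized solves.** Gauss-Newton systems are solved through a
  Woodbury split (sparse Cholesky of the smoothness part, low-rank update
  for the data part) with a 1e-8 relative ridge removing the constant null
  space of the first-order difference operator. Smoothness differences are
  weighted by shared-edge length over centroid distance so the roughness
  penalty per physical distance is uniform on the graded mesh.
* **Discrepancy control.** Both stages target RMS 1 and bisect back into
  [0.9, 1.1] when a step or cooling overshoots, so converged results sit at
  the error level rather than over-fitting. The phase stage additionally
  stops cooling when one more cooling step improves the misfit by less
  than 3%: the magnitude model feeding the phase Jacobian leaves a small
  model-error floor slightly above RMS 1, and chasing it fits noise.
* **Candidate hygiene.** Configurations whose homogeneous impedance is
  near-null, or whose sensitivity row has L1 norm above `l1_cap`, are
  excluded from the design pool: they are measurable but amplify noise and
  intrinsic phase by that factor (we observed apparent phases near -2900
  mrad from a -25 mrad anomaly before the cap).
* **Degenerate inputs.** Duplicate electrodes, quadrupoles with repeated
  electrodes, non-positive conductivities, empty masks, all-masked zones,
  `m_tot >= 1`, non-positive power-law data and empty candidate pools are
  rejected with errors; magnitude noise that would produce non-positive
  `|Z|` is redrawn.

## What the synthetic generators emulate -- and what they do not

`phantom_spec()` reproduces the study conditions of the design-comparison
experiment: tap water at 105.1 uS/cm, a root-shaped polygon whose cells
carry a Debye-consistent dispersion reaching -25 mrad at 1 kHz, and
Gaussian noise at 1% relative + 0.001 Ohm magnitude and 0.5 mrad phase. The
chargeability spectrum is a broad log-normal in log tau (measured root
spectra show no pronounced peak), centred at 1 ms. The centre value is a
deliberate compromise: mean relaxation times observed on real roots span
1-12 ms, but a spectrum centred much above 1 ms cannot produce -25 mrad at
1 kHz without a total chargeability so large that the resistivity magnitude
would drop by tens of percent, contradicting the observation that root
zones are nearly invisible in magnitude. At 1 ms the phantom reaches the
target phase with `m_tot ~ 0.11` and a ~10% magnitude dip.

`make_plant_ensemble()` emulates the measured plant set (23 plants: 7
maize, 7 black bean, 5 pinto bean, 4 soy bean, 13-73 days after sowing;
surface areas up to ~2554 cm^2, biomass up to ~2.15 g, mean diameters
0.35-0.55 mm). Root-zone chargeability is tied to the traits by inverting
the power-law calibrations with 20% log-normal scatter, so
parameter-recovery tests have known ground truth. This is a statistical
emulation only: polygons are smooth droplets, chargeability is uniform
within a zone, and no physiology, depth gradients or species-specific
architecture are modelled. Passing tests therefore demonstrate that the
*pipeline* recovers what it assumes — not that real roots obey it.

The scheme-comparison experiment commits the usual synthetic-study
simplification of simulating and inverting on the same mesh; the added
Gaussian noise, not discretization error, is the dominant perturbation.

## Design choices on genuinely open points

* **Electrode layout.** Only a figure, not coordinates, documents the real
  layout. The default reconstructs its visual arrangement: 7 electrodes on
  each side wall, 7 on the bottom, and three interior columns of 5 spanning
  the rooting zone. The "central batch" whose exclusion defines the
  reduced scheme is taken as the lower three electrodes of each interior
  column: removing every configuration touching it creates the documented
  central low-sensitivity zone, and the reduced scheme then under-resolves
  the lower part of the anomaly, the failure mode the experiment is about.
  All downstream code consumes coordinates and never assumes this layout.
* **Candidate pool.** The published design states the greedy algorithm, the
  800/40 structure and the ROI weighting but not the pool. We use long
  injection dipoles (>= 0.2 m, 60 dipoles) crossed with short potential
  dipoles (<= 0.15 m), reciprocal-unique and lexicographically ordered,
  filtered for near-null impedance and sensitivity cancellation.
* **Image metrics.** PCC is computed on cell values over the whole domain;
  SSIM on 2 mm nearest-cell rasters with an 11x11 Gaussian window (sigma
  1.5) and standard constants, the dynamic range taken from the true
  image. SSIM is strongly convention-dependent (window, range, clipping,
  raster); absolute SSIM values are comparable only within one convention.
* **Calibration statistics.** R^2 and PCC of the trait power laws are
  computed in log10 space, where the fit is performed.
* **m_rz units.** Reported in cm^3 to match the calibration constants.

## Problem sizes

The default experiment uses a ~2900-cell inversion mesh, a ~1100-cell
design mesh, a 5875-candidate pool and 10 noise realizations per scheme;
a full run (design + 20 inversions + metrics) completes in a few minutes
on a single core. The per-cell Debye decomposition fits ~100 chargeability
unknowns to each cell spectrum by damped Gauss-Newton and processes a few
thousand cells per minute.

## Known limitations

* 2D thin-tank physics with point electrodes: no 3D effects, no
  complete-electrode-model contact impedances, no electrode polarization.
  The 0.5 cm physical electrode protrusion is ignored; at the tank scale
  its field perturbation is far below the assumed noise.
* The two-stage inversion linearizes the phase problem; for phase
  magnitudes far beyond ~100 mrad a coupled complex Gauss-Newton would be
  preferable.
* Band-limited Debye decomposition underestimates total chargeability when
  the generating spectrum extends below `1/(2 pi f_max)` — an intrinsic
  property of the band, visible in the phantom round-trip tests (~10-13%
  deficit for the default phantom).
* Real-data corrections (3D-to-2D magnitude ratio, setup polarization) are
  implemented as a single swappable interface reconstructing the stated
  intent; validating them needs the original raw data.
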