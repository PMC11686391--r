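# pfasim

Computational models of focal **pulsed field ablation (PFA)** of the
ventricles, for cardiac electrophysiology and electroporation researchers
who want a fully scripted, testable counterpart to the usual commercial
FEM workflow. The package covers the whole modelling chain used to
characterise ventricular PFA dosing:

* an idealized biventricular geometry (two truncated ellipsoids, an RV
  crescent, an IVC cylinder with a decapolar return catheter, surrounding
  bulk tissue) voxelised on a graded hexahedral grid, with the 13-segment
  LV labelling and perpendicular catheter placement with a 0.5 mm tip
  indentation;
* rule-based myocardial fiber frames: the transmural (sheet) direction from
  a Laplace solve, the wall-depth parameter
  `beta = D_epi / (D_epi + D_endo)`, and a helix angle interpolated
  linearly from +80° (endocardium) to −40° (epicardium);
* the stationary nonlinear conduction problem
  `div(sigma(E) grad V) = 0` with anisotropic myocardium
  (`sigma_par = 0.5 S/m`, anisotropy ratio 1.34), an electroporation
  conductivity increase `f_E` rising smoothly from 1 to 2.65 across
  550 ± 250 V/cm, isotropic scar blending
  `sigma = f_scar * 1 S/m + (1 - f_scar) * sigma_myo(E)`, and electrode /
  insulation boundary conditions, solved by under-relaxed Picard iteration;
* **lethal electric field threshold (LET)** inversion: bisection on the
  exceedance isovolume `V(LET) = ∫ [E >= LET] dV` against measured lesion
  volumes, per-dose medians, and the dose power law `LET(N) = a N^b`;
* transient pulsed Joule heating
  `rho C (dT/dt + u . grad T) = div(k grad T) + ONOFF * duty * sigma E^2`
  with analytic fully developed laminar blood flow in the LV and IVC,
  temperature-dependent `k(T)` and `sigma(E, T)`, and two damage scores:
  the thermal dose (≥ 55 °C for ≥ 1 s) and the Arrhenius integral
  `Omega = ∫ A exp(-dE/(R T)) dt` (damage at `Omega >= 1`);
* intracardiac electrogram (iEGM) analysis: slope-threshold QRS detection,
  per-beat bipolar peak-to-peak amplitude, the unipolar **current of
  injury** (ST-segment area divided by window length), 10-s segment
  medians and pre / 30 s / 3.5 min timepoints;
* biplane fluoroscopic catheter reconstruction: cubic-spline resampling at
  1 mm, equal-height matching across views, least-squares ray
  triangulation, and scale calibration from the known return-electrode
  span;
* seeded synthetic-data generators for every pipeline input (lesion-volume
  tables, scar intensity maps, ECG/iEGM records, biplane projections) with
  exact ground truth.

Everything is plain R on top of `Matrix` (sparse linear algebra) and
`signal` (filters); the hexahedral finite-element and finite-volume solvers
are part of the package.

## Worked example: recovering lethal thresholds from lesion volumes

Generate a synthetic lesion cohort from forward field solves at known
per-dose thresholds (725 / 520 / 484 / 394 V/cm for 1 / 4 / 8 / 16 trains,
lognormal measurement noise `sigma_log = 0.15`), then invert each lesion
volume by bisection and summarise:

```r
library(pfasim)
study <- run_let_study(
  params = coarse_geometry_params(),
  doses = data.frame(amplitude = 1500, n_trains = c(1, 4, 8, 16)),
  true_let = c(725, 520, 484, 394),
  lesions_per_dose = 8, sigma_log = 0.15, seed = 7)
study$medians
#>   n_trains timepoint median_let n
#> 1        1        7d   786.4197 8
#> 2        4        7d   504.0955 8
#> 3        8        7d   479.2480 8
#> 4       16        7d   380.9387 8
with(study$power_fit, sprintf("LET(N) = %.0f * N^(%.3f), R^2 = %.3f", a, b, r_squared))
#> [1] "LET(N) = 768 * N^(-0.252), R^2 = 0.969"
```

The recovered medians sit within 8% of the generating thresholds at this
cohort size; the fitted exponent is negative — more pulse trains lower the
field needed to kill tissue, with diminishing returns.

The thermal side runs the same way:

```r
thermal <- run_thermal_study(params = coarse_geometry_params(),
                             protocol = pulse_protocol(amplitude = 1500,
                                                       n_trains = 16),
                             scenarios = c("low", "high"))
thermal$runs$low$probe_max        # peak temperature at 1 / 3 / 7 mm depth
thermal$runs$low$dose_volume_mm3  # >= 55 degC for >= 1 s
```

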