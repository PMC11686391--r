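---
title: "Modelling ventricular pulsed field ablation with pfasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventricular pulsed field ablation with pfasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfasim)
```

## The problem

Focal pulsed field ablation delivers trains of high-voltage biphasic pulses
between a catheter tip pressed against the endocardium and a multi-electrode
return catheter in the inferior vena cava. Tissue above a *lethal electric
field threshold* (LET) dies by irreversible electroporation; Joule heating is
a side effect that must stay small for the "nonthermal" safety argument to
hold. `pfasim` implements the complete model chain needed to study this:
the stationary nonlinear field problem that maps a delivery to a field
distribution, the inversion of measured lesion volumes into LETs, the pulsed
electro-thermal problem that bounds thermal damage, the electrogram
current-of-injury analysis used to track lesions acutely, and the biplane
reconstruction used to localise catheters. All inputs can be produced by
seeded generators with known ground truth, so every stage is testable
end to end.

## Geometry and discretization

The ventricles are idealized as two coaxial ellipsoids truncated at the
basal plane (LV cavity 20 × 20 × 42 mm, epicardium 29 × 29 × 50 mm by
default, porcine scale), an optional thinner RV crescent from a third,
offset ellipsoid, an IVC cylinder (9 mm radius) in surrounding bulk tissue,
and voxelised catheters: an 8 F, 5 mm-tip focal catheter placed
perpendicular to the wall at the centre of any of the 13 LV segments
(3 long-axis levels × 4 sectors + apical cap) with a rigid 0.5 mm
indentation, and a 10-band decapolar return catheter, by default pressed
against the IVC wall. The exact heart dimensions are documented assumptions
(in vivo such schematic hearts are scaled per animal to MRI measurements);
every length is configurable through `geometry_params()`.

The domain is a graded tensor-product hexahedral grid (`graded_axis()`):
0.9 mm cells in an ±8 mm window around the catheter tip, 2 mm across the
IVC electrode span (grid lines aligned with the band edges), geometric
coarsening (ratio 1.6, cap 28 mm) towards a bulk box 2.2× the heart+IVC
bounding box — about 120k cells. Tests and exploratory runs use
`coarse_geometry_params()` (~33k cells); the blood-exposure accounting uses
an electrode-refined variant (`ivc_fine = TRUE`, 0.65 mm tip cells, ~310k).
A convergence contract (shell volumes within 2% of the analytic ellipsoid
values under 2× refinement) is enforced in the tests.

Electrodes are *immersed*: electrode cells stay in the conduction problem
with a large effective conductivity (`sigma_metal = 1e4` S/m, enough to be
equipotential) and the Dirichlet potential is applied on an eroded interior
node set. This removes the systematic half-cell enlargement that
interface-node constraints produce. It does not remove voxelisation error
entirely: at 0.65–0.9 mm cells the 2.67 mm tip is only 3–4 cells across,
and the total current converges from above (22.3 → 21.1 → 20.6 A at
1.1 / 0.9 / 0.65 mm). Quantities that scale with total current — notably
the blood volumes exposed above 1000/1500 V/cm, which scale like
`I^(3/2)` — inherit this bias and should be read as upper estimates at the
default resolution.

## Fiber architecture

The sheet (transmural) axis is the normalized gradient of a Laplace
solution `U` (1 on the endocardium, 0 on the epicardium, basal plane
insulated). The wall-depth parameter is computed from distances to the two
surfaces, `beta = D_epi / (D_epi + D_endo)`, and the fiber helix angle is
`theta = beta * 80° + (1 - beta) * (-40°)`, measured from the
circumferential direction. The frame is built by projecting the global
apico-basal axis (+z) orthogonal to the sheet axis, completing the
right-handed triad, and rotating about the sheet axis by `theta`; the
handedness of the rotation is not fixed by the physics described above, so
it is exposed as `rot_sign` (default: positive `theta` rotates from
circumferential toward apico-basal, counterclockwise seen from outside the
epicardium). Thin, coarsely resolved wall regions can yield a vanishing
transmural gradient; `build_frames()` treats this as an error by default
and can drop such cells (they then get the direction-averaged isotropic
conductivity), which is what the pipeline does — the affected cells are far
from any lesion.

## Electrical model

Charge conservation `div(sigma grad V) = 0` with the tip electrode at
`amplitude * (1 - 0.03)` (3% wire drop), the return bands at 0 V, and
zero normal current elsewhere. Myocardial conductivity is
`sigma_par f_E(E)` along the fiber and `sigma_perp f_E(E)` across it, with
`sigma_par = 0.5` S/m and `sigma_perp = sigma_par / 1.34 = 0.373` S/m by
the anisotropy-ratio formula (some sources round this to 0.375; a
`sigma_perp_override` is provided). The electroporation factor `f_E` is a
quintic smoothstep — the minimal polynomial with two continuous
derivatives — from 1 to `EF = 2.65` over the interval 300–800 V/cm
(centre 550, width 500); "centre" rather than "onset" is the reading
consistent with a symmetric smoothstep, and both numbers are configurable.
Scar is isotropic 1 S/m, blended linearly through the 40%/60%
intensity-threshold scar function. Blood is 0.7 S/m, bulk 0.38 S/m (a value calibrated upstream
against measured delivery currents; no current measurements ship here, so
it is used as-is).

The nonlinearity is resolved by Picard iteration with under-relaxation 0.5
on `f_E`, converged when the total current changes by less than 0.1%
(typically 7–9 iterations). Linear systems are solved with
Jacobi-preconditioned conjugate gradients, warm-started across Picard
iterations; discrete charge balance between the two electrodes holds to
machine precision because the only non-insulated boundaries are the
electrode node sets. The element field is the potential gradient at the
cell centre, consistent with the element-wise conductivity update.

## LET inversion

`volume_above()` integrates the myocardial volume with `E >= threshold`;
it is monotone nonincreasing in the threshold, so `estimate_let()` can
invert a measured lesion volume by bisection (bracket 50–3000 V/cm,
tolerance 1 V/cm — both documented defaults, spanning all reported
thresholds with margin). Only total volume is matched, not lesion shape.
The bracket and tolerance are this package's defaults; they are not
physical constants.
Per-dose medians use the standard middle / mean-of-middle-two convention
and the dose dependence is fitted as `log(LET) = log(a) + b log(N)` by
ordinary least squares — the natural objective for a power law.

## Thermal model

Energy balance `rho C (dT/dt + u . grad T) = div(k grad T) + Q` with
`Q = ONOFF * duty * sigma E^2`. Materials: myocardium 1081 kg/m³,
3686 J/(kg K), `k = 0.56 (1 + 0.0012 (T - 37))` W/(m K); blood
1050 / 3617 / 0.52; bulk 1027 / 2372 / 0.39; myocardial electrical
conductivity additionally carries `exp(0.015 (T - 37))`. Inflows enter at
37 °C, the outer boundary is insulated, initial temperature 37 °C.

Two deliberate design choices need explanation:

* **ON gating.** The heat source is gated on over each pulse train. The
  train of biphasic pulses lasts about 0.1 s (the ~2 s per-train delivery
  window is cardiac gating, not current flow), so `train_on_duration`
  defaults to 0.1 s with 2.5 s pauses, extended to 5 s after every fourth
  train.
* **Duty factor.** The fraction of the ON window during which current
  actually flows is a generator waveform parameter that is never published.
  An energy argument brackets it tightly: at the solved operating point
  (~21 A at 1455 V, ~30 kW instantaneous) a duty of a few per mille
  deposits the clinically plausible ~200 J per 16-train application,
  whereas duties of a few per cent would deposit kilojoules and drive the
  near-electrode tissue hundreds of kelvin above body temperature. Within
  that admissible decade the default (0.0042, i.e. ~0.42 ms of cumulative
  pulse time per train) was fixed once by matching the published
  depth-temperature maxima of the 16-train low-flow delivery; it is not
  revisited per run, and all damage volumes and exposure volumes are
  computed with it as genuine predictions.

Blood motion is the stationary fully developed laminar profile rather than
a Navier–Stokes solve: a parabolic axial profile in the LV scaled so the
cross-section average at the catheter level is 3 cm/s (low flow) or 9 cm/s
(high flow), tapering to a distributed outlet over the apical quarter, and
in the IVC the cross-section Poisson solution (no slip on wall and return
catheter, which is eccentric when pressed against the wall) scaled to
15 / 37 ml/s. For an unobstructed circular lumen this is exactly
Poiseuille flow (centreline = 2× mean).

Discretization: cell-centred finite volumes on the same grid, restricted to
a box around the heart and IVC (heat never reaches the far bulk); implicit
Euler diffusion at a 0.25 s base step with event steps at train boundaries
and four sub-steps inside each ON window, solved by conjugate gradients;
explicit first-order upwind advection sub-stepped to the CFL limit in its
advective (bounded) form, which tolerates the small divergence of the
constructed LV profile. The diffusion operator is rebuilt when `k(T)` has
drifted by more than 2 °C anywhere; the stationary field is re-solved at a
train start when the power-weighted temperature change implies a
total-current change above 1% (the bidirectional coupling contract).

Damage is scored two ways: the thermal dose (cumulative time at ≥ 55 °C
reaching 1 s — cumulative rather than contiguous, the conservative reading)
and the Arrhenius integral with `A = 2.94e39` 1/s and
`deltaE = 2.596e5` J/mol accumulated by the trapezoidal rule, with damage
at `Omega >= 1` (63% cell death). Probe traces are trilinear
interpolations of the cell-centred temperature at 1 / 3 / 7 mm below the
tip–tissue interface along the catheter axis.

## Electrogram analysis

QRS detection uses a slope-threshold detector (smoothed five-point slope,
adaptive threshold seeded from the first 3 s, 200 ms refractory) after a
10 Hz high-pass pre-filter; the first 50 samples are zeroed (and their
slopes ignored) so a segment-initial QRS cannot lock the adaptive
threshold. Per beat, the bipolar peak-to-peak amplitude is the max–min of
the raw bipolar channel in a 400 ms window starting 200 ms before the R
peak. The current of injury is the area under the unipolar ST segment —
from the QRS end (filtered envelope below 10% of the R amplitude for
40 ms) to the estimated T-wave onset (R + 0.25 × median RR, capped at
+350 ms) — relative to an isoelectric pre-QRS baseline (latest 50 ms span
with peak-to-peak below 0.1 mV ending at least 20 ms before the QRS
onset), divided by the window length so that T-onset uncertainty cancels
to first order. Both estimators are heuristics for quantities that published
descriptions of the measurement leave unspecified; their parameters are
exposed. Summaries
use non-overlapping 10 s windows (≥ 10 valid beats, ≤ 20% contaminated;
windows failing the contamination rule are labelled before the count rule),
unipolar windows within 30 s of the delivery are excluded by rule
(amplifier saturation), and timepoints are reported pre (median of
all pre-delivery windows — a documented choice; a single reference window
would also be defensible), 30 s, and 3.5 min post.

## Synthetic data and what passing tests show

The generators emulate the *statistical structure* of the study inputs,
not their full physiology: lesion volumes are forward isovolumes times
lognormal noise (`sigma_log = 0.15`, an assumption matching the wide
right-skewed spread of in vivo volumes); ECGs are P-QRS-T Gaussian
composites with RR jitter, band-limited noise, baseline drift and a
raised-cosine ST plateau decaying exponentially after the delivery;
scar maps are smooth parametric patches; projections are exact perspective
geometry plus pixel noise. Tests passing on these inputs demonstrate that
the algorithms are correct against their own ground truth — they do not
demonstrate robustness to real-world pathologies (ectopy, electrode motion,
MRI segmentation error, respiratory drift), which in practice is covered by
manual review of recordings and images.

## Numerical choices and limitations

* Voxel geometry: region classification by cell centres; watertightness and
  partition identities hold by construction. Electrode voxelisation is the
  dominant discretization error (see above); body-fitted meshing is out of
  scope.
* The apico-basal reference for fiber frames is global +z; near the apex it
  degenerates and a fixed fallback axis is used with a warning.
* Trilinear elements on strongly graded cells can overshoot the maximum
  principle by discretization error; the transmural coordinate is clipped
  to [0, 1].
* The LV flow profile is not exactly divergence-free at slice transitions;
  the advective upwind form keeps temperatures bounded regardless.
* Catheter thermal properties (polymer shaft, platinum-like electrode) are
  generic values — they only buffer heat locally and are not printed in the
  source model.
* Problem sizes: default field grid ~120k cells, exposure grid ~310k,
  coarse test grid ~33k; the full 16-train thermal history (51.6 s of
  physical time, ~310 stored steps) runs in a few minutes on one CPU.
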