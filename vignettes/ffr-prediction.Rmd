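---
title: "Model-based FFR prediction with guidewire effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based FFR prediction with guidewire effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrwire)
```

## Scope and idea

Fractional flow reserve (FFR) is measured invasively by threading a
0.36 mm pressure guidewire across a coronary stenosis under maximal
vasodilation and taking the ratio of cycle-averaged distal to aortic
pressure. Computational FFR pipelines usually model the vessel without
that wire. `ffrwire` implements a reduced-order version of the standard
prediction pipeline in which the wire can be switched on and off on the
identical anatomy, so its hemodynamic footprint on the prediction can be
isolated per lesion and summarised per severity class.

The deliberate fidelity trade-off is that the three-dimensional
Navier--Stokes problem is replaced by a zero-dimensional network: each
vessel segment carries a closed-form viscous resistance and each stenosis
a lumped empirical loss model. This keeps a full 24-lesion paired study
(96 pulsatile simulations plus the calibration runs) in the seconds
range on one CPU, at the price of not resolving velocity fields,
secondary flow or wall shear. Because FFR is a ratio of cycle-averaged
pressures, a loss-accurate network is the natural reduced model.

## The pipeline

For one tree and one patient, `ffr_model()` performs the calibration:

1. **Total baseline flow.** `q_cor = 0.045 CO`, with CO in L/min
   converted to mL/s. The fraction 0.045 is the conventional coronary
   share of cardiac output.
2. **Flow distribution.** Either Murray weights
   `fraction_k = d_k^m / sum d_j^m` on the outlet diameters (default
   exponent `m = 3`; 2.66 is also in circulation and any value in
   [2, 3] is accepted without complaint) or crown-length weights: each
   outlet in proportion to the summed length of segments distal to and
   including its terminal segment. For binary trees whose outlets are
   leaves, the crown is the terminal segment itself; the definition is
   written for general subtrees so deeper serialized anatomies are
   handled identically.
3. **Baseline steady solve (Scenario I).** Inlet pressure fixed at MAP,
   outlet flows prescribed. On a tree the segment flows are sums of
   distal outlet flows, so the solve is a single pressure march from the
   inlet; no iteration, exact to round-off.
4. **Peripheral resistance calibration.**
   `R_out,k = (p_out,k - p_v)/q_out,k` with venous reference
   `p_v = 5` mmHg, then `R_hyp = R_out / TCRI` with `TCRI = 3`, the
   hyperemic vasodilation factor. A baseline outlet pressure at or below
   `p_v` is rejected as unphysiological rather than silently producing a
   negative resistance.
5. **Windkessel closure.** Each outlet's hyperemic resistance splits
   into the coronary-bed elements as 0.01 (Ra), 0.84 (Ra-micro),
   0.15 (Rd); its compliance into 0.025 (Ca), 0.975 (Cmyo). The last
   element of each split is computed by difference so the totals are
   conserved exactly, not just to rounding. Per-outlet compliances are a
   coronary portion of the systemic arterial compliance of 1.7 mL/mmHg,
   distributed by Murray weights.
6. **Hyperemic pulsatile solve (Scenario II).** The inlet follows a
   scaled aortic waveform; the myocardial compliances are loaded by a
   scaled left-ventricular waveform, which reproduces the diastolic-
   dominant coronary flow pattern (systolic impediment). Cycles repeat
   until the cycle-mean distal pressure is periodic.
7. **FFR extraction.** `FFR = mean(p_d)/mean(p_a)` over the final cycle,
   with `p_d` sampled at a fixed distance distal to the lesion.

`predict(fit)` runs steps 6–7; `predict(fit, type = "steady")` solves the
steady analogue (outlets loaded by `Ra + Ra_micro + Rd` onto `p_v`),
which is the fast path used inside calibration sanity checks and agrees
closely with the pulsatile prediction because FFR averages over the
cycle.

## Segment hydraulics

A healthy segment of radius $r$ and length $L$ has Poiseuille resistance
$R = 8\mu L/(\pi r^4)$ with blood viscosity $\mu = 0.035$ g/(cm s) and
density $\rho = 1.05$ g/cm³; 1 mmHg = 1333.22 dyn/cm² is fixed in one
place. With the guidewire (radius $r_i$) present the lumen is a
concentric annulus and the exact closed form
$R = 8\mu L / \bigl(\pi [r^4 - r_i^4 - (r^2 - r_i^2)^2/\ln(r/r_i)]\bigr)$
applies; it reduces to Poiseuille at $r_i = 0$ and is verified in the
tests against numerical quadrature of the annular velocity profile.
Notably, even a thin centered wire roughly doubles the viscous
resistance of a 2 mm vessel — the logarithmic term, not the blocked
area, dominates.

A stenosis is parameterized by its fractional **area** reduction
`degree` $= 1 - A_s/A_0$ (the diameter convention is *not* used), a
throat length, and a fractional position along its segment. Its drop is
a Young--Tsai-type loss,
$$\Delta P = R_v q + K_t \frac{\rho}{2A_0^2}
  \Bigl(\frac{A_0}{A_s} - 1\Bigr)^2 q\,|q|,$$
with $R_v$ the viscous resistance of the throat (annular when wired, and
both areas reduced by the wire cross-section) and $K_t = 1.52$ the
classical empirical expansion-loss coefficient. The $q|q|$ form makes
the loss odd in the flow, so transient flow reversals are handled
consistently. Degree 1 (occlusion) is rejected, as is a wire wider than
the stenotic lumen ("wire does not fit").

## Numerical scheme

The pulsatile solver (C++ kernel) advances with $\Delta t = 1$ ms. Per
step, the algebraic tree network and the Windkessel ODEs are coupled by
fixed-point iteration until self-consistent (tolerance $10^{-10}$ mmHg
on the bed pressures, at most 12 passes — two or three suffice in
practice):

* the network is solved by damped Newton on the outlet flows (residual
  tolerance $10^{-8}$ mmHg), marching pressures from the inlet;
* each bed advances by a trapezoidal (Crank--Nicolson) step, solved in
  closed form as a 2×2 linear system, with the left-ventricular pressure
  increment applied exactly.

The combined step is A-stable and second-order; halving $\Delta t$
moves FFR at the $10^{-5}$ level, comfortably inside the $10^{-3}$
robustness bound the tests assert. States are initialised from the
steady hyperemic solution, so periodicity (relative change of the
cycle-mean distal pressure below $10^{-3}$) is typically reached in two
to three cycles, with a hard cap of 10 cycles after which the result is
returned flagged `converged = FALSE` with a warning — never silently.
An earlier operator-splitting variant (backward Euler with frozen
coupling) was first-order and left a visible $\sim 2\times10^{-3}$ FFR
bias at 1 ms, which motivated the coupled trapezoidal design.

The measurement pressure is interpolated along its segment: the
distributed viscous drop scales with arc length and the stenosis lump is
included once the sampling point lies distal to it.

## The synthetic generator and the study design

Real anatomies are CCTA segmentations and are not reproducible here; the
generator emulates the features that drive the pipeline:

* **Topology/radii.** Binary trees, default 3 generations, root radius
  0.15 cm (proximal coronary calibre). Bifurcation radii satisfy
  Murray's cube law exactly; the daughter asymmetry ratio is drawn from
  Uniform(0.5, 0.8), i.e. a dominant continuing trunk with smaller side
  branches, as in epicardial arteries. A useful consequence of exact
  cube-law trees with Murray flow splitting is uniform wall shear: the
  per-segment pressure drop per unit length-to-radius ratio is the same
  everywhere, so the tree's total loss is controlled by the length
  ratios alone.
* **Lengths.** Segment length-to-radius ratios are Uniform(4, 8):
  sub-centimeter inter-branch segments at coronary calibres, which
  keeps the lossless (degree-zero) hyperemic tree near-unity FFR as a
  healthy epicardial pathway should be, and leaves headroom for the
  least severe calibration targets.
* **Lesions.** One stenosis per tree on the larger first-generation
  daughter (the analogue of a proximal/mid main-branch lesion), throat
  0.3 cm at mid-segment; the distal pressure is sampled 2.5 cm
  downstream of it (midpoint of the clinical 2–3 cm convention),
  clipped to the branch end, following the larger-radius child at
  bifurcations.
* **Calibration.** The default cohort uses the 24 packaged invasive FFR
  measurements as targets, paired with their real patients (MAP, CO),
  giving six lesions per severity class by construction. Stenosis
  degree is found by bisection — the predicted FFR is strictly
  decreasing in degree, a property the tests assert — until the
  wire-absent pulsatile prediction is within ±0.01 of the target
  (inner acceptance at half that, ±0.005, so the contract holds with
  margin). Trees whose lossless FFR cannot reach a mild target are
  redrawn deterministically (up to 20 attempts) before the generator
  fails with the class and seed named. Because targets equal the
  invasive values, the diagnostic indices of the wire-absent model on
  this cohort are near-perfect by construction; they exercise the
  statistics machinery and show the wire's effect on them, but say
  nothing about real predictive accuracy.
* **Other sizes.** For `n_per_class != 6`, targets are drawn uniformly
  inside each class interval (kept 0.01 away from the boundaries, and
  capped at 0.95 in the top class to stay below the lossless tree's
  FFR), cycling through the patient table.

What the generator does **not** emulate: vessel taper and continuous
side-branch loss, curvature and eccentric wire position, dominance-
dependent topology (dominance is carried as metadata only), patient-
specific waveform shapes, and any imaging-derived myocardial mass. Tests
passing on this cohort therefore validate the pipeline's mechanics and
its qualitative severity trends, not agreement with any particular
patient population.

## Waveforms

The normalized driving shapes are analytic stand-ins: the aortic wave is
a three-harmonic profile with a systolic peak and a dicrotic-notch-like
secondary deflection; the ventricular wave a squared half-sine over a
0.35 systolic fraction, zero in diastole. Both are exactly periodic on
the closed phase grid. The aortic wave is affinely scaled to the
patient's MAP (cycle mean) and pulse pressure (range); the LV wave is
scaled to a systolic peak of MAP + pulse/2, a proxy the data do not pin
down (only MAP is tabulated). Since FFR is a ratio of cycle means and
the beds are linear, the shape details matter little — the time step
and steady-mode consistency checks in the test suite quantify exactly
how little. Cycle duration (0.8 s) and pulse pressure (40 mmHg) are
population defaults, overridable per patient.

## Study conventions

* **Severity classes.** Class 1 `FFR <= 0.52`, class 2 `(0.52, 0.72)`,
  class 3 `[0.72, 0.84)`, class 4 `>= 0.84`. The boundary convention is
  the unique assignment placing exactly six of the 24 packaged
  measurements in each class; `classify_ffr()` documents and enforces it.
* **Wire extent.** The wire is modelled along the stenotic branch: from
  the lesion segment through the measurement segment, matching the
  clinical geometry the model represents (the sensor sits distal to the
  lesion, the wire crosses it). An `inlet_to_measurement` option threads
  it from the ostium instead; both are exposed in the configuration.
* **Paired runs.** Each wire state runs the *full* pipeline, baseline
  included, on the identical tree — the wire alters the baseline outlet
  pressures and hence the calibrated peripheral resistances, exactly as
  re-running a segmentation-to-FFR pipeline on a wire-included geometry
  would.
* **Percent changes** are relative to the wire-absent value:
  `100 (FFR - gFFR)/FFR`, `100 (dP_wire - dP_abs)/dP_abs`,
  `100 (q_abs - q_wire)/q_abs`, lesions weighted equally, class
  membership by invasive FFR when available.
* **Diagnostics.** Positivity is `FFR <= 0.8` (the comparator the
  figures use; the exposed `cutoff` lets a strict inequality be
  emulated by nudging the cutoff). Zero-denominator indices are
  reported missing rather than coerced. Bland--Altman differences
  default to `invasive - predicted` and the direction is carried in
  the output, since both conventions appear in the literature. ROC AUC
  sweeps the prediction cut-point over all distinct values with
  trapezoidal integration, which equals pairwise concordance with ties
  counted one half — the tests verify that identity exhaustively and
  against an independent ROC implementation.

## Problem sizes

The shipped tests and the acceptance script use 3-generation trees
(7 segments, 4 outlets), 1 ms steps over 0.8 s cycles, the 24-lesion
default cohort, and both flow setups — 96 paired pulsatile simulations
plus bisection calibration, which completes in well under a minute on a
single CPU. Deeper trees and finer steps only change run time; every
size is a configuration value.

## Known limitations

Rigid walls (no compliance in the tree itself), concentric and static
wire, laminar Newtonian rheology inside a lumped loss model, no
patient-specific TCRI, and a stenosis model whose constants ($K_t$,
throat-length convention) are empirical: absolute pressure-drop
percentages depend on them, which is why the package's own verification
leans on orderings, invariants and oracle equivalences rather than on
exact loss values. The guidewire's effect is therefore best read
comparatively — wire-included versus wire-absent on the same tree —
which is the quantity the study design isolates.
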