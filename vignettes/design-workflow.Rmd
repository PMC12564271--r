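---
title: "Designing a stepped microfluidic channel for carotid-like wall shear stress"
author: "stepwss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a stepped microfluidic channel for carotid-like wall shear stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stepwss)
```

## The design problem

At the carotid bifurcation, two wall-shear-stress (WSS) regimes coexist:
the stenosed carotid sinus sees *low oscillatory* WSS (OWSS) — small in
magnitude, reversing sign over the cardiac cycle — while the healthy
downstream segment sees *high pulsatile* WSS (PWSS), strictly positive with
a systolic peak. Low OWSS is the regime associated with endothelial
dysfunction and atherosclerotic plaque formation, so in-vitro models that
reproduce **both** regimes in one device are valuable for mechanobiology.

`stepwss` implements a design-by-simulation workflow for such a device: a
variable cross-section microfluidic chamber consisting of a narrow part I
(width $b_1$, height $h_1$) carrying a backward-facing floor step of height
$h_3$, a transition, and a wide part II (width $b_2$, height $h_2$). The
step sheds a recirculation vortex that produces OWSS on the floor just
downstream of the step face; the wide section downstream behaves as a
parallel-plate chamber and produces PWSS. The step dimensions are chosen by
sweeping $b_1$ and $h_3$ and scoring each candidate by the root mean square
error (RMSE) between the simulated wall WSS at five observation points in
the vortex region and the target OWSS waveform, with an acceptance
threshold of 0.15 on the point-averaged RMSE.

## Model

The fluid (water-like culture medium, $\mu = 10^{-3}$ Pa·s,
$\rho = 1000$ kg/m³) is incompressible and Newtonian, governed by the
Navier–Stokes and continuity equations with a uniform-velocity inlet,
no-slip walls, and zero outlet pressure. Two closed-form results anchor the
pipeline:

* the parallel-plate wall shear of the wide section,
  $\tau_{w2}(t) = 6\mu Q(t)/(b_2 h_2^2)$, inverted to obtain the flow-rate
  waveform $Q(t)$ that realizes a prescribed PWSS target
  (`flow_rate_from_pwss()`);
* the wall shear definition $\tau_{w1} = \mu\,\partial u/\partial y$ at the
  floor, extracted from the computed velocity field
  (`wall_shear_bottom()`).

### 2-D mid-plane reduction

The chamber is flat ($b/h \ge 13$ everywhere), so the mid-plane ($x$–$y$)
flow is quasi-planar. The solver therefore works on the 2-D mid-plane
profile, with the width entering through the per-width flow rate
$q = Q/b_1$ in part I. Part II fidelity is assessed by scaling the solved
downstream per-width WSS by $b_1/b_2$, which is the exact width conversion
for the same $Q$. This reduction reproduces the two width dependencies that
drive the design (velocity $\propto 1/b_1$ in the step region, flow rate
$\propto b_2$ at fixed PWSS target) at desk-scale cost. What it does not
capture: sidewall boundary layers and any three-dimensional vortical
structure near the channel edges; conclusions hold on the mid-axis, which
is where observation points are placed.

### Discretization

A staggered (MAC) finite-difference grid with exact discrete mass
conservation: $u$ on vertical faces, $v$ on horizontal faces, $p$ at cell
centers. The coupled momentum–continuity saddle-point system is solved by a
sparse direct LU factorization (`Matrix`). Walls falling half a cell from a
velocity node use non-uniform three-point stencils through the no-slip
value, so quadratic (plane Poiseuille) profiles are differentiated and
solved exactly; the leading straight-channel WSS error is the $O(dy^2)$
midpoint quadrature of the flux profile (~0.5 % at default resolution,
observed convergence order 2.0, `wss_convergence_study()`).

The convective term is retained but Picard-lagged: it is evaluated on the
previous iterate and moved to the right-hand side, so the matrix is
constant and factorized **once per grid**, then reused across Picard
iterations, time samples and sweep candidates sharing a step height. Aitken
dynamic relaxation (initial factor 0.7, clamped to $[0.05, 1]$) keeps the
fixed-point iteration convergent up to the peak-flow Reynolds numbers of
the device (Re ≈ 14 for the narrowest step width); convergence is declared
at a relative velocity change of $10^{-8}$. A pure-Stokes mode
(`include_convection = FALSE`) is available; note that the flow-rate
dependence of the vortex size — the mechanism that makes the near-wall WSS
oscillatory — is a convective (finite-Re) effect and disappears in that
mode.

### Time dependence

The Womersley number is $\alpha = (h_2/2)\sqrt{2\pi\rho/(T\mu)} \approx
0.21$ for the default period $T = 0.8$ s, so pulsatile inertia is
negligible and the default mode is **quasi-steady**: one steady solve per
0.01 s sample of $Q(t)$, warm-started from the previous sample. A
semi-implicit **unsteady** mode (implicit viscous/pressure, explicit
convection with automatic advective-CFL sub-stepping, integrated from rest
over two cycles) serves as the regime check: its uniform-section WSS agrees
with the quasi-steady series to 0.5 % and reaches a limit cycle within one
period (periods 2 and 3 agree to $10^{-12}$).

## Synthetic target waveforms

The in-vivo targets came from a patient-specific carotid simulation driven
by ultrasound-Doppler velocimetry and are not published as data; `stepwss`
generates synthetic stand-ins (they emulate the waveform class, not the
patient):

* `make_pwss_target()` — truncated Fourier series (8 harmonics) of a von
  Mises systolic pulse, period 0.8 s, cycle mean 0.5 Pa, peak 1.5 Pa at
  $t_p = 0.11$ s, strictly positive, sampled at the solver step
  $dt = 0.01$ s. The sampled cycle mean equals the requested mean exactly
  (discrete Fourier orthogonality), and scaling mean and amplitude scales
  every sample linearly.
* `make_owss_target()` — the same construction inverted (negative excursion
  at systole, concentration 3 for the broader reversal of a stenosed
  sinus), mean −0.02 Pa, excursion amplitude 0.1 Pa, guaranteed to cross
  zero at least twice per cycle.

The cardiac period is not printed in the source description of the device;
0.8 s is adopted (consistent with a systolic peak at 0.11 s early in the
cycle) and configurable. With these amplitudes the peak part II Reynolds
number is ≈ 5.6 — the solver reports Re and $\alpha$ as diagnostics
(`flow_diagnostics()`) rather than asserting a regime.

### Calibrating the OWSS target

In the original workflow the OWSS target is *achievable by construction*
(it was extracted from the same carotid model that defined the PWSS
target). The synthetic analogue, `calibrate_owss_target()`, simulates the
reference design (step 0.06 mm × 4 mm, $b_2 = 5$ mm), averages the wall-WSS
series over the five vortex-region points, and truncates it to 8 Fourier
harmonics. This yields a sign-reversing target on the WSS scale the device
can actually produce (calibrated mean ≈ 0.023 Pa, amplitude ≈ 0.15 Pa with
the defaults), recorded in the `"calibration"` attribute. Calibrating
against the accepted design—rather than, say, a mid-sweep candidate—is
deliberate: it reproduces the original situation in which the target was
matchable by the optimal channel, so the sweep's job is to rediscover that
optimum from the physics, which it does.

## Observation points

The wall WSS is evaluated on the floor of the 14–17 mm band downstream of
the step face at $x = 14$ mm. Within the creeping-to-moderate-Re regime of
this device, the recirculation bubble behind a 0.03–0.09 mm step is tens of
micrometres long: for the reference geometry the reattachment point sweeps
$x \in [14.029, 14.043]$ mm as the flow rate traverses the cardiac cycle.
Only inside that excursion band does the wall WSS change sign over the
cycle, so the five vortex-region points default to
$x_{1\text{–}5} = \{14.032, 14.034, 14.036, 14.038, 14.040\}$ mm — centered
in the band, inside the vortex region. Points placed far outside the bubble
(e.g. spread over the full 14–17 mm band) would see redeveloped, strictly
positive Poiseuille WSS and could not discriminate the candidates. The five
part II points default to $x_{6\text{–}10} = \{18, \dots, 22\}$ mm on the
wide-section floor. Both sets are configurable (`observation_set()`).

## Vortex characterization

"Vortex area" is made operational via the separating streamline: the
streamfunction is integrated from the floor ($\psi = 0$ on it), and the
recirculation bubble is the connected set of cells with cell-averaged
$\psi < 0$ downstream of the step, seeded at the $\psi$ minimum (the vortex
core). The reported metrics are the summed cell area, the core location,
and the reattachment length (distance from the step face to the last
sign change of the wall WSS, interpolated between faces). Reversed-flow
cells ($u < 0$) are the existence cross-check; absence of a vortex is a
valid result, not an error.

## The sweep

`sweep_optimize()` evaluates every combination of
$b_1 \in \{2, 3, 4\}$ mm, $h_3 \in \{0.03, 0.06, 0.09\}$ mm and
$b_2 \in \{5, 4\}$ mm (the increments of the original manual loop,
automated exhaustively; `early_stop = TRUE` reproduces the
stop-at-first-acceptance behaviour). Candidates are ranked by ascending
average RMSE with deterministic tie-breaks (smaller $h_3$, then smaller
$b_1$); the whole pipeline is free of randomness, so identical
configurations give bitwise-identical reports. RMSE is computed on signed
WSS in Pa over one cycle (a normalized variant is exposed via
`rmse(..., normalized = TRUE)`); the 0.15 threshold is interpreted in Pa,
the scale on which the achieved RMSEs (~0.02–0.36) and the reported
"around 0.1" naturally live.

With the default targets the sweep finds, at $b_2 = 5$ mm:

* vortex area non-increasing in $b_1$, non-decreasing in $h_3$, smaller at
  the mean-flow instant $t_m = 0.16$ s than at the peak $t_p = 0.11$ s, and
  smaller throughout at $b_2 = 4$ mm — the four qualitative trends of the
  design study;
* near-disappearance of the vortex at $(h_3, b_1) = (0.03, 4)$ mm (≈ 5 % of
  the largest vortex in the sweep);
* best candidate $(b_1, h_3) = (4, 0.06)$ mm with average RMSE ≈ 0.02 Pa,
  well under the 0.15 acceptance bound, while the part II WSS tracks the
  PWSS target to 0.02 % normalized RMSE.

## Numerical choices and problem sizes

* Default grid: 5 µm vertical cells (30 across $h_2$; at least 6 across any
  admissible step), streamwise 0.25 mm cells graded (ratio ≤ 1.3) into a
  2.5 µm uniform window over $x \in [13.5, 14.5]$ mm bracketing the step —
  about 16 000 cells, 37 000 unknowns, one ~1.4 s factorization per step
  height. A full 9-candidate sweep runs in about two minutes on one core.
* The test suite uses two documented reduced resolutions (20 µm and 5 µm
  step-window cells) chosen so every asserted property is resolution-stable.
* Step rasterization is half-open by cell center, with the step face
  snapped to the nearest grid face; the discrete fluid area matches the
  mid-plane polygon to within one cell.
* Degenerate inputs: $h_3 = 0$ is a valid step-free channel (no solid
  cells, no vortex); $q = 0$ returns the exact zero field; a step resolved
  by fewer than 6 cells is refused rather than silently under-resolved.
* Part I height follows the step as $h_1 = h_2 - h_3$, reading the step as
  a backward-facing drop from the part I floor to the part II floor — the
  reading consistent with observation points "downstream of the step" at
  $y = -h_2$. Lengths not fixed by the device description default to
  $L_1 = 13.5$, $L_{trans} = 1$, $L_2 = 10$, $x_{step} = 14$ mm.

## Limitations

* The synthetic targets emulate carotid waveform *classes*; agreement with
  any specific patient's waveform is out of scope, and all acceptance
  checks are against the synthetic targets and the device's own physics.
* The 2-D mid-plane model omits sidewall effects; the circular inlet and
  outlet ports enter only as boundary conditions (`inlet_signal_from_flow()`
  provides the port-velocity conversion for the 3-D plumbing).
* The re-entrant step corner is a weak singularity: local quantities within
  a cell or two of the corner converge at reduced order, which is why the
  observation points and the convergence oracle avoid the corner itself.
* The sweep is exhaustive over the printed candidate grid, not a general
  optimizer; surrogate- or gradient-based search is intentionally out of
  scope.
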