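---
title: "Shear-driven VWF unfolding: model, criteria, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-driven VWF unfolding: model, criteria, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwfdyn)
```

## The physical picture

von Willebrand factor (VWF) is a multimeric plasma glycoprotein that mediates
shear-induced platelet activation: under strong flow its globular conformation
stretches out, exposing A1 domains that engage platelet GPIb receptors.  In
steady flow this happens above a well-defined shear stress; in stenotic
vessels and blood-wetted devices, however, platelets see *brief, intense*
shear transients, and whether a transient activates depends jointly on its
amplitude and duration.  The classical summary of this joint dependence is
the cumulative shear stress (CSS), the time integral of shear along a
platelet trajectory, compared against a threshold CSS~0~.

`vwfdyn` implements a mechanical model that derives that threshold instead of
postulating it.  A multimer of `N` subunits of size `d`, grafted on the
platelet surface, is described by a single conformational coordinate

$$q = (2r/d)^7,$$

where `r` is the radius of the still-globular part.  The fully folded state
sits at $q_m = (3N/2)^{7/3}$; complete unfolding is $q = 0$.  The observable
order parameter is the degree of unfolding $u = 1 - (q/q_m)^{3/7} \in [0,1]$,
the unfolded tail length over the contour length $L = N d$.  Balancing the
shear-driven unfolding moment against the refolding moment from the effective
surface tension of the globule gives a conservative, dimensionless equation
of motion

$$\ddot q \;=\; -\tilde\tau(\tilde t)\, q^{3/7} + q^{1/7} - 1,$$

with dimensionless shear $\tilde\tau = k\tau d/4\sigma$ and time
$\tilde t = t/\sqrt{4 m_0/15\sigma\pi}$.  Equivalently, the coordinate moves
in the potential

$$\tilde U_{\tilde\tau}(q) = \tfrac{7}{10}\tilde\tau\, q^{10/7}
  - \tfrac{7}{8} q^{8/7} + q .$$

There is no damping term: the model asks whether an impulse imparts enough
momentum to carry the molecule over the landscape barrier, and for that
question conservative dynamics is the clean idealization.

## Landscape, regimes, bifurcation

Stationary points of the potential solve, after the substitution
$s = q^{1/7}$, the cubic $\tilde\tau s^3 - s + 1 = 0$.  Three regimes follow
(`landscape_at()`, `bifurcation_diagram()`):

* **Folded-bistable** ($\tilde\tau < \tilde\tau_*$): minima at $q = 0$ and at
  the folded wall $q_m$, separated by a barrier; at zero shear the barrier is
  the saddle $q_s = 1$ exactly, with $\tilde U_0(1) = 1/8$.
* **Partial-bistable** ($\tilde\tau_* < \tilde\tau < \tilde\tau_c$): an
  interior, partially unfolded minimum detaches from the wall at
  $\tilde\tau_* = ((3N/2)^{1/3}-1)/(3N/2)$.
* **Monostable-unfolded** ($\tilde\tau > \tilde\tau_c$): barrier and interior
  minimum merge in a fold catastrophe at $\tilde\tau_c = 4/27$ — independent
  of `N`, because the double root of the cubic sits at $s = 3/2$.

The totally unfolded state is a minimum at *every* shear: a molecule that
ever reaches $q = 0$ stays unfolded under any later quasistatic shear
history, which is what makes complete unfolding the natural activation
criterion.

```{r landscape}
p <- vwf_multimer(36)
glance(landscape_at(0.1, p))
c(tau_star = tau_star(p), tau_c = tau_c(p), tau_hash = tau_threshold(p))
```

## Activation criteria

For a molecule starting folded and at rest, complete unfolding is decided in
phase space: the trajectory must cross the zero-shear separatrix through the
saddle.  Three nested criteria are implemented (`classify_profile()`):

* **Momentum sufficient condition**: exit momentum
  $\dot q_{out} < 0$ with $|\dot q_{out}| > |\dot q_A| =
  \sqrt{2(\tilde U_0(1)-\tilde U_0(q_m))}$ guarantees unfolding.
* **Ground truth**: direct integration of the equation of motion; the verdict
  is origin contact during the profile, or the exact energy form of the
  separatrix test at switch-off ($\dot q < 0$ and
  $E_0 > \tilde U_0(1)$, with the sub-saddle cases handled exactly).
* **CSS necessary condition**: bounding the shear coupling $q^{3/7}$ by its
  folded-state value $q_m^{3/7} = 3N/2$ turns the momentum condition into
  $\int \tilde\tau\, d\tilde t > CSS_0(N)$ with the closed form
  $$CSS_0(N) = (3N/2)^{1/3}\sqrt{\tfrac74 + \tfrac14 (3N/2)^{-8/3}
    - 2 (3N/2)^{-1/3}},$$
  an increasing function of `N`: larger multimers need a stronger impact.

For rectangular impulses of amplitude $\tilde\tau_m$ the package computes the
critical duration $\tilde t_F(\tilde\tau_m)$ (`critical_duration()`,
`critical_curve()`).  The curve lies above the hyperbola
$\tilde\tau_m \tilde t_F = CSS_0$, converges onto it in the impulsive limit,
and has a vertical asymptote at the amplitude $\tilde\tau_\#$
(`tau_threshold()`) where the from-rest energy of the folded state equals the
barrier energy — below it no impulse of any duration unfolds the molecule.
Because the model is conservative this asymptote is sharp and is computed
from the energy equality, not from long simulations.

```{r criteria}
css0(p)
classify_profile(shear_rectangular(10, 1), p) |> glance()
```

## Numerical design choices

* **Stationarity as a cubic.**  Critical points are found as roots of
  $\tilde\tau s^3 - s + 1$ in $s = q^{1/7}$ (`polyroot()` plus a Newton
  polish, skipped near the degenerate fold), never by bracketing fractional
  powers in `q`; at $\tilde\tau = 0$ the barrier is pinned to the saddle
  value 1 rather than extracted from the degenerate cubic.
* **Integrator.**  LSODAR (via deSolve) with boundary roots at $q = 0$ and
  $q = q_m$; integration is split at the waveform's non-smooth points so
  switch-on/off times are hit exactly, which in turn makes the separatrix
  test at switch-off exact.  Default tolerances are
  `rtol = atol = 1e-9`: momenta of order $10^2$–$10^3$ and energies of order
  $10^4$ must be resolved against a saddle energy of $1/8$.  A fixed-step
  velocity-Verlet mode exists solely to audit energy drift.
* **Boundary events.**  Contact states are re-integrated over the last
  inter-sample span at `1e-12` tolerance (the root-time interpolant of
  LSODAR is an order coarser than its regular output) and then snapped onto
  the boundary with the residual potential folded into the momentum, so
  contacts are energy-consistent to the integrator's precision.  Default
  boundary: absorbing (`restitution = 0`) at the origin — an unfolded
  molecule stays unfolded — and a sticky wall at $q_m$, where the landscape
  presses the folded molecule until the shear exceeds the detachment value.
  The activation verdict is fixed at first origin contact, so it does not
  depend on the restitution coefficient.
* **The origin is non-Lipschitz.**  The force term $q^{1/7}$ has infinite
  slope at $q = 0$, which defeats polynomial steppers restarted exactly at
  the origin after an elastic bounce.  Freshly bounced states are therefore
  carried out of that zone analytically, by energy quadrature at frozen
  shear — exact on constant-shear stretches and asymptotically exact in
  general, because the shear coupling $q^{3/7}$ vanishes at the origin.
* **Critical duration by event location.**  Along the constant-shear
  trajectory from rest, the free-motion energy
  $E_0 = \dot q^2/2 + \tilde U_0(q)$ is monotone on the inward leg
  ($dE_0/d\tilde t = -\tilde\tau q^{3/7}\dot q \ge 0$ while $\dot q \le 0$),
  so $\tilde t_F$ is the first root of $E_0 - \tilde U_0(1)$ and is located
  by the integrator's root finder in a single integration, rather than by
  bisection over impulse durations with repeated simulations.  Amplitudes at
  or below $\tilde\tau_\#$ return `Inf` without integrating.
* **Raw dimensionless durations.**  Critical durations are reported in the
  model's own time unit.  No characteristic-time normalization is applied;
  users with a preferred unit can rescale through
  `time_from_dimensionless()`.
* **No default physical constants.**  The model's source provides no numeric
  values of `k`, `d`, `sigma`, `m0`, so the package refuses to invent them:
  all core computation is dimensionless, and `calibrate_stress_scale()` is
  documented as a convenience heuristic that pins the fold catastrophe
  $\tilde\tau_c = 4/27$ to a user-supplied steady activation stress (80
  dyn/cm² gives a stress scale of 540 dyn/cm²).

## What the waveform generator emulates — and what it does not

The analytic waveforms (rectangular, trapezoid, half-sine, truncated
Gaussian) are idealized stenosis-transit shear histories: single, smooth
(or piecewise-constant) pulses with finite support and exact areas.  Sampled
CSV profiles interpolate CFD exports piecewise-linearly, which is monotone,
non-negativity-preserving, and exactly integrable; CFD trajectories are
typically sampled densely enough that spline accuracy would buy nothing at
the cost of overshoot risk.  The randomized profiles used in the tests draw
amplitudes log-uniformly over 0.02–8 and durations over 0.05–100 (in
dimensionless units), spanning the parametric and the impulsive regime
around `N = 36`, the multimer size used throughout the worked examples.

Real near-wall shear histories differ in ways the generator deliberately
omits: measurement noise, multiple peaks per transit, turbulent fluctuation,
and thermal agitation of the molecule itself.  Passing tests therefore
certify the mechanics of the model and the correctness of its thresholds and
integrator — not that any particular in vivo trajectory is classified
correctly.

## Problem sizes used in the test suite

The structural checks sweep `N` over 3–100 (and 3–1000 for the threshold
identity); dynamical checks run single trajectories over dimensionless spans
of order 10–2500 with a few hundred reported samples, and the randomized
criteria check classifies 200 profiles.  These sizes keep every property in
its asymptotic regime while the whole suite remains a desk-scale computation.

## Known limitations

* Dissipative relaxation after an impulse is outside the model: a molecule
  that fails to unfold keeps oscillating forever instead of settling into a
  minimum.  Verdicts are unaffected (they are fixed by energy), but
  post-impulse trajectories should not be read as relaxation dynamics.
* Thermal noise is absent, so the thresholds are sharp rather than
  probabilistic; near-threshold impulses in reality would activate with some
  probability rather than deterministically.
* Applicability to turbulent flow is an open question of the underlying
  model; the package only consumes laminar trajectory histories.
* Multimers with fewer than three subunits are rejected: below that size the
  fold point can leave the physical domain and the three-regime landscape
  degenerates.
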