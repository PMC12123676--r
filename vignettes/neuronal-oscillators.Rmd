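---
title: "Methods: planar neuronal oscillators, Hopf boundaries and relaxation periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar neuronal oscillators, Hopf boundaries and relaxation periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nosc)
```

# The models

`nosc` analyzes planar oscillator circuits of the form
$\dot u = F(u, x)$, $\dot x = G(u, x)$, where $u$ is a voltage and $x$ a
single internal state. Two concrete systems are implemented.

**FitzHugh–Nagumo (FHN) circuit.** A cubic fast branch and an inductive
recovery branch:
$$\dot u = \frac{1}{\tau_0}\Big(u - \frac{u^3}{3}\Big) + \frac{I_0 - x}{C_0},
\qquad
\dot x = \frac{u}{\tau_L R_a} - \frac{x}{\tau_L},$$
with $\tau_0 = R_0 C_0$, $\tau_L = L_a/R_a$ and the bifurcation ratios
$\epsilon = \tau_0/\tau_L$ and $r_{0a} = R_0/R_a$. The stationary curve is
$I_0(u) = (u^3/3 - u)/R_0 + u/R_a$ (N-type: multivalued in current; the
negative-resistance segment is hidden in the summed curve when
$r_{0a} > 1$). Here $u$ is the *fast* variable.

**S-type NDR oscillator.** A memristor-like element whose conductance is
set by an internal state,
$$\dot u = \frac{1}{C_0}\big(I_0 - g(x)\,u\big), \qquad
\dot x = \frac{1}{\tau_k}\big(g(x)\,u - x\big),$$
with the cubic-characteristic conductance
$g(x) = 1/\big(a(x^2 - 3bx + 3b^2) - c\big)$, so the stationary
current–voltage curve is $u(I) = a\big((I-b)^3 + b^3\big) - cI$ (S-type:
multivalued in voltage). The relaxation equation for $x$ plays the role of
a *chemical inductor*: no physical inductor is needed. At constant voltage
the drive current is $I_0 = (V_a - u)/R_0$, which replaces the first
equation by
$\dot u = \frac{1}{C_0}\big(V_a/R_0 - (1/R_0 + g(x))u\big)$.
Here the roles are reversed: $x$ is fast ($\tau_k$ small), $u$ is slow.

The conductance form is the *reciprocal* reading of the cubic model — the
only reading under which $u(x)\,g(x) = x$ holds identically along the
$\dot x = 0$ nullcline; the package asserts this identity in its tests.
The conductance denominator must stay positive; `stype_g()` raises an
error outside that domain rather than clamping, because silent clamping
would corrupt the period integrals. For all parameter sets used by the
presets the denominator is positive for every real $x$.

# Stability and Hopf boundaries

At a stationary point the Jacobian $J$, its trace $T_\lambda$ and
determinant $\Delta_\lambda$ classify the dynamics through
$\lambda_\pm = \tfrac12\big(T_\lambda \pm \sqrt{T_\lambda^2 -
4\Delta_\lambda}\big)$: saddle ($\Delta_\lambda < 0$), stable/unstable
node or focus, and the non-hyperbolic Hopf point at $T_\lambda = 0$,
$\Delta_\lambda > 0$. The zero test for the trace is scale-aware
($|T_\lambda| < 10^{-9}\max(|F_u|, |G_x|)$); a vanishing determinant is
reported as its own `degenerate` class rather than being folded into
`saddle`.

Closed forms implemented and cross-checked against finite differences:

* constant current: $T_\lambda = -g/C_0 + (g'u - 1)/\tau_k$,
  $\Delta_\lambda = g/(C_0\tau_k) > 0$ always — no saddle can occur, and
  oscillation onset is purely a Hopf bifurcation at
  $C_{0B} = \tau_k\, g/(g'u - 1)$, defined only on the NDR branch
  ($g'u > 1$, i.e. between the folds $I_{F1,2} = b \pm \sqrt{c/3a}$);
* constant voltage: $T_\lambda = -(1/R_0 + g)/C_0 + (g'u-1)/\tau_k$,
  $\Delta_\lambda = (1 - g'u + gR_0)/(R_0C_0\tau_k)$, with
  $C_{0B} = \frac{\tau_k}{R_0}\frac{gR_0 + 1}{g'u - 1}$ and the critical
  ratio $\epsilon_B = (g'u-1)/(gR_0+1)$ for $\epsilon = \tau_k/(R_0C_0)$;
  in the singular limit $\epsilon \to 0$ the oscillation window in $R_0$
  is bounded by the load lines through the fold points,
  $R_{0H} = (V_a - u(I_F))/I_F$;
* FHN: $T_\lambda = (1 - u^2 - \epsilon)/\tau_0$, Hopf voltages
  $u_{\mathrm{Hopf}} = \pm\sqrt{1-\epsilon}$, window closing at
  $\epsilon_B = 1 - \bar u^2$.

Note the opposite roles of the capacitor: the S-type oscillator needs
$C_0 > C_{0B}$ (large capacitance), the FHN circuit needs small $C_0$
(small $\epsilon$). This sign reversal is asserted by tests sampling both
sides of each boundary. The stable/unstable character of the emerging
limit cycle is distinguished only by the crossing direction of
$T_\lambda$ (the package does not compute Lyapunov coefficients).

# Frequencies

Near the Hopf boundary the oscillation is harmonic with
$\omega_0 = \sqrt{\Delta_\lambda}$ (at constant current
$\omega_0 = \sqrt{g/(C_0\tau_k)}$, at the boundary
$\omega_{0H} = \sqrt{g'u - 1}/\tau_k$). `harmonic_solution()` returns the
amplitude ratio $A_0/a_0 = \sqrt{g^2/C_0^2 + g/(C_0\tau_k)}$ and the
phase angle $\phi = \arctan(\omega_0 C_0/g) \in (0, \pi/2)$ between $u$
and $x$. One convention note: the mode that literally satisfies the
linearized system carries phase $\phi + \pi$ (equivalently, a sign flip
of the free amplitude $a_0$); the reported $\phi$ is the magnitude of the
$u$–$x$ phase angle, which is what the formula above states. The test
suite verifies the linearized residual with the consistent convention.

Far above $C_{0B}$ the cycle becomes a relaxation oscillation: slow drift
along the two outer branches of the slow-variable nullcline with
near-instantaneous jumps at the folds (at constant voltage in the
$u$–$x$ plane, i.e. the jump preserves $u$). Because the jump time is
negligible, the period is a loop integral over the slow branches only:

* **constant current**: $T_R = C_0 \oint du/|I_0 - x|$ has the closed-form
  antiderivative
  $B(x) = -\tfrac{3a}{2}x(-4b + 2I_0 + x) + (c - 3a(b-I_0)^2)\log|x-I_0|$,
  and $T_R = C_0\sum |\Delta B|$ over the two branches between each fold
  and the same-voltage landing state $x_{\text{land}} = 3b - 2x_F$ (the
  remaining root of the stationary cubic). The logarithm is taken of
  $|x - I_0|$; each branch keeps a constant sign of $x - I_0$, so
  within-branch differences are well defined. A second, independent route
  (adaptive quadrature of the same integral parameterized by $x$, with
  the integrable zero $du/dx = 0$ at the folds) agrees to $10^{-6}$
  relative and guards the closed form.
* **constant voltage**: $T_R = C_0 R_0\oint du/|V_a - (1 + gR_0)u|$ by
  adaptive quadrature along the branches (absolute orientation so each
  branch contributes positive time); the result is exactly proportional
  to $\tau_0 = R_0C_0$.
* **FHN**: the default reproduces the two-segment symmetric approximation
  $T_R = 2\,\big|\int_1^2 (1-u^2)\,\tau_L\,du/\big((r_{0a}-1)u + u^3/3 -
  R_0I_0\big)\big|$. The exact asymmetric loop (branches $u \in [1,2]$
  and $[-2,-1]$ integrated separately) is available via `exact = TRUE`
  and differs markedly for $I_0 \neq 0$ (1.578 s vs 1.856 s at the
  worked-example parameters); the symmetric form is the default because
  it is the stated closed form of the source analysis. Quadratures use
  `stats::integrate` with tight tolerances (`rel.tol` $10^{-10}$).

# Simulation and period measurement

There is no ODE-solver package in the supported dependency set, so the
package ships a compiled adaptive Dormand–Prince 5(4) integrator
(`src/rk45.cpp`) with PI-like step control, FSAL, default tolerances
rtol $10^{-8}$/atol $10^{-10}$, and a maximum step bounded by half the
fastest intrinsic time constant so output is dense everywhere. The model
right-hand sides are duplicated in C++ for speed; a test cross-checks the
trajectory against the R-side definitions with a second-order
finite-difference stencil on the nonuniform grid. The relaxation regimes
reach time-scale ratios of $10^4$; the explicit pair handles them because
the stability-limited step on the slow branches is still cheap at these
problem sizes.

`estimate_period()` discards the first half of the trajectory as
transient, takes the mean of $u$ over the remaining window as the
Poincaré level (robust for both sinusoidal and triangular waveforms),
interpolates upward-crossing times linearly, and averages at least five
cycle intervals. Verdicts: `limit_cycle` needs cycle-to-cycle dispersion
below $10^{-3}$; `fixed_point` needs the peak-to-peak $u$ range over the
last quarter below $10^{-6}\max(|u|, 1\,\mathrm V)$; everything else is
`undecided`, and `classify_long_term()` doubles the horizon (up to 4
times) before giving up. All runs are deterministic — there is no
randomness anywhere in the computation; test seeds only choose the
sampling of property checks.

# Sweeps

Sweeps evaluate the closed-form boundary per point
(`hopf_boundary_sweep`), or simulate per point (`amplitude_sweep`,
`frequency_vs_C0`). Simulated sweeps warm-start each point from the
previous final state to shorten transients; if the warm start has
collapsed onto the stationary point (which may be unstable at the next
parameter value) it is re-perturbed by 1%. The per-point horizon is
chosen from the analytic scales (30 linearized periods or 20 relaxation
periods, whichever is larger). Log-spaced $C_0$ grids are recommended:
the oscillatory window spans about four decades of capacitance at the
canonical parameters.

# The stated world, and what a green test establishes

There is no external data; all inputs are the printed parameter sets of
the worked examples, exposed as presets (`fig2`, `fig5`, `fig8a/c/e`,
`fig10a/c/e`). Initial conditions follow the examples where stated
((0.18, 0.2) A/V for the constant-current cases, (0.1, 0.1) for the
constant-voltage cases); for the FHN presets no initial condition is
printed and (1, 0.5) is used — for limit-cycle measurements the choice is
immaterial (Poincaré–Bendixson; asserted by the initial-condition
independence test). Simulation horizons in tests are scaled to roughly
8–15 settled cycles to stay well inside CPU budgets; the period
estimates are insensitive to this (dispersion $< 10^{-3}$ is required).

Tests therefore establish internal consistency (closed forms vs
finite-difference and quadrature oracles, simulation vs analytic limits)
and agreement with the printed values of the source analysis. They do not
establish anything about real devices: physical S-type elements have
temperature-dependent, asymmetric conductance laws, noise, and parameter
drift, none of which are modeled.

# Numerical choices and degenerate inputs

* Stationary cubics (voltage-mode intersections, relaxation landing
  points) use the closed-form depressed cubic with a trigonometric branch
  for three real roots, an explicit double-root branch when the
  discriminant is within rounding of zero (fold tangencies), a
  `polyroot()` fallback, and a final Newton polish; roots with imaginary
  part below $10^{-9}$ are accepted as real.
* Strict SI units throughout (V, A, Ω, F, H, s, rad/s); no internal
  nondimensionalization, so parameters can be typed exactly as printed.
* `harmonic_solution()` warns when $|C_0 - C_{0B}|/C_{0B} > 5\%$, where
  the linearization stops describing the cycle.
* Degenerate cases: $c = 0$ collapses the fold window to a point
  (`fold_points` returns equal folds; `relaxation_orbit` errors);
  $c < 0$ has no NDR and errors; $\epsilon \ge 1$ closes the FHN window.

# Finite-$\epsilon$ accuracy of the relaxation limit

The loop integrals are exact only in the singular limit. At finite
time-scale ratio the simulated period exceeds the loop-integral value by
a fold-delay correction that scales like $\epsilon^{2/3}$: at constant
current with $C_0 = 10$ F ($\epsilon_{\text{eff}} = \tau_k g/C_0 =
10^{-3}$) the measured offset is $\approx 4.5\%$, shrinking to
$\approx 2.2\%$ at $C_0 = 30$ F and $\approx 1.0\%$ at $C_0 = 100$ F;
at constant voltage with $C_0 = 1$ F ($\epsilon = 2.5\times10^{-3}$) the
offset is $\approx 18\%$ (the printed simulated period 1.95 s vs the
singular-limit $0.41\tau_0 = 1.65$ s shows the same gap), falling to
$\approx 1.5\%$ at $\epsilon = 5\times10^{-5}$. The tests assert both the
band and the convergence rather than pretending the limit is attained at
moderate $C_0$.

# Known limitations

* No Lyapunov-coefficient computation (sub- vs supercritical Hopf is
  inferred from the crossing direction only).
* No asymptotic expansion for the period between the harmonic and
  relaxation limits; the intermediate regime is handled by simulation.
* The explicit integrator is stability-limited on slow branches; for
  time-scale ratios far beyond $10^4$ an implicit method would be
  preferable.
* One-parameter sweeps only; the three-dimensional $(V_a, R_0, C_0)$
  bifurcation volume is exposed as one-dimensional slices.
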