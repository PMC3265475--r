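---
title: "Models and methods: gene expression under oscillatory transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: gene expression under oscillatory transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscmotif)
```

## The model family

`oscmotif` treats a gene as a two-rate linear birth–death process: product
is synthesized at the basal rate `synth_off` (β₀, concentration/hour) or
the driven rate `synth_on` (β₁) depending on a boolean regulatory
condition, and decays by mass action with rate `degradation` (α, 1/hour).
The regulatory condition is a hard threshold on an upstream concentration
— either the oscillating input X or the intermediate gene Y — so the
analog upstream signal is converted into a 0/1 "digital" drive.  Three
wirings are supported: direct (X→Y), two-step (X→Y→Z), and the eight
feed-forward loops (X→Y, X→Z, Y→Z with an AND/OR gate at Z).  Feedback is
out of scope by design: the motif graph must be acyclic, which is what
makes stage-by-stage exact solution possible.

Repression can be expressed two ways, and both appear in the motif
catalog: an `active_below` edge sense (the gate arm is satisfied while the
regulator is *below* its threshold — the natural reading for the IFFL-1
repressor condition) or an inhibitor rate ordering β₁ < β₀ on the stage.
A declared FFL type (1–8; type 1 all-activator, types 1–4 coherent,
5–8 incoherent, following the standard published numbering convention) is
validated against the net signs implied by senses and rate orderings
together.

All concentrations of X are normalized to [0,1]; time is in hours
throughout.  The natural scale for frequency effects is the
*dimensionless period* τ = αT, the oscillation period measured in units of
the responding gene's lifetime.

## Input signals

The canonical oscillation shapes (left-skewed, symmetric, right-skewed)
are defined by small anchor-point tables on the unit interval and share a
fixed duty structure: above 0.1 for 75% of each cycle and above 0.75 for
25%.  Interpolating those anchors with an unconstrained cubic spline would
overshoot 1, undershoot 0, and manufacture spurious threshold crossings,
so the package uses monotone shape-preserving piecewise-cubic
(Fritsch–Carlson) interpolation via `pracma::pchip`: the curve passes
through every anchor exactly and is monotone between consecutive anchors,
which preserves the printed duty structure to machine precision.  (R's
`splinefun(method = "monoH.FC")` was rejected: it is not shape-preserving
at interior extrema and overshoots the peak by ~6%.)

Threshold crossings are located per monotone anchor interval — a sign
change brackets exactly one root, refined by `uniroot` to ~1e-12 relative
time accuracy — and anchors that sit exactly on a threshold are taken as
exact event times.  Two conventions are fixed once, repo-wide: a value
exactly equal to a threshold counts as *not* above (strict inequality; the
difference has measure zero), and digital traces are right-continuous.

## Exact dynamics and the stationary regime

Between events the ODE is linear with constant synthesis, so each segment
is `asymptote + (start − asymptote)·exp(−α·Δt)` with asymptote β/α.
`propagate()` chains these closed forms; gate logic (`gate_combine`)
operates exactly on merged switch-time sets, with simultaneous events
merged and zero-length segments elided, so the cascade evaluation
digitize → propagate → digitize → gate → propagate is event-exact.

Stationary statistics never come from burn-in simulation.  Over one drive
period each segment acts affinely on the concentration, hence the
one-period return map is affine, y(T) = A + B·y(0) with B = e^(−αT), and
the periodic orbit is its fixed point y* = A/(1−B), solved in closed form
(`stationary_cycle`).  Cycle means are closed-form segment integrals
(never quadrature); extrema are attained at segment endpoints because
each segment is monotone.

The headline closed forms are derived from the two-exponential
self-consistency conditions for a single-crossing drive (on for pT, off
for (1−p)T):

* mean: ⟨Y⟩ = (1−p)β₀/α + pβ₁/α (`stationary_mean`), exactly the cycle
  integral over T, hence period- and shape-invariant at fixed duty;
* extrema (`stationary_extrema`): with a = e^(−αpT), b = e^(−α(1−p)T),
  Y_max = (β₁/α(1−a) + β₀/α·a(1−b))/(1−ab) and symmetrically Y_min;
* onset delay (`onset_delay`): t* = log((y∞−y_start)/(y∞−K))/α;
* downstream duty (`downstream_duty`): p_out = p + (d_off − d_on)/T with
  the two log-delay terms above, clamped to 1 when K ≤ Y_min and to 0 when
  K ≥ Y_max.

These algebraic layouts were derived here and are certified in the test
suite against two independent witnesses: the event-driven engine itself
(self-consistency at 1e-9) and a `deSolve` numerical integrator
(cross-validation at 1e-6 relative sup-norm).  The closed forms are only
exposed under the single-crossing assumption; a drive that crosses more
than once per cycle makes `downstream_duty` signal "closed form
inapplicable" and the event-driven path must be used, which supports any
number of crossings.

## The numerical oracle

`integrate_step_model` integrates the same threshold model with
`deSolve::lsoda` at rtol 1e-10 / atol 1e-12 — tight enough that any
disagreement with the analytic engine beyond ~1e-8 indicates a logic bug,
not integrator error.  Discontinuities are handled by breakpoint restarts:
the input's crossing times are supplied analytically (integrating across a
rate jump silently degrades the integrator's order), while the
*intermediate's* crossings are deliberately detected numerically (grid
sign changes refined on an interpolant of the numerical solution), keeping
the oracle independent of the closed-form crossing algebra it checks.
Time integrals for long-run averages are accumulated as auxiliary ODE
states rather than quadrature over samples.

`integrate_hill_model` replaces the step with a Hill rate
β₀ + (β₁−β₀)Xⁿ/(Xⁿ+Kⁿ).  The half-activation constant is identified with
the edge threshold K — the package's choice, documented here, since the
two could in principle differ.  The Hill variant is implemented for direct
regulation, where the smooth-versus-step comparison is meaningful and
tested (deviation monotone non-increasing over n ∈ {2, 5, 10, 50});
cascades reuse the step model.

## Representative parameters

Numerical scenario parameters in fixtures, tests and examples use
off/on rates 0 and 1.5 concentration/h and α = 1/h (so τ = T in hours),
with thresholds placed to satisfy each scenario's *ordering constraints* —
the quantity that actually selects a regime:

* two-step, switch-off case: K_yz = 1.3 above ⟨Y⟩ = 1.125;
* two-step, switch-on case: K_yz = 0.5 below ⟨Y⟩ *and* below β₁/(2α).
  The second condition keeps the offset-delay log term dominant for all
  periods, so the mean of Z is globally monotone in T — the regime the
  switching claim describes.  For β₁/(2α) < K_yz < ⟨Y⟩ the duty crosses
  its long-period asymptote from above and the response is no longer
  monotone in the tail; the package reproduces that too, it is simply not
  the representative scenario.
* FFL cases A–D: thresholds 0.1/0.75 on the input arms (matching the
  canonical profiles' duty structure) and gate thresholds on either side
  of ⟨Y⟩.

Sweep grids default to logarithmically spaced periods spanning τ from
0.1 to 100, covering both limits of the extrema formulas.

## Regime classification

`classify_regime` assigns cases A–D from exactly two signed orderings:
k_xy − k_xz (which branch the input triggers first) and k_yz − ⟨Y⟩
(whether the gate reads Y's maxima or minima).  ⟨Y⟩ depends on the input
only through its duty above k_xy, so the label is period-invariant.
Orderings that are equalities (within 1e-9) yield the explicit label
`"boundary"`: the case boundaries may in principle depend on further
details (e.g. relative gate-threshold magnitudes), and the package
declines to force a pick there.  The test suite verifies that each
assigned case's defining sweep behavior (flatness, shutoff direction,
saturation values) holds in the computed tables.

## What the synthetic inputs do and do not capture

The canonical profiles are idealized: perfectly periodic, noiseless,
amplitude-normalized, with a single rise and fall per cycle.  They isolate
frequency and shape as the only information carriers, which is the point
of the exercise — but real transcription-factor oscillations (NF-κB, p53)
have cycle-to-cycle amplitude and period variability, baseline drift, and
stochastic transcription downstream.  Passing tests therefore certify the
deterministic threshold-model mathematics, not quantitative agreement
with any experimental time series; no fitting to data is attempted
anywhere.  Stochastic gene expression, delay equations and spatial
effects are out of scope.

## Numerical choices and problem sizes

* Crossing refinement: `uniroot` at tol 1e-14 (interval scale ≤ 1), giving
  event times accurate to ~1e-12 of a period; sloppy roots would leak
  into every downstream statistic.
* Event ties are merged; constant-state traces are legal everywhere.
* The cross-validation grid used by `validate_engine()` (and the test
  suite) is 6 motif scenarios × 3 shapes × 3 periods {0.5, 1, 3} h,
  horizon 8 h, 500 comparison points per run; long-run average checks use
  100 analysis cycles after 100 burn-in cycles.  These sizes were chosen
  so the whole suite runs in seconds while leaving discretization error
  orders of magnitude below the asserted tolerances.
* The core pipeline contains no random number generation; all fixtures
  are reproducible byte-for-byte.

## Known limitations

* The closed-form stationary layer assumes one up/down crossing of each
  threshold per cycle (multi-crossing drives fall back to the exact
  event-driven path, losing the interpretable formulas).
* The Hill variant covers direct regulation only.
* Square waves are discontinuous by construction and are excluded from
  the Hill (continuous-input) integrator.
* Boundary regime configurations are reported, not resolved.
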