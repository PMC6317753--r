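---
title: "Mood-expectation dynamics: model, analysis, and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mood-expectation dynamics: model, analysis, and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcycle)
```

## The model

`moodcycle` simulates a two-variable continuous-time model of mood
regulation. Mood $m(t)$ (dimensionless) and learned expectation $v(t)$
(in reality units) interact through a prediction-error, or *surprise*,
signal $s = fm + r - v$: the mismatch between *perceived* reality —
external reality $r(t)$ additively biased by mood through the scale
$f$ — and the expectation:

$$
\frac{dm}{dt} = \eta_m\,(fm + r - v) - k\,m - k_3\,m^3, \qquad
\frac{dv}{dt} = \eta_v\,(fm + r - v).
$$

All rates are per week. $\eta_m$ and $\eta_v$ are learning rates for
mood and expectation; $k$ is a linear mood-recovery rate (hedonic
adaptation: mood relaxes to baseline even after good news) and $k_3$ a
cubic recovery coefficient that bounds mood physiologically. People
respond differently to positive and negative surprises, so the mood
learning rate switches with the sign of the surprise:
$\eta_m = \eta_m^+$ when $s > 0$ and $\eta_m = \eta_m^-$ when
$s \le 0$ (the boundary belongs to the minus branch). When
$\eta_m^+ = \eta_m^-$, eliminating $v$ turns the system into a single
Liénard-type oscillator in $m$ whose nonlinear damping changes sign
with $|m|$ — the van der Pol mechanism.

The product $f\eta_m$, the **mood sensitivity**, is the bifurcation
parameter. Linearizing about the fixed point $(m, v) = (0, r_0)$
(reality can be shifted to $0$ without loss of generality; the package
asserts this shift invariance numerically) gives eigenvalues

$$
\lambda_\pm = \tfrac12\,(f\eta_m - \eta_v - k) \pm \tfrac12\sqrt{\Delta},
\qquad
\Delta = (f\eta_m - \eta_v - k)^2 - 4\eta_v k .
$$

Below the critical sensitivity $f\eta_m = \eta_v + k$ the origin is
stable and mood oscillations are damped (cyclothymic for $\Delta < 0$);
at the critical value a supercritical Hopf bifurcation creates a limit
cycle — persistent mood oscillation under constant reality, the model's
signature of a bipolar state. The rectangle with vertices
$(\pm m^*, \pm f m^*)$, $m^* = \sqrt{(2 f\eta_m - k)/k_3}$, traps all
trajectories that start inside it, which both guarantees the cycle
(Poincaré–Bendixson) and bounds its amplitude.

## Reference parameter sets

Two configurations recur throughout the package and its tests, both
with $f = 0.3$:

* the *slow* set $\eta_v = k = 0.37$, $k_3 = 2.8\times10^{-3}$
  (critical sensitivity $0.74$, Hopf period
  $2\pi/\sqrt{\eta_v k} \approx 17$ weeks), used for the bifurcation,
  amplitude and medication analyses;
* the *fast-expectation* set $\eta_v = 1.48$, $k = 0.37$ (critical
  sensitivity $1.85$, spiral window half-width
  $2\sqrt{\eta_v k} = 1.48$), used for the two-parameter stability
  map, because it gives all four half-plane regimes a comfortably wide
  sensitivity range.

The step-response (unipolar bias) protocol instead uses
$\eta_v = k = 1.85$, $k_3 = 0.014$ so that adaptation to single
reality events happens on the one-week scale of the protocol.
`mood_params_from_ratios()` constructs parameter sets directly from
sensitivity ratios $f\eta_m^\pm/(\eta_v + k)$, the natural coordinates
of every analysis here.

## Asymmetric sensitivities: half-plane analysis

With $\eta_m^+ \ne \eta_m^-$ the phase plane splits along $v = fm$
into two half-planes, each governed by its own linear system near the
origin. `classify_halfplane()` labels each branch stable/unstable
node/spiral by where $f\eta_m$ falls relative to
$\eta_v + k \mp 2\sqrt{\eta_v k}$. `predict_stability()` combines the
two regimes:

* both stable → stable; both unstable → unstable;
* node + spiral → the node decides (almost all trajectories end up in,
  and remain in, the node half-plane; trajectories starting in the
  wedge between the fast eigendirection and the boundary are the
  exception and are deliberately not special-cased — the stability-map
  agreement statistic absorbs them);
* spiral + spiral → a trajectory alternates half-planes every
  half-cycle $\Delta t = 2\pi/\sqrt{4\eta_v k - \mathrm{tr}^2}$, its
  radius multiplied by
  $\exp(\pi\,\mathrm{tr}/\sqrt{4\eta_v k - \mathrm{tr}^2})$ per
  half-plane; the sign of the summed exponents (`spiral_stability_criterion()`)
  decides, with the zero set
  $f(\eta_m^+ + \eta_m^-) = 2(\eta_v + k)$;
* stable node + unstable node → reported unstable (full-model
  simulations behave so) but flagged `initial_condition_sensitive`,
  since no half-cycle argument applies there and the outcome genuinely
  depends on the starting wedge. Both facts are surfaced rather than
  resolved.

Parameters within a relative $10^{-9}$ of a regime boundary return a
`degenerate` verdict instead of a silent classification; the boundary
cases hold only for measure-zero parameter combinations and behave
qualitatively differently on either side.

## Numerical design

Integration uses `deSolve::lsodar` (adaptive, with root finding).
Defaults: `rel_tol = 1e-8`, `abs_tol = 1e-10`, output grid
`0.05` weeks — oscillation periods are tens of weeks, so this
resolves every feature cheaply. Scans relax to `1e-6`/`1e-8` and a
`0.25`-week grid for throughput.

The switching field is continuous across $v = fm + r$ (only its
derivative jumps), so classical solutions suffice and no sliding mode
arises. Nevertheless the solver never steps across the discontinuity
in the derivative: with asymmetric sensitivities a root function
locates each crossing of $s = 0$, integration stops there, the new
branch is chosen by the sign of the surface drift
$\dot s = -f(km + k_3 m^3)$ (drift $\le 0$ → minus branch, matching
the Heaviside boundary convention), and a single $10^{-9}$-week RK4
step moves the state off the surface before the adaptive solver
resumes. A switch counter guards against chattering in pathological
configurations, and `solver_options(smooth_width = )` offers an
optional logistic blend of the two learning rates for robustness
experiments (default off). Reality jumps and intervention times are
hard integration breakpoints; the state is continuous across them.

Cycle statistics (`estimate_cycle()`) discard the first half of the
run by default — matching the assessment window of the 162.5-week
stability-map protocol — and detect mood extrema by sign changes of
the discrete derivative. Peak *times* are refined by a parabolic
vertex; peak *values* keep the raw dense-grid sample, because a
parabolic value overshoots by a few percent on the steep asymmetric
peaks of relaxation oscillations at large $f\eta_m$ while the raw
sample is accurate to $O((\Delta t/T)^2)$. Convergence is declared
when the last few maxima agree within 1%.

The simulation-based Hopf-threshold bisection classifies a run as
oscillation-sustaining when the mood-envelope standard deviation grows
between the third and fourth quarters of a 900-week run *or* the final
quarter's exceeds 0.5 — far above the 0.05 starting amplitude — to
catch runs that settle onto the cycle before the final quarter. Near
the threshold the cycle amplitude follows the supercritical normal
form $\propto\sqrt{f\eta_m - (\eta_v + k)}$; the package verifies the
square-root exponent rather than any absolute amplitude, since no
closed-form amplitude exists (a weakly nonlinear expansion is out of
scope).

## Stochastic reality

Real lives are punctuated by abrupt, lasting changes — a raise, a
bereavement — so reality is modelled piecewise-constant: levels i.i.d.
$\mathcal N(0, \sigma_r^2)$, durations i.i.d. log-normal with both
mean and standard deviation of the *log* duration equal to $1/k_r$
(the stated log-time moments are read literally as the parameters of
the underlying normal). Levels are uncorrelated, the first segment
starts at $t = 0$ with a drawn level, and realizations are *not*
re-centred per draw — the population mean is zero. Draws come from a
private, seeded Mersenne–Twister stream in fixed-size blocks, so a
seed fully determines the realization, the retained window is
independent of the horizon, and the ambient RNG state is untouched.

What this generator emulates: the abruptness, persistence and scale of
life events, sufficient for every qualitative contrast the package
tests (larger mood variability above threshold, unipolar bias under
asymmetry, intermittent QIDS spikes). What it does not: autocorrelated
or continuously drifting realities, heavy-tailed event magnitudes, and
any feedback from mood onto reality. Tests passing under this
generator therefore say nothing about, e.g., mood-dependent exposure
to life events.

## Clinical layer

Depression scores are modelled on the QIDS-SR16 scale as rectified
negative mood, $\min(27, c\cdot\max(0, -m))$, with the scale factor
$c$ a configuration knob (default 1) since only mood *shape* is
predicted. Interventions modify a running simulation at scheduled
times:

* **antidepressant as mood elevation** — mood is reset to $p$ times
  the lowest mood attained so far ($p \in (0,1)$, smaller = stronger
  dose). "Lowest so far" and "current trough" coincide when the dose
  is given within a depressive episode, which the protocols do; an
  event at $m \ge 0$ warns and applies the same rule. Mild doses
  transiently relieve depression and slightly *delay* the next mania;
  strong doses advance it — the dose threshold between the two is an
  empirical output of the dose ladder, not a hard-coded constant.
* **antidepressant as increased positive sensitivity** —
  $f\eta_m^+$ is raised to the requested value from the event time on;
  cycles become earlier, larger and faster with dose.
* **lithium-like sedation** — both learning rates are scaled by
  $1 -$ reduction. Amplitude and QIDS peaks shrink and no mania is
  ever induced; a reduction deep enough to cross the threshold ends
  the oscillation entirely.

## Problem sizes and reproducibility

The packaged analyses use: 1000 random parameter draws for the
eigenvalue oracle; 50 random spiral configurations for the half-cycle
multiplier cross-check (solver at $10^{-12}$ relative tolerance
against the $10^{-6}$ assertion); a $21\times21$ sensitivity grid over
ratios $[0.1, 2.2]$ with a 162.5-week horizon and second-half
assessment for the stability map; 300-week runs for the amplitude
power law at $f\eta_m \in \{5, 10, 20, 50\}\times(\eta_v+k)$;
900-week runs inside the threshold bisection; and $10^4$ segments for
the stochastic-reality moment checks. Every stochastic step takes an
explicit seed, and `run_simulate()` round-trips bit-identically from
a configuration file.

## Known limitations

* The half-plane stability criteria are exact for the piecewise-linear
  system only; near the boundary of the spiral–spiral box the
  finite-horizon variability statistic resolves stability to about one
  grid cell.
* No amplitude formula near threshold is provided (only the
  square-root law is verified), and no Floquet analysis of the
  nonlinear cycle.
* Mania is one-dimensional mood; multidimensional trait models, plastic
  (time-varying) parameters, and parameter estimation from
  physiological measurements are out of scope.
* The stochastic layer is forcing-only: no noise enters $m$ or $v$
  directly, and no rigorous stochastic analysis of mood bias under
  random reality is attempted.
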