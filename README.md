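# moodcycle

Simulation and analysis of a dynamical-systems model of bipolar
disorder, for computational psychiatry researchers and modellers who
want a tested, scriptable implementation of mood–expectation dynamics
with asymmetric mood sensitivity.

## The model

Mood `m(t)` and learned expectation `v(t)` interact through a
prediction-error ("surprise") signal `f·m + r − v`, the mismatch
between perceived reality (external reality `r(t)` biased by mood) and
expectation:

    dm/dt = η_m (f·m + r − v) − k·m − k₃·m³
    dv/dt = η_v (f·m + r − v)

with learning rates `η_m`, `η_v`, mood-recovery rates `k` (linear) and
`k₃` (cubic), all per week, and a mood-to-perceived-reality scale `f`.
The mood learning rate may differ for positive (`η_m⁺`) and
non-positive (`η_m⁻`) surprise, which splits the phase plane into two
half-planes along `v = f·m + r`.

The **mood sensitivity** `f·η_m` is the bifurcation parameter. At
`f·η_m = η_v + k` the resting state loses stability in a supercritical
Hopf bifurcation and mood settles onto a limit cycle — persistent
oscillation under constant reality, the model's signature of a bipolar
state. The package provides:

* event-accurate integration of the piecewise-smooth system
  (deSolve `lsodar` with root-located branch switching), with
  piecewise-constant deterministic or seeded stochastic reality;
* closed-form linear analysis: eigenvalues
  `λ± = ½(f·η_m − η_v − k) ± ½√Δ`, `Δ = (f·η_m − η_v − k)² − 4·η_v·k`,
  per-half-plane node/spiral classification, half-cycle growth
  multipliers `exp(π·tr/√(4·η_v·k − tr²))`, and the spiral–spiral
  stability criterion with zero set
  `f(η_m⁺ + η_m⁻) = 2(η_v + k)`;
* limit-cycle quantification: amplitude, period, mood variability, the
  trapping-rectangle bound `m* = √((2·f·η_m − k)/k₃)`, Hopf-threshold
  bisection, amplitude–sensitivity scaling, and two-parameter
  stability maps;
* a clinical layer: QIDS-SR16 scoring (rectified negative mood) and
  medication protocols — antidepressant as mood elevation or increased
  positive sensitivity, lithium-like symmetric sensitivity reduction.

## Worked example

```r
library(moodcycle)

# bipolar reference configuration: sensitivity 1.5x the critical value
p <- mood_params_from_ratios(1.5, eta_v = 0.37, f = 0.3, k = 0.37,
                             k3 = 2.8e-3)
p
#> Mood-expectation model parameters (rates per week)
#>   eta_m+ = 3.7  eta_m- = 3.7  eta_v = 0.37
#>   f = 0.3  k = 0.37  k3 = 0.0028
#>   mood sensitivities f*eta_m: + 1.11  - 1.11  (critical 0.74)

traj <- simulate_mood(p, constant_reality(0, 300), init = c(0, -1))
estimate_cycle(traj)
#> limit cycle: amplitude 13.03, period 12.57 weeks, mood sd 9.065 (converged)

m_star(p)   # trapping-rectangle bound on |m|
#> [1] 25.70436
```

The converged cycle swings mood between about ±13 with a 12.6-week
period, inside the analytic outer bound 25.7. An asymmetric
configuration where only the positive sensitivity is supercritical is
still stable when the two half-plane spirals jointly contract:

```r
predict_stability(mood_params_from_ratios(1.2, eta_v = 1.48, f = 0.3,
                                          k = 0.37, k3 = 2.8e-3,
                                          ratio_minus = 0.7))
#> linear stability of the origin
#>   plus half-plane:  unstable_spiral
#>   minus half-plane: stable_spiral
#>   spiral-spiral criterion value: -0.459681
#>   verdict: stable (spiral_spiral_full_cycle_multiplier)
```

Simulations can also be described by YAML/JSON configuration files and
run via `run_simulate()` / `run_linstab()` / `run_scan()` or the thin
command-line wrapper in `exec/moodcycle` (subcommands
`simulate | linstab | scan`); trajectories serialize to
`time,m,v,r,branch,qids` CSV and reports to JSON. See the vignette
`vignettes/mood-dynamics.Rmd` for the full account of the model,
numerical choices and protocols.

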