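# delayswarm

Simulation, reduced theory, and trajectory analysis for **microswimmers
with retarded attraction to a fixed target**.

## The science

A feedback-controlled active particle is steered toward a target at the
origin, but the steering acts on outdated information: the propulsion
direction at time *t* is set by the particle's position a delay
*δt* in the past,

    û(t) = −r(t − δt) / |r(t − δt)|.

For a particle in contact with a target obstacle of the same radius *a*
(orbit radius *R* = 2*a*), the aiming error θ — the signed angle between
û(*t*) and the instantaneous target direction −r(*t*) — obeys, after
reduction, a Langevin equation in a **quartic virtual potential**

    U(θ) = (1/δt) [ (1/(ω₀δt) − 1) θ² + θ⁴/12 ],      ω₀ = v₀/R.

The dimensionless control parameter ω₀δt governs a **supercritical
pitchfork bifurcation**: for ω₀δt < 1 the swimmer jitters around perfect
aim (θ = 0); above 1 two mirror rotational states
θ± = ±√(6(1 − 1/(ω₀δt))) appear and the swimmer orbits the target with a
transient chirality. Beyond ω₀δt = π/2 the orbit takes off the contact
circle to radius R = 2v₀δt/π. The theory module also provides the
relaxation time τ (critical slowing down, τ → ∞ at ω₀δt = 1) and the
Kramers rate k of noise-driven chirality switching between ±θ±.

The package contains:

- **theory** — the closed forms above: `fixed_points()`, `theta_pm()`,
  `potential()`, `drift()`, `relaxation_time()`, `kramers_rate()`,
  `takeoff_orbit_radius()`, `effective_delay()`.
- **simulator** (compiled, Rcpp) — `simulate_swimmers()` /
  `make_multiparticle()`: full 2D many-particle Langevin dynamics with the
  delayed aiming rule, zero-order-hold feedback, translational noise and
  steric exclusion; `simulate_constrained()`: the scalar stochastic delay
  equation on the contact circle; `simulate_reduced_theta()`: the reduced
  angle equation.
- **estimation** — `propulsion_angle()`, `order_parameter()`,
  `angle_histogram()`, `pmf_and_fit_Dtheta()` (one-parameter Boltzmann fit
  of the effective temperature D_θ), `autocorrelation()` /
  `relaxation_time_from_acf()`, `switching_rate()` (residence times with
  hysteresis), `bifurcation_scan()`, `analysis_report()`.
- **collective** — `assign_shells()`, `per_shell_bifurcation()`,
  `rotation_sense()`, `velocity_field()`, `bias_hook()`.
- **io** — deterministic TSV trajectories (`write_trajectory()` /
  `read_trajectory()`), YAML configs (`load_config()`), JSON
  `run_manifest()`, and a thin CLI at `exec/delayswarm`
  (`theory | simulate | analyze | scan | collective`).

## Worked example

A single swimmer at the default experimental parameters
(a = 1.09 µm, v₀ = 2.16 µm/s, D₀ = 0.0642 µm²/s, instrumental latency
64 ms) with a programmed delay of 1.14 s:

```r
library(delayswarm)

p  <- swimmer_params(delta_t = 1.14)
cf <- sim_config(duration = 620, dt = 0.002, seed = 1, sample_every = 5,
                 initial_positions = matrix(c(2.18, 0), 1))
tr  <- simulate_swimmers(p, cf)
ser <- discard_burnin(propulsion_angle(tr), p)

R <- mean(sqrt(tr$x[,1]^2 + tr$y[,1]^2))
m <- reduced_model(omega0 = p$v0 / R, delta_t = p$delta_t + p$instr_delay)
analysis_report(ser, m)
```

```
Propulsion-angle analysis report
  control omega0*delta_t = 1.166
  modes: +0.676 / -1.008 rad
  D_theta (fit) = 0.0505 1/s
  relaxation time tau = 25.9 s
  switching rate k = 0.0309 1/s
```

The control parameter is above 1, so the angle distribution is bimodal:
the modes sit near the stationary sine-equation roots
(`fixed_points(1.166)` gives ±0.946 rad; the ± asymmetry of a single
620 s run reflects the slow chirality switching), the fitted effective
temperature D_θ ≈ 0.05 1/s sets the depth of the measured potential of
mean force `−D_θ log p(θ)`, and the switching rate reports how often the
orbit reverses its chirality.

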