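---
title: "Methods: delayed attraction, the reduced angle dynamics, and how the package estimates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed attraction, the reduced angle dynamics, and how the package estimates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayswarm)
```

## The model

An overdamped active particle at position $\mathbf r(t)$ (relative to a
fixed target at the origin) propels at constant speed $v_0$ along a unit
heading $\hat{\mathbf u}(t)$ and diffuses translationally with
coefficient $D_0$:

$$\dot{\mathbf r} = v_0\,\hat{\mathbf u}(t) + \sqrt{2D_0}\,\boldsymbol\xi(t),
\qquad
\hat{\mathbf u}(t) = -\frac{\mathbf r(t-\delta)}{|\mathbf r(t-\delta)|},$$

where $\delta = \delta t + \Delta t$ is the programmed delay plus the
instrumental latency of the feedback loop. The heading is not a body
axis: it is imposed by the feedback, refreshed at multiples of a frame
period and held constant in between (zero-order hold), which is why the
simulator has no rotational diffusion of headings.

When the particle is in steric contact with an immobile target particle
of equal radius $a$, its distance is pinned at $R = 2a$ and only the
polar angle $\phi$ evolves:
$\dot\phi = \omega_0 \sin(\phi(t)-\phi(t-\delta t)) + \sqrt{2D_0/R^2}\,\eta$,
with $\omega_0 = v_0/R$. The aiming error
$\theta(t) = \phi(t) - \phi(t-\delta t)$ then follows, to third order in
the delay, the non-delayed normal form

$$\dot\theta = \frac{1}{3\delta t}\left[\theta_\pm^2 - \theta^2\right]\theta
 + \sqrt{2 D_\theta}\,\eta, \qquad
\theta_\pm^2 = 6\left(1 - \frac{1}{\omega_0\delta t}\right),$$

i.e. diffusion in the quartic virtual potential
$U(\theta) = \delta t^{-1}[(1/(\omega_0\delta t)-1)\theta^2 + \theta^4/12]$
at an effective temperature $D_\theta$. The systematic reduction
produces a noise amplitude that is quantitatively inaccurate, so
$D_\theta$ is treated throughout as a free parameter fitted to the
stationary angle histogram; the package follows the convention of
quoting it in units of 1/s. Everything the theory module computes —
fixed points of $\theta/(\omega_0\delta t)=\sin\theta$, the pitchfork
branch $\theta_\pm$, the relaxation time
$\tau = 1/U''(\theta_{\min})$, the Kramers switching rate
$k = \sqrt{U''(\theta_\pm)|U''(0)|}/(2\pi)\,
e^{-[U(0)-U(\theta_\pm)]/D_\theta}$, and the take-off orbit radius
$2v_0\delta t/\pi$ — is a closed-form consequence of these two
equations.

## Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `a` | particle radius | 1.09 | µm |
| `v0` | propulsion speed | 2.16 (single), 2.06 (15-particle) | µm/s |
| `D0` | translational diffusion | 0.0642 | µm²/s |
| `delta_t` | programmed delay | none (the control knob) | s |
| `instr_delay` | feedback latency | 0.064 | s |
| `frame_period` | heading refresh interval | every step | s |
| `dt` | integration step | 0.002 | s |
| `D_theta` | effective angular temperature | 0.05 | 1/s |

The defaults are the experimental conditions of the feedback system the
package emulates; `delta_t` has no default because it is the quantity
scanned across the bifurcation. The default `frame_period` is the
continuous-feedback limit (refresh every step); the camera loop of a
real setup is discrete, and a coarser hold (e.g. 80 ms) can be set
explicitly — the main-text level of description does not fix it, so the
package does not pretend to know it.

## What the generator emulates — and what it does not

The simulator is the package's synthetic-data source. It reproduces:
constant-speed propulsion with the retarded aiming rule, translational
Brownian noise, zero-order-hold feedback with separate programmed and
instrumental delays, steric exclusion among swimmers and with the
immobile target, and (optionally) a tangential bias hook. It does
**not** include hydrodynamic or thermophoretic inter-particle
interactions, optical forces, laser heating physics, 3D motion, or
measurement noise of the tracking. Consequences to keep in mind:

- The single-particle pitchfork, critical slowing down, Boltzmann
  statistics in $U(\theta)$ and Kramers switching are quantitatively
  testable against the closed forms, and the test suite does so.
- Collective phenomena that rest on flow and temperature fields — the
  delayed simultaneous shell transition, counter- versus co-rotation
  thresholds and their flip — are *not* claimed by the package. The
  steric-only swarm still forms the two-shell geometry with
  $R^{\rm out}\approx 2R^{\rm in}$, which is what the acceptance checks
  assert; rotation-sense phenomenology can be explored qualitatively
  through the `bias_hook` interface, which is a hypothesis port, not a
  calibrated model.
- Passing tests therefore validate the implementation of the stated
  model, not the fidelity of that model to any particular laboratory
  system.

## Numerical choices

- **Integration** is fixed-step Euler–Maruyama. Delays are converted to
  an integer number of steps (warning if rounding moves them by more
  than 1%), so the delay ring buffer is indexed exactly. The
  pre-history for $t<0$ is the constant initial position (constrained
  runs optionally use a linear ramp so the initial aiming error can be
  set); its influence decays after one delay period and is removed by
  the burn-in rule below.
- **Undefined aim** (delayed position within $10^{-9}$ µm of the
  origin) keeps the previous heading — the zero-order hold of a real
  feedback loop.
- **Steric contacts** default to hard projection: pairwise overlap is
  removed symmetrically along the center line (the immobile target
  reflects its half), iterated up to 40 sweeps per step. This preserves
  the contact distance $R = 2a$ that the reduced theory assumes. A
  stiff harmonic alternative is available.
- **Root finding** for the sine fixed points uses sign-bracketed
  bisection on $(0,\pi)$ to $10^{-10}$; on that interval the first
  (physical) intersection is the only one.
- **Burn-in**: the first $\max(5\delta t,\,5\tau_{\rm est})$ seconds of
  a run are discarded, with $\tau_{\rm est}$ capped at 20 s near the
  critical point where $\tau$ diverges.
- **Histograms** use 73 uniform bins on $(-\pi,\pi]$ (≈5° resolution);
  mode extraction smooths with a kernel density whose bandwidth equals
  one bin width. The $D_\theta$ fit minimizes squared differences of
  log bin probabilities with bin masses computed by within-bin Simpson
  quadrature of $e^{-U/D_\theta}$ — midpoint evaluation is badly biased
  when the well is narrower than a bin.
- **Switching detection** uses hysteresis: a chirality switch counts
  only when $\theta$ crosses from beyond $+\theta_h$ to beyond
  $-\theta_h$ (default $\theta_h=\theta_\pm/2$), so intra-well noise
  never registers. The rate is the inverse mean residence time.
- **Relaxation times** are read off the autocorrelation's first $1/e$
  crossing, linearly interpolated between lag samples.
- **Reproducibility**: one master seed drives a single Mersenne–Twister
  stream; particles draw noise in a fixed order, so identical seed and
  configuration give bitwise-identical trajectories. (Per-particle
  independent sub-streams were considered and rejected: a single stream
  achieves the same determinism contract without a hand-rolled
  stream-splitting generator.)

## Design decisions on genuinely open points

- **Instrumental latency.** The refined delay theory that treats the
  camera latency $\Delta t$ exactly is not part of the package;
  `effective_delay()` implements the simplest additive surrogate
  $\delta t \to \delta t + \Delta t$ and flags the result approximate.
  It captures the direction of the shift (bifurcation at smaller
  programmed delay) but not its exact magnitude, and it is excluded
  from the quantitative acceptance checks.
- **Shell boundary.** Default $3a$, the midpoint of the nominal inner
  ($2a$) and outer ($4a$) shell radii, applied to 1 s window means
  because particles exchange between shells. Shell radii are
  occupancy-weighted means.
- **Angular velocities** for rotation-sense labels use unwrapped
  $\phi$ differences, never arctangents of finite differences, to avoid
  branch-cut artifacts; the noise floor is twice the standard error of
  per-window means.
- **Bias hook evaluation.** A user-supplied bias function is tabulated
  on a 721-point angle grid and linearly interpolated inside the
  compiled loop, keeping the hook cheap enough to run at every step.
- **Pooling**: repeated runs are pooled by concatenating angle series,
  never by averaging histograms of unequal lengths.

## Problem sizes used by the tests and the acceptance script

The suite checks the stationary Boltzmann density with $10^5$ thinned
samples from a $4\times10^5$ s reduced-equation run ($dt=5$ ms);
Kramers rates against ~100 observed switches at a barrier of
$3.5\,D_\theta$; relaxation times from 4000 s runs at four control
values spanning both regimes; effective-temperature recovery from
$10^5$ exact inverse-CDF samples; and the full simulator against the
free-orbit radius (200 s deterministic), the ±80° histogram modes at
$\delta t = 1.4$ s (five pooled 620 s runs at $dt=2$ ms), and the
15-particle two-shell geometry (250 s). These sizes were chosen so each
statistical check has an expected estimation error several times
smaller than its stated tolerance.

## Known limitations

- The third-order reduction is asymptotic: the relative deviation of
  $\theta_\pm$ from the exact sine-equation root grows as
  $\theta^2/40$, reaching ~1% at control ≈ 1.07 and ~2.7% at 1.2. The
  package reports both quantities; tests document the convergence
  order.
- Euler–Maruyama stationary densities carry an $O(dt)$ bias; at the
  default steps it is far below the statistical tolerances used.
- The effective temperature $D_\theta$ fitted from data absorbs
  feedback discretization and (in experiments) tracking noise; it is
  not the bare $D_0/R^2$.
- Without hydrodynamics the package does not reproduce — and does not
  claim — the experimental shell-transition delays or the
  counter-to-co-rotation flip of a real swarm.
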