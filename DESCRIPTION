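Package: delayswarm
Title: Delayed-Attraction Microswimmer Dynamics: Simulation, Bifurcation
    Theory and Trajectory Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying feedback-controlled active Brownian
    particles that self-propel toward a fixed target with a retarded
    aiming rule.  Provides a compiled Langevin simulator for the full 2D
    many-particle dynamics with steric exclusion, scalar integrators for
    the constrained delay oscillator and for the reduced propulsion-angle
    equation, the closed-form reduced theory (delay-induced pitchfork
    bifurcation, quartic virtual potential, critical slowing down,
    Kramers chirality-switching rates), and an estimation pipeline that
    extracts propulsion angles, rotational order parameters, histograms
    and potentials of mean force, effective angular temperatures,
    autocorrelation relaxation times, residence-time switching rates,
    bifurcation diagrams, shell structure and velocity fields from
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
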