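#' Aiming direction from a delayed position history
#'
#' The feedback rule of the retarded attraction: the propulsion direction at
#' time `t` is the unit vector from the particle's position a total delay
#' `delta_total` in the past toward the target at the origin,
#' \eqn{\hat u(t) = -r(t - \delta)/|r(t - \delta)|}.
#'
#' @param history Data frame with columns `time`, `x`, `y`: past positions
#'   relative to the target center (um).  Must cover `t - delta_total`.
#' @param t Current time (s).
#' @param delta_total Total delay (programmed + instrumental, s).
#' @return Unit 2-vector `c(ux, uy)`.
#' @export
aim_direction <- function(history, t, delta_total) {
  stopifnot(is.data.frame(history),
            all(c("time", "x", "y") %in% names(history)))
  tq <- t - delta_total
  if (tq < min(history$time) - 1e-12)
    stop("history does not cover the delayed time t - delta_total")
  i <- max(which(history$time <= tq + 1e-12))
  r <- c(history$x[i], history$y[i])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) stop("undefined aim: delayed position is at the target center")
  -r / nr
}

new_trajectory <- function(time, x, y, ux, uy, params, config,
                           escaped = FALSE) {
  structure(list(time = time, x = x, y = y, ux = ux, uy = uy,
                 params = params, config = config, escaped = escaped),
            class = "swim_trajectory")
}

#' @export
print.swim_trajectory <- function(x, ...) {
  cat(sprintf("Swimmer trajectory: %d particle(s), %d samples, t = 0..%g s%s\n",
              ncol(x$x), length(x$time), max(x$time),
              if (isTRUE(x$escaped)) " [escaped, stopped early]" else ""))
  invisible(x)
}

#' @export
as.data.frame.swim_trajectory <- function(x, ...) {
  n <- ncol(x$x)
  data.frame(
    time_s = rep(x$time, n),
    particle_id = rep(seq_len(n), each = length(x$time)),
    x_um = as.vector(x$x), y_um = as.vector(x$y),
    ux = as.vector(x$ux), uy = as.vector(x$uy))
}

auto_positions <- function(params, config) {
  n <- config$n_particles
  r0 <- config$start_radius
  if (is.null(r0)) r0 <- max(4 * params$a, 2.2 * params$a * n / pi)
  ang <- 2 * pi * (seq_len(n) - 1) / n + 0.25 # fixed offset off the x-axis
  cbind(r0 * cos(ang), r0 * sin(ang))
}

#' Simulate the full 2D delayed-aiming Langevin dynamics
#'
#' Integrates, with an Euler--Maruyama scheme, overdamped swimmers
#' propelling at constant speed `v0` along the delayed aiming direction
#' ([aim_direction()]) with translational noise of strength `D0`:
#' \deqn{r \leftarrow r + v_0 \hat u \, dt + \sqrt{2 D_0 dt}\,\xi.}
#' The heading is refreshed at multiples of `frame_period` from the position
#' lagged by `delta_t + instr_delay` and held constant in between
#' (zero-order hold).  Steric overlaps with the optional immobile target and
#' between swimmers are resolved each step.  Runs are bitwise reproducible
#' for a given seed and configuration.
#'
#' @param params A [swimmer_params()].
#' @param config A [sim_config()].
#' @param bias_fn Optional tangential-bias hook: a function of the
#'   particle's own propulsion angle (rad) returning a tangential drift
#'   speed (um/s, positive = counter-clockwise), added to the propulsion.
#'   Default `NULL` (off).  See [bias_hook()].
#' @return A `swim_trajectory`: sampled times and per-particle positions
#'   (um, relative to the target center) and unit headings.
#' @examples
#' p <- swimmer_params(delta_t = 1.14)
#' tr <- simulate_swimmers(p, sim_config(duration = 10, seed = 42))
#' @export
simulate_swimmers <- function(params, config, bias_fn = NULL) {
  stopifnot(inherits(params, "swimmer_params"), inherits(config, "sim_config"))
  dt <- config$dt
  nsteps <- as.integer(round(config$duration / dt))
  delay_steps <- delay_in_steps(params$delta_t + params$instr_delay, dt,
                                "total delay")
  hold_steps <- if (is.null(params$frame_period)) 1L
                else max(1L, delay_in_steps(params$frame_period, dt,
                                            "frame_period"))
  pos0 <- config$initial_positions
  if (is.character(pos0) && identical(pos0, "auto")) {
    pos0 <- auto_positions(params, config)
  } else {
    pos0 <- as.matrix(pos0)
    if (nrow(pos0) != config$n_particles || ncol(pos0) != 2)
      stop("initial_positions must be an n_particles x 2 matrix")
    # auto-respacing of overlapping initial placements (steric runs only)
    for (pass in if (config$interaction == "none") integer(0) else 1:50) {
      d <- as.matrix(stats::dist(pos0))
      diag(d) <- Inf
      if (all(d > 2 * params$a)) break
      bad <- which(d < 2 * params$a, arr.ind = TRUE)
      for (k in seq_len(nrow(bad))) {
        i <- bad[k, 1]; j <- bad[k, 2]
        if (i >= j) next
        v <- pos0[j, ] - pos0[i, ]
        nv <- sqrt(sum(v^2)); if (nv < 1e-9) v <- c(1, 0) else v <- v / nv
        push <- (2 * params$a - nv) / 2 + 1e-6
        pos0[i, ] <- pos0[i, ] - push * v
        pos0[j, ] <- pos0[j, ] + push * v
      }
    }
  }
  use_bias <- !is.null(bias_fn)
  bias_grid <- 0
  if (use_bias) {
    grid <- seq(-pi, pi, length.out = 721L)
    bias_grid <- vapply(grid, function(th) as.numeric(bias_fn(th)), 0.0)
    if (any(!is.finite(bias_grid)))
      stop("bias_fn returned a non-finite value")
  }
  box <- config$escape_box
  if (is.null(box)) box <- 50 * params$a
  inter <- match(config$interaction, c("none", "projection", "harmonic")) - 1L

  set.seed(config$seed)
  out <- sim_full_cpp(config$n_particles, nsteps, dt, params$v0, params$D0,
                      params$a, delay_steps, hold_steps,
                      config$target_fixed, inter, config$k_harmonic,
                      pos0[, 1], pos0[, 2], box, config$sample_every,
                      use_bias, bias_grid)
  ns <- out$nsamp
  if (isTRUE(out$escaped))
    warning("a particle escaped the simulation box; run stopped early")
  idx <- seq_len(ns)
  new_trajectory(out$time[idx],
                 out$x[idx, , drop = FALSE], out$y[idx, , drop = FALSE],
                 out$ux[idx, , drop = FALSE], out$uy[idx, , drop = FALSE],
                 params, config, escaped = isTRUE(out$escaped))
}

#' Simulate the constrained-orbit delay oscillator
#'
#' The particle slides on the contact circle of radius `R = 2a` around the
#' target; its polar angle obeys the scalar stochastic delay equation
#' \deqn{\dot\phi(t) = \omega_0 \sin(\phi(t) - \phi(t - \delta t)) +
#' \sqrt{2 D_0/R^2}\,\eta(t),} with \eqn{\omega_0 = v_0/R}.  The propulsion
#' angle is recovered as \eqn{\theta(t) = \phi(t) - \phi(t - \delta t)}.
#' The pre-history (`t < 0`) is the constant initial angle.
#'
#' @inheritParams simulate_swimmers
#' @param phi0 Initial polar angle (rad).
#' @param theta0 Initial propulsion angle (rad): the pre-history is a linear
#'   ramp \eqn{\phi(t) = \phi_0 + \theta_0 t/\delta t} for \eqn{t \le 0}, so
#'   \eqn{\theta(0) = \theta_0}.  With `theta0 = 0` the constant pre-history
#'   sits exactly on the non-rotational state.
#' @return A list of class `constrained_run` with `time`, `phi`, `theta`,
#'   and the inputs; convert with [as_trajectory()] or extract the angle
#'   series with [theta_series()].
#' @export
simulate_constrained <- function(params, config, phi0 = 0, theta0 = 0) {
  stopifnot(inherits(params, "swimmer_params"), inherits(config, "sim_config"))
  dt <- config$dt
  nsteps <- as.integer(round(config$duration / dt))
  delay_steps <- delay_in_steps(params$delta_t, dt, "delta_t")
  if (delay_steps < 1) stop("constrained run needs delta_t >= dt")
  R <- 2 * params$a
  omega0 <- params$v0 / R
  noise_sd <- sqrt(2 * params$D0 / R^2)
  set.seed(config$seed)
  out <- sim_constrained_cpp(nsteps, dt, omega0, noise_sd, delay_steps,
                             phi0, theta0, config$sample_every)
  idx <- seq_len(out$nsamp)
  structure(list(time = out$time[idx], phi = out$phi[idx],
                 theta = out$theta[idx], R = R, omega0 = omega0,
                 params = params, config = config),
            class = "constrained_run")
}

#' Convert a constrained-orbit run to a full trajectory
#'
#' Reconstructs positions `r = R (cos phi, sin phi)` and the held headings
#' \eqn{\hat u(t) = -\hat r(t - \delta t)} so that the position-based
#' propulsion-angle estimator can be applied to constrained runs.
#'
#' @param run A `constrained_run`.
#' @return A `swim_trajectory` with one particle.
#' @export
as_trajectory <- function(run) {
  stopifnot(inherits(run, "constrained_run"))
  ds <- delay_in_steps(run$params$delta_t, run$config$dt) /
    run$config$sample_every
  if (ds != round(ds))
    stop("sample_every must divide the delay steps for conversion")
  n <- length(run$time)
  phi_del <- c(rep(run$phi[1], min(ds, n)), run$phi[seq_len(max(0, n - ds))])
  x <- matrix(run$R * cos(run$phi), ncol = 1)
  y <- matrix(run$R * sin(run$phi), ncol = 1)
  ux <- matrix(-cos(phi_del), ncol = 1)
  uy <- matrix(-sin(phi_del), ncol = 1)
  new_trajectory(run$time, x, y, ux, uy, run$params, run$config)
}

#' Simulate the reduced propulsion-angle Langevin equation
#'
#' Euler--Maruyama integration of the non-delayed normal form
#' \deqn{\dot\theta = \frac{1}{3\delta t}(\theta_\pm^2 - \theta^2)\theta +
#' \sqrt{2 D_\theta}\,\eta,} i.e. diffusion in the quartic virtual
#' potential ([potential()]) at effective temperature `D_theta`.
#'
#' @param model A [reduced_model()].
#' @param duration Total time (s).
#' @param dt Integration step (s); warns if `dt > delta_t / 10`.
#' @param theta0 Initial angle (rad).
#' @param seed RNG seed.
#' @param sample_every Store every k-th step.
#' @return A `theta_series` data frame (columns `time`, `particle`,
#'   `theta`).
#' @export
simulate_reduced_theta <- function(model, duration, dt = 0.005, theta0 = 0,
                                   seed = 1L, sample_every = 1L) {
  stopifnot(inherits(model, "reduced_model"), duration > 0, dt > 0)
  if (model$delta_t <= 0) stop("reduced dynamics require delta_t > 0")
  if (dt > model$delta_t / 10)
    warning("dt > delta_t/10: the drift may be under-resolved")
  nsteps <- as.integer(round(duration / dt))
  s2 <- 6 * (1 - 1 / model$control)
  set.seed(seed)
  out <- sim_reduced_cpp(nsteps, dt, model$delta_t, s2, model$D_theta,
                         theta0, as.integer(sample_every))
  idx <- seq_len(out$nsamp)
  new_theta_series(out$time[idx], out$theta[idx], particle = 1L,
                   delta_t = model$delta_t)
}

#' Simulate a multi-particle swarm around the fixed target
#'
#' Convenience front end to [simulate_swimmers()] for `n` swimmers with
#' pairwise steric exclusion, all aiming at the common immobile target with
#' the same delayed rule.  With `n = 1` it reduces exactly to a
#' single-particle run.
#'
#' @inheritParams simulate_swimmers
#' @param n Number of active particles.
#' @return A `swim_trajectory`.
#' @export
make_multiparticle <- function(params, n, config, bias_fn = NULL) {
  config$n_particles <- as.integer(n)
  simulate_swimmers(params, config, bias_fn = bias_fn)
}
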