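#' Physical and control parameters of one swimmer experiment
#'
#' Defaults are the single-particle parameters of the feedback experiment
#' the package models: melamine spheres of radius 1.09 um, translational
#' diffusion 0.0642 um^2/s, propulsion speed 2.16 um/s, and an instrumental
#' feedback latency of 64 ms on top of the programmed delay.
#'
#' @param delta_t Programmed delay (s), non-negative.  No default: it is the
#'   experiment's control knob.
#' @param a Particle radius (um), positive.
#' @param v0 Propulsion speed (um/s), non-negative.
#' @param D0 Translational diffusion coefficient (um^2/s), non-negative.
#' @param instr_delay Instrumental latency (s), non-negative.
#' @param frame_period Feedback update interval (s); `NULL` means refresh the
#'   heading every integration step (continuous-feedback limit).
#' @return Object of class `swimmer_params`.
#' @examples
#' swimmer_params(delta_t = 1.14)
#' @export
swimmer_params <- function(delta_t, a = 1.09, v0 = 2.16, D0 = 0.0642,
                           instr_delay = 0.064, frame_period = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("%s must be a single finite number", nm))
    x
  }
  num1(delta_t, "delta_t"); num1(a, "a"); num1(v0, "v0"); num1(D0, "D0")
  num1(instr_delay, "instr_delay")
  if (a <= 0) stop("a must be > 0")
  if (v0 < 0) stop("v0 must be >= 0")
  if (D0 < 0) stop("D0 must be >= 0")
  if (delta_t < 0) stop("delta_t must be >= 0")
  if (instr_delay < 0) stop("instr_delay must be >= 0")
  if (!is.null(frame_period)) {
    num1(frame_period, "frame_period")
    if (frame_period <= 0) stop("frame_period must be > 0")
  }
  structure(list(a = a, v0 = v0, D0 = D0, delta_t = delta_t,
                 instr_delay = instr_delay, frame_period = frame_period),
            class = "swimmer_params")
}

#' @export
print.swimmer_params <- function(x, ...) {
  cat(sprintf(paste0("Swimmer parameters: a = %g um, v0 = %g um/s, ",
                     "D0 = %g um^2/s,\n  delta_t = %g s, instr_delay = %g s, ",
                     "frame_period = %s\n"),
              x$a, x$v0, x$D0, x$delta_t, x$instr_delay,
              if (is.null(x$frame_period)) "every step" else
                paste0(x$frame_period, " s")))
  invisible(x)
}

#' Simulation configuration
#'
#' @param duration Total simulated time (s).
#' @param dt Integration step (s).  The programmed + instrumental delay is
#'   rounded to the nearest multiple of `dt` for exact delay-buffer
#'   indexing; a warning is issued if the rounding changes it by more than
#'   1 percent.
#' @param n_particles Number of active particles.
#' @param seed Master RNG seed (integer).
#' @param target_fixed Is the immobile target particle physically present at
#'   the origin (steric obstacle of the same radius), or is the attraction
#'   toward a bare point?
#' @param interaction Steric contact model: `"projection"` (pairwise overlap
#'   removed along the center line each step; the immobile target reflects
#'   its half), `"harmonic"` (stiff linear repulsion), or `"none"`.
#' @param k_harmonic Stiffness (1/s) of the harmonic contact model.
#' @param initial_positions Either `"auto"` (particles placed on a ring at
#'   distance `start_radius` with equal angular spacing, respaced if
#'   overlapping) or an `n_particles` x 2 matrix of coordinates (um).
#' @param start_radius Radius (um) of the automatic initial ring placement;
#'   `NULL` picks `max(4a, (2.2 a n) / pi)` so auto-placed particles never
#'   overlap.
#' @param sample_every Store every k-th integration step (1 = every step).
#' @param escape_box Half-width (um) of the escape box; a particle leaving
#'   it stops the run early with a warning and sets the `escaped` flag.
#'   `NULL` defaults to `50 a`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duration, dt = 0.002, n_particles = 1L, seed = 1L,
                       target_fixed = TRUE,
                       interaction = c("projection", "harmonic", "none"),
                       k_harmonic = 200, initial_positions = "auto",
                       start_radius = NULL, sample_every = 1L,
                       escape_box = NULL) {
  interaction <- match.arg(interaction)
  stopifnot(is.numeric(duration), duration > 0, is.numeric(dt), dt > 0,
            duration >= dt, n_particles >= 1, sample_every >= 1)
  structure(list(duration = duration, dt = dt,
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed), target_fixed = isTRUE(target_fixed),
                 interaction = interaction, k_harmonic = k_harmonic,
                 initial_positions = initial_positions,
                 start_radius = start_radius,
                 sample_every = as.integer(sample_every),
                 escape_box = escape_box),
            class = "sim_config")
}

# Round a delay to an exact number of integration steps; warn when the
# rounding moves it by more than 1% (delay-buffer indexing must be exact).
delay_in_steps <- function(delay, dt, label = "delay") {
  steps <- as.integer(round(delay / dt))
  if (delay > 0 && abs(steps * dt - delay) > 0.01 * delay)
    warning(sprintf("%s = %g s rounded to %d steps (%g s), off by > 1%%",
                    label, delay, steps, steps * dt))
  steps
}
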