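#' Reduced model of a delayed swimmer orbiting a target
#'
#' Bundles the three parameters of the reduced propulsion-angle dynamics: the
#' natural angular velocity \eqn{\omega_0 = v_0 / R} (the angular speed of a
#' particle propelling tangentially on the contact circle of radius \eqn{R}),
#' the delay \eqn{\delta t}, and the effective angular diffusion coefficient
#' \eqn{D_\theta}.  The dimensionless product \eqn{\omega_0 \delta t} is the
#' control parameter of the pitchfork bifurcation and is stored in
#' `$control`.
#'
#' @param omega0 Natural angular velocity \eqn{v_0/R} (rad/s), positive.
#' @param delta_t Delay (s), non-negative.
#' @param D_theta Effective angular diffusion coefficient; the field's
#'   convention treats it as an effective temperature with unit 1/s.
#' @param approximate Logical flag marking models whose delay was modified by
#'   an approximate correction (see [effective_delay()]).
#' @return An object of class `reduced_model` with fields `omega0`,
#'   `delta_t`, `D_theta`, `control`, `approximate`.
#' @examples
#' m <- reduced_model(omega0 = 1, delta_t = 1.2, D_theta = 0.05)
#' theta_pm(m)
#' @export
reduced_model <- function(omega0, delta_t, D_theta = 0.05, approximate = FALSE) {
  stopifnot(is.numeric(omega0), length(omega0) == 1L, is.finite(omega0),
            is.numeric(delta_t), length(delta_t) == 1L, is.finite(delta_t),
            is.numeric(D_theta), length(D_theta) == 1L, is.finite(D_theta))
  if (omega0 <= 0) stop("omega0 must be > 0")
  if (delta_t < 0) stop("delta_t must be >= 0")
  if (D_theta < 0) stop("D_theta must be >= 0")
  structure(list(omega0 = omega0, delta_t = delta_t, D_theta = D_theta,
                 control = omega0 * delta_t,
                 approximate = isTRUE(approximate)),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("Reduced delayed-swimmer model\n")
  cat(sprintf("  omega0  = %g rad/s\n  delta_t = %g s\n  D_theta = %g 1/s\n",
              x$omega0, x$delta_t, x$D_theta))
  cat(sprintf("  control omega0*delta_t = %g (%s)%s\n", x$control,
              if (x$control < 1) "non-rotational regime"
              else if (x$control < pi / 2) "rotational regime"
              else "take-off regime",
              if (x$approximate) " [approximate delay correction]" else ""))
  invisible(x)
}

check_control <- function(control) {
  if (!is.numeric(control) || length(control) != 1L || !is.finite(control) ||
      control <= 0)
    stop("control parameter omega0*delta_t must be a finite positive number")
  control
}

#' Fixed points of the stationary aiming-angle condition
#'
#' Stationary propulsion angles solve the intersection of a line and a sine,
#' \eqn{\theta / (\omega_0\delta t) = \sin\theta}.  For control
#' \eqn{\omega_0\delta t < 1} the only intersection on \eqn{[0, \pi]} is
#' \eqn{\theta = 0} (stable); above 1 the origin is unstable and a symmetric
#' pair of stable rotational solutions \eqn{\pm\theta^*} appears.  The
#' nonzero root crosses \eqn{\pi/2} exactly at control \eqn{= \pi/2}, where
#' the orbit takes off from the contact circle.
#'
#' @param control Dimensionless control parameter \eqn{\omega_0 \delta t}.
#' @param tol Absolute tolerance of the bisection root search.
#' @return A data frame of class `fixed_point_set` with columns `theta`
#'   (rad, includes the mirrored negative roots) and `stability`
#'   (`"stable"` or `"unstable"`).
#' @examples
#' fixed_points(0.5)   # only theta = 0
#' fixed_points(1.2)   # pitchfork pair at +-1.0267 rad
#' @export
fixed_points <- function(control, tol = 1e-10) {
  check_control(control)
  theta <- 0
  stability <- if (control < 1) "stable" else "unstable"
  if (control > 1) {
    # f(theta) = theta - control*sin(theta): f < 0 just above 0, f(pi) > 0,
    # and f' = 1 - control*cos(theta) changes sign once on (0, pi), so there
    # is exactly one root there (the physical first intersection).
    f <- function(th) th - control * sin(th)
    root <- uniroot(f, lower = 1e-12, upper = pi, tol = tol,
                    check.conv = TRUE)$root
    theta <- c(theta, root, -root)
    stability <- c(stability, "stable", "stable")
  }
  structure(data.frame(theta = theta, stability = stability),
            class = c("fixed_point_set", "data.frame"), control = control)
}

#' Stationary rotational angles of the reduced quartic theory
#'
#' Closed-form pitchfork branch \eqn{\theta_\pm = \pm\sqrt{6(1 -
#' 1/(\omega_0\delta t))}}: the small-amplitude expansion of the sine
#' fixed-point condition.  Real only at and above the bifurcation
#' (control \eqn{\ge 1}); below it the radicand is negative and no
#' rotational state exists.
#'
#' @param model A [reduced_model()], or a bare numeric control parameter.
#' @return Numeric vector `c(+theta, -theta)` (rad), or `numeric(0)` below
#'   the bifurcation.
#' @export
theta_pm <- function(model) {
  control <- if (inherits(model, "reduced_model")) model$control else model
  check_control(control)
  rad <- 6 * (1 - 1 / control)
  if (rad < 0) return(numeric(0))
  th <- sqrt(rad)
  c(th, -th)
}

#' Virtual potential of the propulsion angle
#'
#' Quartic landscape \eqn{U(\theta) = \delta t^{-1}[(1/(\omega_0\delta t) -
#' 1)\theta^2 + \theta^4/12]} governing the reduced angle dynamics.  Below
#' the bifurcation it is a single well at 0; above, a symmetric double well
#' with minima at \eqn{\pm\theta_\pm}.  Units follow the effective-
#' temperature convention of `D_theta` (1/s), so that \eqn{U/D_\theta} is
#' dimensionless.
#'
#' @param theta Angle(s) in rad (vectorized).
#' @param model A [reduced_model()] with `delta_t > 0`.
#' @return Potential value(s), `U(0) = 0`.
#' @export
potential <- function(theta, model) {
  stopifnot(inherits(model, "reduced_model"))
  if (model$delta_t <= 0) stop("potential requires delta_t > 0")
  (1 / model$delta_t) *
    ((1 / model$control - 1) * theta^2 + theta^4 / 12)
}

#' Deterministic angular drift of the reduced dynamics
#'
#' \eqn{\dot\theta = (3\delta t)^{-1}(\theta_\pm^2 - \theta^2)\theta} with
#' \eqn{\theta_\pm^2 := 6(1 - 1/(\omega_0\delta t))} kept as an algebraic
#' quantity (negative below the bifurcation, where the drift is purely
#' restoring).  Identically equal to \eqn{-\partial U/\partial\theta}.
#'
#' @inheritParams potential
#' @return Drift value(s) (rad/s).
#' @export
drift <- function(theta, model) {
  stopifnot(inherits(model, "reduced_model"))
  if (model$delta_t <= 0) stop("drift requires delta_t > 0")
  s2 <- 6 * (1 - 1 / model$control)
  (s2 - theta^2) * theta / (3 * model$delta_t)
}

#' Relaxation time in the (meta)stable state
#'
#' Inverse curvature of the virtual potential at the relevant minimum:
#' \eqn{\tau = (\delta t/2)(1/(\omega_0\delta t) - 1)^{-1}} below the
#' bifurcation and \eqn{-(\delta t/4)(1/(\omega_0\delta t) - 1)^{-1}} above.
#' Diverges at the bifurcation (critical slowing down); exactly at
#' control = 1 the function returns `Inf` to report the divergence
#' explicitly.
#'
#' @param model A [reduced_model()].
#' @return Relaxation time (s), positive on both branches; `Inf` at
#'   control = 1.
#' @export
relaxation_time <- function(model) {
  stopifnot(inherits(model, "reduced_model"))
  c <- check_control(model$control)
  if (model$delta_t <= 0) stop("relaxation_time requires delta_t > 0")
  if (c == 1) return(Inf)
  if (c < 1) (model$delta_t / 2) / (1 / c - 1)
  else      -(model$delta_t / 4) / (1 / c - 1)
}

#' Kramers chirality-switching rate
#'
#' Noise-activated transition rate between the two rotational states
#' \eqn{\pm\theta_\pm} of the double-well virtual potential:
#' \deqn{k = \frac{\sqrt2}{\pi}\frac{|\omega_0\delta t - 1|}{\omega_0\delta
#' t^2} \exp\left[-\frac{3}{\delta t D_\theta}\left(\frac{1}{\omega_0\delta
#' t} - 1\right)^2\right].}
#' The prefactor is the exact Kramers prefactor
#' \eqn{\sqrt{U''(\theta_\pm)|U''(0)|}/(2\pi)} of the quartic potential and
#' the exponent is the barrier \eqn{[U(0) - U(\theta_\pm)]/D_\theta}.
#'
#' @param model A [reduced_model()] with control > 1 (double-well regime).
#' @return Switching rate (1/s); 0 when `D_theta == 0`.
#' @export
kramers_rate <- function(model) {
  stopifnot(inherits(model, "reduced_model"))
  c <- check_control(model$control)
  if (model$delta_t <= 0) stop("kramers_rate requires delta_t > 0")
  if (c <= 1) stop("kramers_rate requires control > 1 (no barrier below the bifurcation)")
  if (model$D_theta == 0) return(0)
  pref <- sqrt(2) / pi * abs(c - 1) / (model$omega0 * model$delta_t^2)
  barrier_over_D <- 3 / (model$delta_t * model$D_theta) * (1 / c - 1)^2
  pref * exp(-barrier_over_D)
}

#' Radius of the free take-off orbit
#'
#' Beyond control \eqn{= \pi/2} the rotational fixed point exceeds
#' \eqn{|\theta| = \pi/2}, radial propulsion turns repulsive and the orbit
#' expands until the delay phase \eqn{\omega\delta t = \pi/2} is restored on
#' a larger circle: \eqn{R = 2 v_0 \delta t / \pi}.
#'
#' @param v0 Propulsion speed (um/s), positive.
#' @param delta_t Delay (s), positive.
#' @return Orbit radius (um).
#' @export
takeoff_orbit_radius <- function(v0, delta_t) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(delta_t), length(delta_t) == 1L, is.finite(delta_t))
  if (v0 <= 0) stop("v0 must be > 0")
  if (delta_t <= 0) stop("delta_t must be > 0")
  2 * v0 * delta_t / pi
}

#' Fold an instrumental latency into the model delay
#'
#' Returns a model whose delay is the programmed delay plus the feedback
#' loop's instrumental latency, `delta_t + instrumental_delay`.  This
#' additive surrogate captures the direction of the effect (the bifurcation
#' occurs at a smaller programmed delay) but not the exact refined delay
#' dynamics, so the result is flagged `approximate`.
#'
#' @param model A [reduced_model()].
#' @param instrumental_delay Latency (s), non-negative.
#' @return A new `reduced_model` with the combined delay and
#'   `approximate = TRUE`.
#' @export
effective_delay <- function(model, instrumental_delay) {
  stopifnot(inherits(model, "reduced_model"),
            is.numeric(instrumental_delay), length(instrumental_delay) == 1L,
            is.finite(instrumental_delay))
  if (instrumental_delay < 0) stop("instrumental_delay must be >= 0")
  reduced_model(model$omega0, model$delta_t + instrumental_delay,
                model$D_theta, approximate = instrumental_delay > 0)
}
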