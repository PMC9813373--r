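new_theta_series <- function(time, theta, particle = 1L, delta_t = NA_real_) {
  structure(data.frame(time = time, particle = particle, theta = theta),
            class = c("theta_series", "data.frame"), delta_t = delta_t)
}

#' Signed propulsion angle from a trajectory
#'
#' The central observable: the signed angle \eqn{\theta =
#' \angle(\hat u, -r)} between the realized propulsion direction and the
#' instantaneous direction toward the target, computed per particle and
#' sample as `atan2` of the z-component of \eqn{\hat r \times \hat u}
#' (which fixes the sign: positive = counter-clockwise aiming error) and of
#' \eqn{\hat u \cdot (-\hat r)}.  Wrapped to \eqn{(-\pi, \pi]}.  Samples
#' with \eqn{|r| < 10^{-9}} um are excluded as invalid.
#'
#' @param traj A `swim_trajectory`.
#' @return A `theta_series` data frame with columns `time`, `particle`,
#'   `theta` (rad).
#' @export
propulsion_angle <- function(traj) {
  stopifnot(inherits(traj, "swim_trajectory"))
  n <- ncol(traj$x)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rx <- traj$x[, i]; ry <- traj$y[, i]
    r <- sqrt(rx^2 + ry^2)
    ok <- r >= 1e-9
    cr <- (rx * traj$uy[, i] - ry * traj$ux[, i]) / r   # (r_hat x u).e_z
    dp <- -(rx * traj$ux[, i] + ry * traj$uy[, i]) / r  # u . (-r_hat)
    th <- atan2(cr, dp)
    out[[i]] <- data.frame(time = traj$time[ok], particle = i,
                           theta = th[ok])
  }
  res <- do.call(rbind, out)
  structure(res, class = c("theta_series", "data.frame"),
            delta_t = traj$params$delta_t)
}

#' Rotational order parameter
#'
#' Per-sample \eqn{o_R = (\hat r \times \hat u) \cdot e_z = \sin\theta}:
#' +1 for purely tangential counter-clockwise propulsion, -1 for clockwise,
#' 0 for perfect aim.
#'
#' @param x A `swim_trajectory` or a `theta_series`.
#' @return A data frame with columns `time`, `particle`, `o_R` in
#'   \eqn{[-1, 1]}.
#' @export
order_parameter <- function(x) {
  if (inherits(x, "swim_trajectory")) x <- propulsion_angle(x)
  stopifnot(inherits(x, "theta_series"))
  data.frame(time = x$time, particle = x$particle, o_R = sin(x$theta))
}

#' Normalized histogram of the propulsion angle
#'
#' Probability mass over uniform bins on \eqn{(-\pi, \pi]}; the default 73
#' bins give roughly 5-degree resolution.
#'
#' @param series A `theta_series` (or numeric vector of angles in rad).
#' @param bins Number of uniform bins.
#' @return Data frame of class `angle_histogram` with columns `theta` (bin
#'   midpoint), `p` (probability mass, sums to 1) and `width`.
#' @export
angle_histogram <- function(series, bins = 73L) {
  th <- if (is.data.frame(series)) series$theta else as.numeric(series)
  th <- th[is.finite(th)]
  if (length(th) == 0) stop("empty angle series")
  if (length(th) < 1000)
    warning("fewer than 1000 samples: histogram will be noisy")
  breaks <- seq(-pi, pi, length.out = bins + 1L)
  idx <- findInterval(th, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(data.frame(theta = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
                       p = counts / sum(counts),
                       width = diff(breaks)),
            class = c("angle_histogram", "data.frame"), n = length(th))
}

#' Potential of mean force and effective-temperature fit
#'
#' Fits the stationary histogram with the Boltzmann-like density
#' \eqn{\exp(-U(\theta)/D_\theta)/Z} built from the model's quartic virtual
#' potential, with the effective temperature \eqn{D_\theta} as the single
#' free parameter (least squares on log-probabilities over occupied bins).
#' Also returns the measured potential of mean force
#' \eqn{-D_\theta \log p(\theta)}, gauge-fixed so its minimum is 0.
#'
#' @param p An [angle_histogram()].
#' @param model A [reduced_model()] supplying \eqn{U(\theta)}; its
#'   `D_theta` is ignored (it is what gets fitted).
#' @param interval Search interval for \eqn{D_\theta} (1/s).
#' @return List with `pmf` (data frame `theta`, `pmf` over occupied bins)
#'   and `D_theta_fit`.
#' @export
pmf_and_fit_Dtheta <- function(p, model, interval = c(1e-4, 5)) {
  stopifnot(inherits(p, "angle_histogram"), inherits(model, "reduced_model"))
  occ <- p$p > 0
  if (sum(occ) < 5) stop("fewer than 5 occupied bins: cannot fit D_theta")
  # bin probabilities by within-bin Simpson quadrature of exp(-U/D): midpoint
  # evaluation is badly biased when the well is narrower than a bin
  nq <- 9L
  qw <- c(1, rep(c(4, 2), (nq - 3) / 2), 4, 1)  # Simpson weights
  qoff <- seq(-0.5, 0.5, length.out = nq)
  Uq <- vapply(seq_len(nrow(p)), function(i)
    potential(p$theta[i] + qoff * p$width[i], model), numeric(nq))
  bin_mass <- function(D) {
    m <- colSums(qw * exp(-Uq / D))   # ~ integral / (h/3), common factor
    m / sum(m)
  }
  obj <- function(logD) {
    pm <- bin_mass(exp(logD))
    sum((log(p$p[occ]) - log(pm[occ]))^2)
  }
  D_fit <- exp(optimize(obj, interval = log(interval))$minimum)
  pmf <- -D_fit * log(p$p[occ] / p$width[occ])
  list(pmf = data.frame(theta = p$theta[occ], pmf = pmf - min(pmf)),
       D_theta_fit = D_fit)
}

#' Normalized autocorrelation of the propulsion-angle fluctuations
#'
#' \eqn{C(t) = \langle\delta\theta(t' + t)\delta\theta(t')\rangle /
#' \langle\delta\theta^2\rangle} with \eqn{\delta\theta = \theta -
#' \langle\theta\rangle}, so that \eqn{C(0) = 1}.  Computed up to lags of
#' one fifth of the series duration.
#'
#' @param series A `theta_series` for a single particle (or numeric
#'   vector), assumed stationary and uniformly sampled.
#' @param max_lag Maximum lag (s); default duration/5.
#' @return Data frame with columns `lag` (s) and `C`.
#' @export
autocorrelation <- function(series, max_lag = NULL) {
  if (is.data.frame(series)) {
    if (length(unique(series$particle)) > 1)
      stop("autocorrelation expects a single-particle series")
    th <- series$theta
    dt <- stats::median(diff(series$time))
  } else {
    th <- as.numeric(series)
    dt <- 1
  }
  n <- length(th)
  if (is.null(max_lag)) max_lag <- (n - 1) * dt / 5
  lag_max <- max(1L, min(n - 1L, as.integer(floor(max_lag / dt))))
  a <- stats::acf(th, lag.max = lag_max, plot = FALSE, demean = TRUE)
  data.frame(lag = (0:lag_max) * dt, C = as.numeric(a$acf))
}

#' Relaxation time from the 1/e crossing of the autocorrelation
#'
#' The first lag at which \eqn{C(t)} drops below \eqn{1/e}, linearly
#' interpolated between lag samples.
#'
#' @param C Data frame from [autocorrelation()] (columns `lag`, `C`).
#' @return Relaxation time (s).
#' @export
relaxation_time_from_acf <- function(C) {
  stopifnot(is.data.frame(C), all(c("lag", "C") %in% names(C)))
  thr <- exp(-1)
  below <- which(C$C < thr)
  if (length(below) == 0)
    stop("underresolved: autocorrelation never crosses 1/e in the lag range")
  i <- below[1]
  if (i == 1) return(0)
  # linear interpolation between the bracketing lags
  C$lag[i - 1] + (thr - C$C[i - 1]) * (C$lag[i] - C$lag[i - 1]) /
    (C$C[i] - C$C[i - 1])
}

#' Chirality-switching rate from residence times
#'
#' Counts committed transitions between the two rotational wells with a
#' hysteresis scheme: a switch is registered only when \eqn{\theta} crosses
#' from beyond \eqn{+\theta_h} to beyond \eqn{-\theta_h} or vice versa
#' (default \eqn{\theta_h = \theta_\pm/2}).  The rate is the inverse mean
#' residence time between committed switches.
#'
#' @param series A `theta_series` (single particle) or numeric vector.
#' @param theta_h Hysteresis threshold (rad); default `theta_pm(model)/2`.
#' @param model A [reduced_model()], used only to default `theta_h`.
#' @return Switching rate (1/s) with attributes `n_switches` and
#'   `wide_uncertainty` (TRUE when fewer than 5 switches were seen).
#' @export
switching_rate <- function(series, theta_h = NULL, model = NULL) {
  if (is.data.frame(series)) {
    th <- series$theta; tm <- series$time
  } else {
    th <- as.numeric(series); tm <- seq_along(th) - 1
  }
  if (is.null(theta_h)) {
    if (is.null(model)) stop("supply theta_h or a model to default it from")
    tp <- theta_pm(model)
    if (length(tp) == 0) stop("model is below the bifurcation: no wells")
    theta_h <- tp[1] / 2
  }
  state <- 0L
  switch_times <- numeric(0)
  for (i in seq_along(th)) {
    s <- if (th[i] > theta_h) 1L else if (th[i] < -theta_h) -1L else 0L
    if (s != 0L && s != state) {
      if (state != 0L) switch_times <- c(switch_times, tm[i])
      state <- s
    }
  }
  n_sw <- length(switch_times)
  if (n_sw == 0) {
    rate <- 0
  } else {
    first_commit <- tm[which(abs(th) > theta_h)[1]]
    res <- diff(c(first_commit, switch_times))
    rate <- 1 / mean(res)
  }
  wide <- n_sw < 5
  if (wide) warning("fewer than 5 switches observed: rate has wide uncertainty")
  structure(rate, n_switches = n_sw, wide_uncertainty = wide)
}

burn_in_time <- function(params, R = NULL) {
  if (is.null(R)) R <- 2 * params$a
  control <- params$v0 / R * (params$delta_t + params$instr_delay)
  tau <- if (control > 0 && abs(control - 1) > 0.02)
    relaxation_time(reduced_model(params$v0 / R,
                                  params$delta_t + params$instr_delay))
  else 20
  max(5 * params$delta_t, 5 * min(tau, 20))
}

#' Drop the initial transient of an angle series
#'
#' Discards the first `max(5 delta_t, 5 tau_est)` seconds (pre-history
#' initialization artifact), with the relaxation-time estimate capped at
#' 20 s near the critical point.
#'
#' @param series A `theta_series`.
#' @param params The [swimmer_params()] of the generating run.
#' @param R Contact radius used for the control-parameter estimate
#'   (default `2 a`).
#' @return The truncated `theta_series`.
#' @export
discard_burnin <- function(series, params, R = NULL) {
  tb <- burn_in_time(params, R)
  keep <- series$time >= tb
  structure(series[keep, , drop = FALSE],
            class = class(series), delta_t = attr(series, "delta_t"))
}

#' Kernel-smoothed modes of the signed angle distribution
#'
#' Most probable positive and negative propulsion angles, extracted from a
#' kernel density estimate whose bandwidth defaults to one histogram bin
#' width (~5 degrees).
#'
#' @param th A `theta_series` or numeric vector of angles (rad).
#' @param bw Kernel bandwidth (rad).
#' @return Named vector `c(mode_pos, mode_neg)` (rad); `NA` for an
#'   unoccupied sign.
#' @export
theta_modes <- function(th, bw = 2 * pi / 73) {
  if (is.data.frame(th)) th <- th$theta
  d_pos <- if (any(th >= 0)) density(th[th >= 0], bw = bw, from = 0, to = pi)
  d_neg <- if (any(th < 0)) density(th[th < 0], bw = bw, from = -pi, to = 0)
  c(mode_pos = if (is.null(d_pos)) NA_real_ else d_pos$x[which.max(d_pos$y)],
    mode_neg = if (is.null(d_neg)) NA_real_ else d_neg$x[which.max(d_neg$y)])
}

#' Kernel-smoothed mode of the propulsion-angle magnitude
#'
#' @param series A `theta_series` or numeric vector of angles (rad).
#' @param bw Kernel bandwidth (rad); default one histogram bin width
#'   (~5 degrees).
#' @return Location (rad) of the maximum of the kernel density of
#'   \eqn{|\theta|}.
#' @export
mode_abs_theta <- function(series, bw = 2 * pi / 73) {
  th <- if (is.data.frame(series)) series$theta else as.numeric(series)
  d <- density(abs(th), bw = bw, from = 0, to = pi)
  d$x[which.max(d$y)]
}

#' Bifurcation scan over programmed delays
#'
#' For each delay: simulate the full dynamics, discard the burn-in, build
#' the kernel-smoothed angle distribution and report its positive and
#' negative modes together with the control parameter
#' \eqn{\omega_0\delta t}, where \eqn{\omega_0 = v_0/R} and \eqn{R} is the
#' run-mean distance to the target (2a when the target obstacle is present
#' and the particle stays at contact).
#'
#' @param params A [swimmer_params()]; its `delta_t` is replaced by each
#'   scanned value.
#' @param delays Vector of programmed delays (s).
#' @param config A [sim_config()]; the seed is advanced per delay for
#'   independent runs.
#' @param use_total_delay Include `instr_delay` in the control parameter
#'   (the physically effective delay); default TRUE.
#' @return Data frame with columns `delta_t`, `R`, `control`, `mode_pos`,
#'   `mode_neg` (rad).
#' @export
bifurcation_scan <- function(params, delays, config, use_total_delay = TRUE) {
  rows <- lapply(seq_along(delays), function(k) {
    p <- params; p$delta_t <- delays[k]
    cf <- config; cf$seed <- config$seed + k - 1L
    tr <- simulate_swimmers(p, cf)
    if (isTRUE(tr$escaped)) return(NULL)  # non-converged run: excluded
    ser <- discard_burnin(propulsion_angle(tr), p)
    R <- mean(sqrt(tr$x[, 1]^2 + tr$y[, 1]^2))
    eff_dt <- delays[k] + if (use_total_delay) p$instr_delay else 0
    m <- theta_modes(ser$theta)
    data.frame(delta_t = delays[k], R = R, control = p$v0 / R * eff_dt,
               mode_pos = m[["mode_pos"]], mode_neg = m[["mode_neg"]])
  })
  do.call(rbind, rows)
}

#' Full analysis report for one angle series
#'
#' Bundles the estimation pipeline: histogram, potential of mean force with
#' fitted effective temperature, modes, autocorrelation relaxation time and
#' (in the bimodal regime) the residence-time switching rate.
#'
#' @param series A `theta_series` (burn-in already removed).
#' @param model A [reduced_model()] for the potential shape and thresholds.
#' @param bins Histogram bins.
#' @return List of class `analysis_report`.
#' @export
analysis_report <- function(series, model, bins = 73L) {
  h <- angle_histogram(series, bins = bins)
  fit <- pmf_and_fit_Dtheta(h, model)
  C <- autocorrelation(series)
  tau <- tryCatch(relaxation_time_from_acf(C), error = function(e) NA_real_)
  tp <- theta_pm(model)
  rate <- if (length(tp) > 0)
    tryCatch(suppressWarnings(
      as.numeric(switching_rate(series, model = model))),
      error = function(e) NA_real_)
  else NA_real_
  m <- theta_modes(series$theta)
  structure(list(histogram = h, pmf = fit$pmf,
                 D_theta_fit = fit$D_theta_fit,
                 modes = m, tau = tau, rate = rate,
                 control = model$control, model = model),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Propulsion-angle analysis report\n")
  cat(sprintf("  control omega0*delta_t = %.4g\n", x$control))
  cat(sprintf("  modes: +%.3f / %.3f rad\n", x$modes[["mode_pos"]],
              x$modes[["mode_neg"]]))
  cat(sprintf("  D_theta (fit) = %.4g 1/s\n", x$D_theta_fit))
  cat(sprintf("  relaxation time tau = %.3g s\n", x$tau))
  cat(sprintf("  switching rate k = %.3g 1/s\n", x$rate))
  invisible(x)
}

#' Extract the angle series of a constrained run
#'
#' @param run A `constrained_run` from [simulate_constrained()].
#' @return A `theta_series` with the delay-difference angle
#'   \eqn{\theta(t) = \phi(t) - \phi(t - \delta t)}.
#' @export
theta_series <- function(run) {
  stopifnot(inherits(run, "constrained_run"))
  new_theta_series(run$time, run$theta, particle = 1L,
                   delta_t = run$params$delta_t)
}
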