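test_that("propulsion angle has the documented sign convention", {
  tr <- make_traj(time = 0:2,
                  x = c(1, 1, 1), y = c(0, 0, 0),
                  ux = c(-1, 0, 0), uy = c(0, 1, -1))
  ser <- propulsion_angle(tr)
  expect_equal(ser$theta, c(0, pi / 2, -pi / 2))
  # sign(theta) equals the sign of the rotational order parameter
  set.seed(4)
  ang_u <- runif(200, -pi, pi); ang_r <- runif(200, -pi, pi)
  tr2 <- make_traj(time = seq_len(200), x = cos(ang_r), y = sin(ang_r),
                   ux = cos(ang_u), uy = sin(ang_u))
  ser2 <- propulsion_angle(tr2)
  oR <- order_parameter(tr2)$o_R
  expect_equal(oR, sin(ser2$theta), tolerance = 1e-12)
  nz <- abs(oR) > 1e-9
  expect_equal(sign(ser2$theta[nz]), sign(oR[nz]))
  expect_true(all(abs(ser2$theta) <= pi))
  # samples at the target center are excluded as invalid
  tr3 <- make_traj(time = 0:1, x = c(1e-12, 1), y = c(0, 0),
                   ux = c(1, -1), uy = c(0, 0))
  expect_equal(nrow(propulsion_angle(tr3)), 1L)
})

test_that("angle histogram is a normalized probability over (-pi, pi]", {
  set.seed(9)
  u <- runif(50000, -pi, pi)
  h <- angle_histogram(u)
  expect_equal(sum(h$p), 1)
  expect_equal(nrow(h), 73L)
  expect_true(all(abs(h$p - 1 / 73) < 5 * sqrt((1 / 73) / 50000)))
  # delta-like series occupies a single bin
  hd <- suppressWarnings(angle_histogram(rep(0.5, 10)))
  expect_equal(sum(hd$p > 0), 1L)
  expect_error(angle_histogram(numeric(0)))
  expect_warning(angle_histogram(runif(10, -1, 1)), "1000")
})

test_that("effective temperature is recovered from Boltzmann-distributed angles", {
  m <- reduced_model(1, 1.2, 0.05)
  samp <- sample_boltzmann(1e5, m, D = 0.05, seed = 5)
  h <- angle_histogram(samp)
  fit <- pmf_and_fit_Dtheta(h, m)
  expect_equal(fit$D_theta_fit, 0.05, tolerance = 0.1)
  # normalization invariance: doubling all counts changes nothing
  h2 <- angle_histogram(c(samp, samp))
  expect_equal(pmf_and_fit_Dtheta(h2, m)$D_theta_fit, fit$D_theta_fit,
               tolerance = 1e-6)
  # gauge: the measured potential of mean force has minimum 0
  expect_equal(min(fit$pmf$pmf), 0)
  # quadratic-well limit: fit agrees with the curvature-variance estimate
  m3 <- reduced_model(1, 0.5, 0.02)   # control 0.5, nearly Gaussian well
  Upp <- (2 / m3$delta_t) * (1 / m3$control - 1)
  set.seed(6)
  g <- rnorm(2e5, sd = sqrt(0.02 / Upp))
  fit3 <- pmf_and_fit_Dtheta(angle_histogram(g), m3)
  expect_equal(fit3$D_theta_fit, Upp * var(g), tolerance = 0.05)
  expect_error(pmf_and_fit_Dtheta(suppressWarnings(
    angle_histogram(rep(0.1, 2000))), m), "occupied")
})

test_that("autocorrelation and its 1/e crossing measure the relaxation time", {
  # exact exponential table
  C <- data.frame(lag = seq(0, 20, by = 0.1), C = exp(-seq(0, 20, by = 0.1) / 3))
  expect_equal(relaxation_time_from_acf(C), 3.0, tolerance = 0.05 / 3)
  # white noise decorrelates immediately (first 20 lags)
  set.seed(11)
  Cw <- autocorrelation(rnorm(20000), max_lag = 20)
  expect_lt(max(abs(Cw$C[-1])), 3 / sqrt(20000))
  expect_equal(Cw$C[1], 1)
  # AR(1) emulation of linear relaxation with tau = 2 s
  dt <- 0.05; tau <- 2; n <- 2e5
  set.seed(12)
  x <- numeric(n); ee <- rnorm(n)
  for (k in 2:n) x[k] <- x[k - 1] * exp(-dt / tau) +
      sqrt(1 - exp(-2 * dt / tau)) * ee[k]
  ser <- data.frame(time = (seq_len(n) - 1) * dt, particle = 1, theta = x)
  Ca <- autocorrelation(ser, max_lag = 10)
  i <- which.min(abs(Ca$lag - tau))
  expect_equal(Ca$C[i], exp(-1), tolerance = 0.05)
  expect_equal(relaxation_time_from_acf(Ca), tau, tolerance = 0.05)
  # no crossing -> underresolved error
  expect_error(relaxation_time_from_acf(
    data.frame(lag = 0:3, C = c(1, 0.9, 0.8, 0.7))), "underresolved")
})

test_that("reduced-model relaxation matches the curvature prediction", {
  m <- reduced_model(0.5 / 0.5, 0.5, 0.01)   # control 0.5, tau = 0.25 s
  ser <- simulate_reduced_theta(m, duration = 1500, dt = 0.005, seed = 13,
                                sample_every = 4)
  tau_hat <- relaxation_time_from_acf(autocorrelation(ser))
  expect_equal(tau_hat, relaxation_time(m), tolerance = 0.25)
})

test_that("switching rate recovers telegraph dwell rates with hysteresis", {
  # synthetic telegraph signal with exponential dwell times, rate 0.02 1/s
  set.seed(14)
  rate <- 0.02; dt <- 0.5
  dwell <- rexp(400, rate)
  state <- rep(rep(c(1, -1), length.out = 400), times = pmax(1, round(dwell / dt)))
  tm <- (seq_along(state) - 1) * dt
  ser <- data.frame(time = tm, particle = 1, theta = state * 1.0)
  k_hat <- switching_rate(ser, theta_h = 0.5)
  expect_equal(as.numeric(k_hat), rate, tolerance = 0.2)
  expect_gt(attr(k_hat, "n_switches"), 100)
  # monotone series: no switches, rate 0, wide-uncertainty flag
  mono <- data.frame(time = 0:100, particle = 1, theta = seq(0, 2, length.out = 101))
  expect_warning(k0 <- switching_rate(mono, theta_h = 0.5), "wide uncertainty")
  expect_equal(as.numeric(k0), 0)
  expect_equal(attr(k0, "n_switches"), 0L)
  # hysteresis: excursions that do not reach the far threshold do not count
  wob <- data.frame(time = 0:5, particle = 1,
                    theta = c(1, 0.2, -0.3, 0.2, 1, 1))
  expect_warning(kw <- switching_rate(wob, theta_h = 0.5))
  expect_equal(attr(kw, "n_switches"), 0L)
})

test_that("position-based and delay-difference angle definitions agree", {
  p <- swimmer_params(delta_t = 1.2 * 2.18 / 2.16, v0 = 2.16, a = 1.09,
                      instr_delay = 0)
  cf <- sim_config(duration = 60, dt = 0.002, seed = 15, sample_every = 2)
  run <- simulate_constrained(p, cf, theta0 = 0.3)
  tr <- as_trajectory(run)
  ser <- propulsion_angle(tr)
  sel <- run$time > p$delta_t          # past the pre-history ramp
  expect_equal(ser$theta[sel], run$theta[sel], tolerance = 1e-6)
})

test_that("mean rotational order vanishes over many chirality switches", {
  m <- reduced_model(1, 1.2, 0.2)      # shallow wells: frequent switching
  ser <- simulate_reduced_theta(m, duration = 3e4, dt = 0.005, seed = 16,
                                sample_every = 100)
  oR <- sin(ser$theta)
  blocks <- split(oR, floor(ser$time / 500))
  bm <- vapply(blocks, mean, 0)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(oR)), 3 * se)
})

test_that("bifurcation scan separates the regimes with symmetric modes", {
  p <- swimmer_params(delta_t = 1, instr_delay = 0)
  cf <- sim_config(duration = 150, dt = 0.002, seed = 18, sample_every = 5,
                   initial_positions = matrix(c(2.18, 0), 1))
  sc <- bifurcation_scan(p, delays = c(0.3, 1.3), config = cf)
  expect_equal(nrow(sc), 2L)
  # subcritical: both modes at the origin
  expect_lt(abs(sc$mode_pos[1]), 0.15)
  expect_lt(abs(sc$mode_neg[1]), 0.15)
  # supercritical: modes near the sine fixed point, mirror-symmetric
  expect_gt(sc$control[2], 1)
  thstar <- max(fixed_points(sc$control[2])$theta)
  expect_equal(sc$mode_pos[2], thstar, tolerance = 0.2)
  expect_equal(sc$mode_pos[2], -sc$mode_neg[2], tolerance = 0.2)
  expect_gt(sc$control[2], sc$control[1])
})

test_that("analysis report bundles the pipeline consistently", {
  m <- reduced_model(1, 1.2, 0.05)
  ser <- simulate_reduced_theta(m, duration = 2e4, dt = 0.005, seed = 19,
                                sample_every = 40)
  rep <- analysis_report(ser, m)
  expect_equal(rep$D_theta_fit, 0.05, tolerance = 0.2)
  expect_equal(rep$modes[["mode_pos"]], 1, tolerance = 0.15)
  expect_equal(sum(rep$histogram$p), 1)
  expect_equal(min(rep$pmf$pmf), 0)
  expect_gt(rep$rate, 0)
  out <- capture.output(print(rep))
  expect_true(any(grepl("switching rate", out)))
})
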