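test_that("aim_direction is the negative normalized delayed position", {
  hist <- data.frame(time = c(0, 1, 2), x = c(3, 1, 0), y = c(4, 0, 2))
  expect_equal(aim_direction(hist, t = 2, delta_total = 2), c(-0.6, -0.8))
  hist2 <- data.frame(time = 0:1, x = c(-1, 5), y = c(0, 5))
  expect_equal(aim_direction(hist2, t = 1, delta_total = 1), c(1, 0))
  set.seed(3)
  for (k in 1:50) {
    h <- data.frame(time = 0:3, x = rnorm(4), y = rnorm(4))
    u <- aim_direction(h, t = 3, delta_total = runif(1, 0, 3))
    expect_equal(sum(u^2), 1, tolerance = 1e-12)
  }
  expect_error(aim_direction(data.frame(time = 0, x = 0, y = 0), 1, 1),
               "undefined aim")
  expect_error(aim_direction(hist, t = 1, delta_total = 5), "cover")
})

test_that("identical seed and config give bitwise-identical trajectories", {
  p <- swimmer_params(delta_t = 0.5)
  cf <- sim_config(duration = 5, dt = 0.002, n_particles = 3, seed = 99)
  t1 <- simulate_swimmers(p, cf)
  t2 <- simulate_swimmers(p, cf)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$ux, t2$ux)
  cf$seed <- 100L
  t3 <- simulate_swimmers(p, cf)
  expect_false(identical(t1$x, t3$x))
})

test_that("passive particles recover free Brownian motion", {
  # v0 = 0: ensemble MSD must equal 4 D0 t; 1000 independent walkers in one run
  p <- swimmer_params(delta_t = 0, v0 = 0, D0 = 0.0642, instr_delay = 0)
  cf <- sim_config(duration = 2, dt = 0.01, n_particles = 1000, seed = 5,
                   target_fixed = FALSE, interaction = "none",
                   initial_positions = matrix(0, 1000, 2), escape_box = 1e6)
  tr <- simulate_swimmers(p, cf)
  for (ti in c(1, 2)) {
    k <- which.min(abs(tr$time - ti))
    msd <- mean(tr$x[k, ]^2 + tr$y[k, ]^2)
    expect_equal(msd, 4 * p$D0 * tr$time[k], tolerance = 0.05)
  }
})

test_that("zero-delay pursuit runs straight into contact", {
  p <- swimmer_params(delta_t = 0, v0 = 2, D0 = 0, instr_delay = 0, a = 1.09)
  cf <- sim_config(duration = 5, dt = 0.002, seed = 1,
                   initial_positions = matrix(c(5, 0), 1))
  tr <- simulate_swimmers(p, cf)
  r_final <- sqrt(tail(tr$x[, 1], 1)^2 + tail(tr$y[, 1], 1)^2)
  expect_equal(r_final, 2 * p$a, tolerance = 1e-9)
  expect_true(all(abs(tr$y[, 1]) < 1e-12))   # no rotation
})

test_that("deterministic retarded pursuit settles on the take-off orbit", {
  p <- swimmer_params(delta_t = 0.5, v0 = 2, D0 = 0, instr_delay = 0)
  cf <- sim_config(duration = 60, dt = 0.002, seed = 1, target_fixed = FALSE,
                   interaction = "none", sample_every = 10,
                   initial_positions = matrix(c(3, 0.2), 1))
  tr <- simulate_swimmers(p, cf)
  r <- sqrt(tr$x[, 1]^2 + tr$y[, 1]^2)
  expect_equal(mean(tail(r, 500)), takeoff_orbit_radius(2, 0.5),
               tolerance = 0.02)
})

test_that("zero-delay stationary radial density decays beyond contact", {
  # barometer-formula regime: propulsion presses the particle onto the
  # obstacle, diffusion lifts it off; density falls monotonically with r
  p <- swimmer_params(delta_t = 0, v0 = 0.3, D0 = 0.0642, instr_delay = 0)
  cf <- sim_config(duration = 400, dt = 0.002, seed = 8, sample_every = 10,
                   initial_positions = matrix(c(2.5, 0), 1))
  tr <- simulate_swimmers(p, cf)
  r <- sqrt(tr$x[, 1]^2 + tr$y[, 1]^2)
  r <- r[tr$time > 20]
  bin <- findInterval(r, 2 * p$a + c(0, 0.15, 0.3, 0.45))
  counts <- tabulate(bin, nbins = 3)   # occupancy of the first 3 bins
  expect_true(all(diff(counts) < 0))
})

test_that("constrained delay oscillator reaches the theoretical fixed points", {
  # control < 1, noise off: the isotropic state attracts
  psub <- swimmer_params(delta_t = 0.5 * 2.18 / 2.16, v0 = 2.16, a = 1.09,
                         D0 = 0, instr_delay = 0)
  run <- simulate_constrained(psub, sim_config(duration = 60, dt = 0.002),
                              theta0 = 0.4)
  expect_lt(abs(tail(run$theta, 1)), 1e-6)

  # control = 1.2, noise off: |theta| converges to the sine fixed point
  psup <- swimmer_params(delta_t = 1.2 * 2.18 / 2.16, v0 = 2.16, a = 1.09,
                         D0 = 0, instr_delay = 0)
  run2 <- simulate_constrained(psup, sim_config(duration = 200, dt = 0.002),
                               theta0 = 0.1)
  expect_equal(abs(tail(run2$theta, 1)), max(fixed_points(1.2)$theta),
               tolerance = 5e-3)

  # rotational symmetry: a global rotation of the initial history leaves the
  # propulsion-angle series unchanged (same noise stream)
  pn <- swimmer_params(delta_t = 1.2 * 2.18 / 2.16, v0 = 2.16, a = 1.09,
                       instr_delay = 0)
  cfn <- sim_config(duration = 30, dt = 0.002, seed = 17)
  rA <- simulate_constrained(pn, cfn, phi0 = 0, theta0 = 0.2)
  rB <- simulate_constrained(pn, cfn, phi0 = 2.1, theta0 = 0.2)
  expect_equal(rA$theta, rB$theta, tolerance = 1e-12)
})

test_that("reduced angle equation relaxes to theta_pm and warns on coarse dt", {
  m <- reduced_model(0.9 / 1.1, 1.1, 0)    # control 0.9
  ser <- simulate_reduced_theta(m, duration = 100, dt = 0.005, theta0 = 0.3)
  expect_lt(abs(tail(ser$theta, 1)), 1e-6)

  m2 <- reduced_model(1.2, 1, 0)           # control 1.2, theta_pm = 1
  ser2 <- simulate_reduced_theta(m2, duration = 100, dt = 0.005, theta0 = 0.1)
  expect_equal(tail(ser2$theta, 1), 1, tolerance = 1e-6)

  expect_warning(simulate_reduced_theta(m2, duration = 1, dt = 0.2),
                 "under-resolved")
})

test_that("constrained and full dynamics agree on the angle mode at control 1.2", {
  delta <- 1.2 * 2.18 / 2.16
  p <- swimmer_params(delta_t = delta, v0 = 2.16, a = 1.09, instr_delay = 0)
  cf <- sim_config(duration = 400, dt = 0.002, seed = 21, sample_every = 5,
                   initial_positions = matrix(c(2.18, 0), 1))
  full <- discard_burnin(propulsion_angle(simulate_swimmers(p, cf)), p)
  cons <- simulate_constrained(p, sim_config(duration = 400, dt = 0.002,
                                             seed = 22, sample_every = 5),
                               theta0 = 0.5)
  th_c <- cons$theta[cons$time > 20]
  expect_equal(mode_abs_theta(full), mode_abs_theta(th_c), tolerance = 0.1)
})

test_that("multi-particle runs respect steric exclusion and reduce to n = 1", {
  p <- swimmer_params(delta_t = 1)
  cf <- sim_config(duration = 20, dt = 0.002, seed = 31, sample_every = 10)
  one <- simulate_swimmers(p, cf)
  also_one <- make_multiparticle(p, 1, cf)
  expect_identical(one$x, also_one$x)

  multi <- make_multiparticle(p, 8, sim_config(duration = 30, dt = 0.002,
                                               seed = 32, sample_every = 10))
  # no inter-center distance below contact (projection tolerance)
  n <- ncol(multi$x)
  for (k in seq(1, length(multi$time), by = 7)) {
    pos <- cbind(multi$x[k, ], multi$y[k, ])
    d <- as.matrix(dist(pos)); diag(d) <- Inf
    expect_gt(min(d), 2 * p$a - 1e-5)
    expect_gt(min(sqrt(rowSums(pos^2))), 2 * p$a - 1e-5)  # target contact
  }
  # headings stay unit norm
  expect_lt(max(abs(sqrt(multi$ux^2 + multi$uy^2) - 1)), 1e-9)
})

test_that("escaping particles stop the run early with a warning", {
  p <- swimmer_params(delta_t = 2, v0 = 2, D0 = 0, instr_delay = 0)
  cf <- sim_config(duration = 100, dt = 0.002, target_fixed = FALSE,
                   interaction = "none", escape_box = 2.0,
                   initial_positions = matrix(c(1.5, 0.2), 1))
  expect_warning(tr <- simulate_swimmers(p, cf), "escaped")
  expect_true(tr$escaped)
  expect_lt(max(tr$time), 100)
})
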