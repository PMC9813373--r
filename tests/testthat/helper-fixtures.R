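# build a swim_trajectory directly from coordinate vectors/matrices
make_traj <- function(time, x, y, ux, uy, a = 1.09, v0 = 2.16,
                      delta_t = 1, instr_delay = 0) {
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, ncol = 1)
  structure(list(time = time, x = as_mat(x), y = as_mat(y),
                 ux = as_mat(ux), uy = as_mat(uy),
                 params = swimmer_params(delta_t = delta_t, a = a, v0 = v0,
                                         instr_delay = instr_delay),
                 config = NULL, escaped = FALSE),
            class = "swim_trajectory")
}

# rigid rotation of particles at given radii and angular velocity (rad/s)
rigid_rotor_traj <- function(radii, omega, duration, dt, a = 1.09) {
  tm <- seq(0, duration, by = dt)
  phi0 <- seq_along(radii) * 2.3
  x <- sapply(seq_along(radii), function(i) radii[i] * cos(phi0[i] + omega * tm))
  y <- sapply(seq_along(radii), function(i) radii[i] * sin(phi0[i] + omega * tm))
  ux <- -x / sqrt(x^2 + y^2)
  uy <- -y / sqrt(x^2 + y^2)
  make_traj(tm, x, y, ux, uy, a = a)
}

# inverse-CDF sampler for the Boltzmann-like stationary angle density
sample_boltzmann <- function(n, model, D, seed) {
  grid <- seq(-pi, pi, length.out = 8001)
  dens <- exp(-potential(grid, model) / D)
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  set.seed(seed)
  stats::approx(cdf, grid, stats::runif(n), ties = "ordered")$y
}
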