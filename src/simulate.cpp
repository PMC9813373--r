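#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delay buffers are exact: the programmed + instrumental delay is an integer
// number of steps (the R wrappers enforce the rounding rule), so the ring
// buffer of length delay_steps + 1 always holds the needed past positions.
// Pre-history (t < 0) is the initial position: ring entries are pre-filled
// and, because reads of negative steps happen before the corresponding slot
// is first overwritten, the constant pre-history falls out of the indexing.

static inline int ring_idx(long step, int L) {
  long m = step % L;
  if (m < 0) m += L;
  return (int)m;
}

// [[Rcpp::export]]
List sim_full_cpp(int n, int nsteps, double dt, double v0, double D0,
                  double a, int delay_steps, int hold_steps,
                  bool target_fixed, int interaction, double k_rep,
                  NumericVector x0, NumericVector y0,
                  double box, int sample_every,
                  bool use_bias, NumericVector bias_grid) {
  const int L = delay_steps + 1;
  const double contact = 2.0 * a;
  const double sig = std::sqrt(2.0 * D0 * dt);
  const int nb = bias_grid.size();

  std::vector<double> hx((size_t)L * n), hy((size_t)L * n);
  std::vector<double> x(n), y(n), ux(n), uy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = x0[i]; y[i] = y0[i];
    for (int s = 0; s < L; ++s) { hx[(size_t)s * n + i] = x0[i]; hy[(size_t)s * n + i] = y0[i]; }
    double r = std::hypot(x0[i], y0[i]);
    if (r > 1e-9) { ux[i] = -x0[i] / r; uy[i] = -y0[i] / r; }
    else { ux[i] = 1.0; uy[i] = 0.0; }
  }

  int nsamp_max = nsteps / sample_every + 1;
  NumericMatrix sx(nsamp_max, n), sy(nsamp_max, n), sux(nsamp_max, n), suy(nsamp_max, n);
  NumericVector stime(nsamp_max);
  int nsamp = 0;
  // sample step 0
  stime[0] = 0.0;
  for (int i = 0; i < n; ++i) { sx(0, i) = x[i]; sy(0, i) = y[i]; sux(0, i) = ux[i]; suy(0, i) = uy[i]; }
  nsamp = 1;
  bool escaped = false;

  for (long s = 1; s <= nsteps; ++s) {
    // feedback refresh (zero-order hold between refreshes)
    if ((s - 1) % hold_steps == 0) {
      long d = s - 1 - delay_steps;
      int di = ring_idx(d, L);
      for (int i = 0; i < n; ++i) {
        double px = hx[(size_t)di * n + i], py = hy[(size_t)di * n + i];
        double r = std::hypot(px, py);
        if (r > 1e-9) { ux[i] = -px / r; uy[i] = -py / r; }
        // else: undefined aim -> keep previous heading (zero-order hold)
      }
    }
    // Euler-Maruyama step
    for (int i = 0; i < n; ++i) {
      double fx = v0 * ux[i], fy = v0 * uy[i];
      if (use_bias) {
        double r = std::hypot(x[i], y[i]);
        if (r > 1e-9) {
          double rx = x[i] / r, ry = y[i] / r;
          // propulsion angle of particle i (signed, from -r_hat to u_hat)
          double cr = rx * uy[i] - ry * ux[i];
          double dp = -(rx * ux[i] + ry * uy[i]);
          double th = std::atan2(cr, dp);
          // linear interpolation of the tangential bias on (-pi, pi]
          double u = (th + M_PI) / (2.0 * M_PI) * (nb - 1);
          int k = (int)std::floor(u);
          if (k < 0) k = 0;
          if (k > nb - 2) k = nb - 2;
          double w = u - k;
          double b = (1.0 - w) * bias_grid[k] + w * bias_grid[k + 1];
          // tangential unit vector (counter-clockwise)
          fx += b * (-ry);
          fy += b * (rx);
        }
      }
      x[i] += fx * dt;
      y[i] += fy * dt;
      if (D0 > 0.0) {
        x[i] += sig * norm_rand();
        y[i] += sig * norm_rand();
      }
    }
    // steric exclusion
    if (interaction == 1) {            // hard projection
      for (int sweep = 0; sweep < 40; ++sweep) {
        bool any = false;
        if (target_fixed) {
          for (int i = 0; i < n; ++i) {
            double r = std::hypot(x[i], y[i]);
            if (r < contact - 1e-12) {
              any = true;
              if (r < 1e-12) { x[i] = contact; y[i] = 0.0; }
              else { x[i] *= contact / r; y[i] *= contact / r; }
            }
          }
        }
        for (int i = 0; i < n - 1; ++i) for (int j = i + 1; j < n; ++j) {
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d = std::hypot(dx, dy);
          if (d < contact - 1e-12) {
            any = true;
            double push;
            if (d < 1e-12) { dx = 1.0; dy = 0.0; push = contact / 2.0; }
            else { push = (contact - d) / 2.0; dx /= d; dy /= d; }
            x[i] -= push * dx; y[i] -= push * dy;
            x[j] += push * dx; y[j] += push * dy;
          }
        }
        if (!any) break;
      }
    } else if (interaction == 2) {     // stiff harmonic repulsion
      std::vector<double> fxs(n, 0.0), fys(n, 0.0);
      if (target_fixed) {
        for (int i = 0; i < n; ++i) {
          double r = std::hypot(x[i], y[i]);
          if (r < contact && r > 1e-12) {
            double f = k_rep * (contact - r);
            fxs[i] += f * x[i] / r; fys[i] += f * y[i] / r;
          }
        }
      }
      for (int i = 0; i < n - 1; ++i) for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::hypot(dx, dy);
        if (d < contact && d > 1e-12) {
          double f = k_rep * (contact - d) / 2.0;
          fxs[i] -= f * dx / d; fys[i] -= f * dy / d;
          fxs[j] += f * dx / d; fys[j] += f * dy / d;
        }
      }
      for (int i = 0; i < n; ++i) { x[i] += fxs[i] * dt; y[i] += fys[i] * dt; }
    }
    // record history
    int wi = ring_idx(s, L);
    for (int i = 0; i < n; ++i) { hx[(size_t)wi * n + i] = x[i]; hy[(size_t)wi * n + i] = y[i]; }
    // escape check
    for (int i = 0; i < n; ++i)
      if (std::hypot(x[i], y[i]) > box) { escaped = true; break; }
    if (s % sample_every == 0) {
      stime[nsamp] = s * dt;
      for (int i = 0; i < n; ++i) { sx(nsamp, i) = x[i]; sy(nsamp, i) = y[i]; sux(nsamp, i) = ux[i]; suy(nsamp, i) = uy[i]; }
      ++nsamp;
    }
    if (escaped) break;
  }

  return List::create(_["time"] = stime, _["x"] = sx, _["y"] = sy,
                      _["ux"] = sux, _["uy"] = suy,
                      _["nsamp"] = nsamp, _["escaped"] = escaped);
}

// Constrained orbit: the particle slides on the contact circle of radius R,
// phi_dot = omega0 * sin(phi(t) - phi(t - delta_t)) + sqrt(2 D0 / R^2) eta.
// [[Rcpp::export]]
List sim_constrained_cpp(int nsteps, double dt, double omega0, double noise_sd,
                         int delay_steps, double phi0, double theta0,
                         int sample_every) {
  const int L = delay_steps + 1;
  // pre-history: linear ramp phi(t) = phi0 + theta0 * t / delta_t for t <= 0,
  // so that theta(0) = phi(0) - phi(-delta_t) = theta0
  std::vector<double> ring((size_t)L, phi0);
  for (long d = -delay_steps; d <= 0; ++d)
    ring[ring_idx(d, L)] = phi0 + theta0 * (double)d / (double)delay_steps;
  double phi = phi0;
  const double sig = noise_sd * std::sqrt(dt);

  int nsamp_max = nsteps / sample_every + 1;
  NumericVector stime(nsamp_max), sphi(nsamp_max), stheta(nsamp_max);
  stime[0] = 0.0; sphi[0] = phi0; stheta[0] = theta0;
  int nsamp = 1;

  for (long s = 1; s <= nsteps; ++s) {
    double phi_del = ring[ring_idx(s - 1 - delay_steps, L)];
    phi += omega0 * std::sin(phi - phi_del) * dt;
    if (noise_sd > 0.0) phi += sig * norm_rand();
    ring[ring_idx(s, L)] = phi;
    if (s % sample_every == 0) {
      stime[nsamp] = s * dt;
      sphi[nsamp] = phi;
      stheta[nsamp] = phi - ring[ring_idx(s - delay_steps, L)];
      ++nsamp;
    }
  }
  return List::create(_["time"] = stime, _["phi"] = sphi, _["theta"] = stheta,
                      _["nsamp"] = nsamp);
}

// Reduced (non-delayed) propulsion-angle equation:
// theta_dot = (1/(3 delta_t)) (theta_pm^2 - theta^2) theta + sqrt(2 D) eta,
// with theta_pm^2 = 6 (1 - 1/control) kept as an algebraic (possibly
// negative) quantity below the bifurcation.
// [[Rcpp::export]]
List sim_reduced_cpp(int nsteps, double dt, double delta_t, double s2,
                     double D, double theta0, int sample_every) {
  double th = theta0;
  const double pref = 1.0 / (3.0 * delta_t);
  const double sig = std::sqrt(2.0 * D * dt);
  int nsamp_max = nsteps / sample_every + 1;
  NumericVector stime(nsamp_max), stheta(nsamp_max);
  stime[0] = 0.0; stheta[0] = th;
  int nsamp = 1;
  for (long s = 1; s <= nsteps; ++s) {
    th += pref * (s2 - th * th) * th * dt;
    if (D > 0.0) th += sig * norm_rand();
    if (s % sample_every == 0) { stime[nsamp] = s * dt; stheta[nsamp] = th; ++nsamp; }
  }
  return List::create(_["time"] = stime, _["theta"] = stheta, _["nsamp"] = nsamp);
}
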