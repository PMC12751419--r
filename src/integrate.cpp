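#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled five-state cardiovascular oscillator.
// State u = (x, y, z, v, w):
//   (x, y)  rotate on an attracting unit limit cycle at angular rate omega;
//   z       is the ECG trace, forced by Gaussian bumps at the wave angles
//           and relaxed towards a sinusoidal baseline z0;
//   (v, w)  are the PPG trace and its intermediary, driven by z^2.
static inline void deriv(const double *u, double t,
                         const double *a, const double *b, const double *th,
                         int nwave,
                         double A, double f0,
                         double B0, double B1, double B2,
                         double omega, double *du) {
  const double x = u[0], y = u[1], z = u[2], v = u[3], w = u[4];
  const double alpha = 1.0 - std::sqrt(x * x + y * y);
  const double theta = std::atan2(y, x);
  double sum = 0.0;
  for (int i = 0; i < nwave; ++i) {
    double d = theta - th[i];
    // wrap into (-pi, pi]
    d -= 2.0 * M_PI * std::floor((d + M_PI) / (2.0 * M_PI));
    if (d > M_PI) d -= 2.0 * M_PI;  // guards the rounding edge
    if (d <= -M_PI) d = M_PI;
    sum += a[i] * d * std::exp(-d * d / (2.0 * b[i] * b[i]));
  }
  const double z0 = A * std::sin(2.0 * M_PI * f0 * t);
  du[0] = alpha * x - omega * y;
  du[1] = alpha * y + omega * x;
  du[2] = -sum - (z - z0);
  du[3] = -B0 * v + B1 * w;
  du[4] = z * z - B2 * w;
}

// [[Rcpp::export(name = ".integrate_pair_cpp")]]
NumericMatrix integrate_pair_cpp(NumericVector u0,
                                 NumericVector a, NumericVector b,
                                 NumericVector theta,
                                 double A, double f0,
                                 double B0, double B1, double B2,
                                 NumericVector omega_per_cycle,
                                 IntegerVector rr_schedule,
                                 double dt) {
  const int ncyc = rr_schedule.size();
  R_xlen_t n = 0;
  for (int c = 0; c < ncyc; ++c) n += rr_schedule[c];
  NumericMatrix out(n, 5);

  double u[5];
  for (int i = 0; i < 5; ++i) u[i] = u0[i];
  double t = 0.0;
  int cyc = 0;
  double omega = omega_per_cycle[0];
  double th_prev = std::atan2(u[1], u[0]);
  double k1[5], k2[5], k3[5], k4[5], ut[5];
  const int nwave = a.size();

  for (R_xlen_t s = 0; s < n; ++s) {
    for (int i = 0; i < 5; ++i) out(s, i) = u[i];

    // classical fixed-step RK4, one step per output sample
    deriv(u, t, a.begin(), b.begin(), theta.begin(), nwave,
          A, f0, B0, B1, B2, omega, k1);
    for (int i = 0; i < 5; ++i) ut[i] = u[i] + 0.5 * dt * k1[i];
    deriv(ut, t + 0.5 * dt, a.begin(), b.begin(), theta.begin(), nwave,
          A, f0, B0, B1, B2, omega, k2);
    for (int i = 0; i < 5; ++i) ut[i] = u[i] + 0.5 * dt * k2[i];
    deriv(ut, t + 0.5 * dt, a.begin(), b.begin(), theta.begin(), nwave,
          A, f0, B0, B1, B2, omega, k3);
    for (int i = 0; i < 5; ++i) ut[i] = u[i] + dt * k3[i];
    deriv(ut, t + dt, a.begin(), b.begin(), theta.begin(), nwave,
          A, f0, B0, B1, B2, omega, k4);
    for (int i = 0; i < 5; ++i)
      u[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t += dt;

    for (int i = 0; i < 5; ++i)
      if (!std::isfinite(u[i]))
        stop("ODE integration diverged (non-finite state at sample %ld)",
             (long)(s + 1));

    // advance the cycle frequency when the phase crosses the R-peak
    // angle theta = 0 from below (upward, not a +pi -> -pi wrap)
    const double th_now = std::atan2(u[1], u[0]);
    if (th_prev < 0.0 && th_now >= 0.0 && (th_now - th_prev) < M_PI) {
      if (cyc + 1 < ncyc) {
        ++cyc;
        omega = omega_per_cycle[cyc];
      }
    }
    th_prev = th_now;
  }
  return out;
}
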