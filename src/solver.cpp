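#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Height of the symmetric absorbing bound at time t: constant at B0 until
// bdel, then exponential decay toward zero with time constant b2.
static inline double bound_at(double t, double B0, double bdel, double b2) {
  if (t < bdel) return B0;
  return B0 * std::exp(-(t - bdel) / b2);
}

// Propagate the Fokker-Planck equation for a unit-diffusion drift process
// between symmetric (possibly collapsing) absorbing bounds by repeated
// convolution with the Gaussian transition kernel of one time step.
// Absorption is applied after each step by removing the probability mass in
// the part of each grid cell that lies beyond the bound.  A continuity
// correction (Broadie-Glasserman-Kou, 0.5826 * sigma * sqrt(dt)) shrinks the
// applied bound to compensate for unobserved within-step excursions.
//
// Returns mass (not density) absorbed at the upper/lower bound per time step,
// plus the surviving (unabsorbed) mass at t_max.
// [[Rcpp::export]]
List cpp_fp_solve(double mu, double B0, double bdel, double b2,
                  double dt, double dx, double t_max,
                  bool continuity_correction = true) {
  if (dt <= 0 || dx <= 0 || B0 <= 0 || b2 <= 0 || t_max <= 0)
    stop("dt, dx, B0, b2 and t_max must be positive");

  const double sd = std::sqrt(dt);
  const double shift = mu * dt;
  const int nt = (int)std::ceil(t_max / dt);

  // Gaussian step kernel sampled on the grid, covering +-4 sd plus the drift
  // displacement; renormalized so each step conserves mass exactly.
  const int K = (int)std::ceil((4.0 * sd + std::fabs(shift)) / dx) + 1;
  std::vector<double> kern(2 * K + 1);
  double ksum = 0.0;
  for (int k = -K; k <= K; ++k) {
    double z = (k * dx - shift) / sd;
    double w = std::exp(-0.5 * z * z);
    kern[k + K] = w;
    ksum += w;
  }
  for (double &w : kern) w /= ksum;

  // Spatial grid x_j = (j - M) * dx covering [-B0, B0] with kernel padding;
  // mass pushed beyond the bound is absorbed, so no further padding needed.
  const int M = (int)std::ceil(B0 / dx) + K + 2;
  const int nx = 2 * M + 1;
  std::vector<double> p(nx, 0.0), pn(nx, 0.0);
  p[M] = 1.0; // accumulation starts at x = 0

  const double corr = continuity_correction ? 0.5826 * sd : 0.0;

  NumericVector times(nt), g_upper(nt), g_lower(nt);
  for (int i = 0; i < nt; ++i) times[i] = (i + 1) * dt;
  double absorbed = 0.0;

  for (int i = 0; i < nt; ++i) {
    const double t = times[i];

    // one Chapman-Kolmogorov step: pn = kern * p
    std::fill(pn.begin(), pn.end(), 0.0);
    for (int j = 0; j < nx; ++j) {
      const double pj = p[j];
      if (pj <= 0.0) continue;
      int lo = j - K, hi = j + K;
      int klo = 0;
      if (lo < 0) { klo = -lo; lo = 0; }
      if (hi > nx - 1) hi = nx - 1;
      const double *kw = &kern[klo];
      double *dst = &pn[lo];
      const int len = hi - lo + 1;
      for (int m = 0; m < len; ++m) dst[m] += pj * kw[m];
    }

    // absorb mass beyond the (corrected) bound, with partial-cell overlap
    double b = bound_at(t, B0, bdel, b2) - corr;
    if (b < 0.0) b = 0.0;
    double up = 0.0, lo_m = 0.0;
    for (int j = 0; j < nx; ++j) {
      const double x = (j - M) * dx;
      if (x > b - 0.5 * dx) {
        double f = (x + 0.5 * dx - b) / dx;
        if (f > 1.0) f = 1.0;
        if (f > 0.0) { up += f * pn[j]; pn[j] *= (1.0 - f); }
      } else if (x < -b + 0.5 * dx) {
        double f = (-b + 0.5 * dx - x) / dx;
        if (f > 1.0) f = 1.0;
        if (f > 0.0) { lo_m += f * pn[j]; pn[j] *= (1.0 - f); }
      }
    }
    g_upper[i] = up;
    g_lower[i] = lo_m;
    absorbed += up + lo_m;
    std::swap(p, pn);

    // once essentially all mass is absorbed the remaining steps are zero
    if (1.0 - absorbed < 1e-12) break;
  }

  double survivor = 0.0;
  for (int j = 0; j < nx; ++j) survivor += p[j];

  return List::create(_["times"] = times,
                      _["mass_upper"] = g_upper,
                      _["mass_lower"] = g_lower,
                      _["survivor"] = survivor,
                      _["absorbed"] = absorbed);
}

// Direct linear ("open") convolution; returns length x.size() + w.size() - 1.
// Used to apply the discrete non-decision-time kernel to the first-passage
// densities: kernels are short, so direct summation beats FFT here.
// [[Rcpp::export]]
NumericVector cpp_conv_open(NumericVector x, NumericVector w) {
  const int n = x.size(), m = w.size();
  NumericVector out(n + m - 1);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    if (xi == 0.0) continue;
    for (int j = 0; j < m; ++j) out[i + j] += xi * w[j];
  }
  return out;
}

// Euler-Maruyama simulation of single-trial diffusion paths to the first
// bound crossing.  Independent of the Fokker-Planck solver above: this is
// the Monte-Carlo oracle used to validate it.  Uses R's RNG, so results are
// reproducible under set.seed().
//
// Returns choice (1 = upper, 0 = lower, NA = no crossing before t_limit),
// decision time, and total rt = decision time + truncated-Gaussian
// non-decision draw.  A trial is valid when it crossed a bound and its rt
// does not exceed the deadline.
// [[Rcpp::export]]
List cpp_em_simulate(int n, double mu, double B0, double bdel, double b2,
                     double tnd, double sigma_tnd, double dt,
                     double deadline) {
  if (n < 1) stop("n must be >= 1");
  if (dt <= 0) stop("dt must be positive");

  const double sddt = std::sqrt(dt);
  IntegerVector choice(n);
  NumericVector dec_t(n), rt(n);
  LogicalVector valid(n);

  for (int i = 0; i < n; ++i) {
    // truncated (at zero, by rejection) Gaussian non-decision time
    double nd = tnd;
    if (sigma_tnd > 0) {
      do { nd = tnd + sigma_tnd * norm_rand(); } while (nd < 0.0);
    }

    double x = 0.0, t = 0.0;
    int ch = NA_INTEGER;
    const double t_limit = deadline - nd;
    while (t < t_limit) {
      t += dt;
      x += mu * dt + sddt * norm_rand();
      const double b = bound_at(t, B0, bdel, b2);
      if (x >= b) { ch = 1; break; }
      if (x <= -b) { ch = 0; break; }
    }
    choice[i] = ch;
    dec_t[i] = t;
    rt[i] = t + nd;
    valid[i] = (ch != NA_INTEGER) && (rt[i] <= deadline);
  }

  return List::create(_["choice"] = choice, _["decision_time"] = dec_t,
                      _["rt"] = rt, _["valid"] = valid);
}
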