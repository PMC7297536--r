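// Core diffusion machinery: trial simulator (Euler-Maruyama with
// Brownian-bridge crossing correction, optional hyperbolically collapsing
// bounds) and the quantile G-square objective built on the analytic Wiener
// first-passage density (series solution; Gauss-Hermite over drift
// variability). Within-trial noise s is a free convention, default 1.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double bup(double a, double tau, double t) {
  if (!R_finite(tau)) return a;
  return clampd(a - a * t / (t + tau), a / 2.0, a);
}

static inline double blo(double a, double tau, double t) {
  if (!R_finite(tau)) return 0.0;
  return clampd(a * t / (t + tau), 0.0, a / 2.0);
}

// [[Rcpp::export]]
List cpp_simulate_ddm(NumericVector mu, double sv, double a, double z_rel,
                      double t0, double tau, double s, double dt,
                      double t_max, int seed, bool bridge) {
  int n = mu.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector censored(n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ud(0.0, 1.0);

  for (int i = 0; i < n; ++i) {
    double drift = mu[i] + (sv > 0 ? sv * nd(rng) : 0.0);
    double x = z_rel * a;
    double t = 0.0;
    int ch = NA_INTEGER;
    double r = NA_REAL;
    bool cen = false;
    for (;;) {
      if (R_finite(tau) && t >= tau - 1e-12) {
        // bounds have met at a/2: forced termination by side, ties randomized
        if (x > a / 2.0) ch = 1;
        else if (x < a / 2.0) ch = 0;
        else ch = (ud(rng) < 0.5) ? 1 : 0;
        r = t + t0;
        break;
      }
      double step = dt;
      if (R_finite(tau) && t + step > tau) step = tau - t;
      if (!R_finite(tau) && t >= t_max) { cen = true; break; }
      double z1 = nd(rng);
      double xn = x + drift * step + s * std::sqrt(step) * z1;
      double tb = t + step;
      double u = bup(a, tau, tb), l = blo(a, tau, tb);
      if (xn >= u) {
        // linear-interpolated crossing time within the step
        double frac = (u - x) / (xn - x);
        ch = 1; r = t + frac * step + t0; break;
      }
      if (xn <= l) {
        double frac = (x - l) / (x - xn);
        ch = 0; r = t + frac * step + t0; break;
      }
      if (bridge) {
        double pu = std::exp(-2.0 * (u - x) * (u - xn) / (s * s * step));
        double pl = std::exp(-2.0 * (x - l) * (xn - l) / (s * s * step));
        double uu = ud(rng);
        // hidden excursion: expected crossing near mid-step
        if (uu < pu) { ch = 1; r = t + 0.5 * step + t0; break; }
        if (uu < pu + pl) { ch = 0; r = t + 0.5 * step + t0; break; }
      }
      x = xn;
      t = tb;
    }
    choice[i] = ch;
    rt[i] = r;
    censored[i] = cen;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["censored"] = censored);
}

// standardized (v=0, a=1, s=1) first-passage density at the LOWER bound,
// start w in (0,1), at scaled time tt > 0; series switched by tt
static double f1_lower(double tt, double w) {
  if (tt <= 0.0) return 0.0;
  if (tt < 0.12) {
    // small-time (reflection) series
    double sum = 0.0;
    for (int j = -6; j <= 6; ++j) {
      double q = w + 2.0 * j;
      sum += q * std::exp(-q * q / (2.0 * tt));
    }
    double val = sum / std::sqrt(2.0 * M_PI * tt * tt * tt);
    return val > 0.0 ? val : 0.0;
  }
  // large-time series
  double sum = 0.0;
  for (int k = 1; k <= 500; ++k) {
    double term = k * std::sin(k * M_PI * w) *
      std::exp(-k * k * M_PI * M_PI * tt / 2.0);
    sum += term;
    if (k > 3 && std::fabs(term) < 1e-12) break;
  }
  double val = M_PI * sum;
  return val > 0.0 ? val : 0.0;
}

// defective first-passage density, lower bound at 0, upper at a, start z,
// drift v, noise s, at decision time t
static double wfpt_lower(double t, double v, double a, double z, double s) {
  if (t <= 0.0) return 0.0;
  double s2 = s * s;
  double tt = t * s2 / (a * a);
  double w = z / a;
  double pref = (s2 / (a * a)) *
    std::exp(-v * z / s2 - v * v * t / (2.0 * s2));
  return pref * f1_lower(tt, w);
}

static double wfpt_upper(double t, double v, double a, double z, double s) {
  return wfpt_lower(t, -v, a, a - z, s);
}

// total probability of absorption at the upper bound (constant bounds)
// [[Rcpp::export]]
double cpp_fp_upper_prob(double v, double a, double z, double s) {
  double s2 = s * s;
  if (std::fabs(v) < 1e-12) return z / a;
  double num = 1.0 - std::exp(-2.0 * v * z / s2);
  double den = 1.0 - std::exp(-2.0 * v * a / s2);
  return num / den;
}

// defective CDF of decision time at sorted edges (on the decision-time
// scale), for one bound, by trapezoid integration of the series density
static void defective_cdf(const std::vector<double> &edges, double v,
                          double a, double z, double s, bool upper,
                          std::vector<double> &out) {
  int m = edges.size();
  out.assign(m, 0.0);
  double tmax = 0.0;
  for (int i = 0; i < m; ++i) if (edges[i] > tmax) tmax = edges[i];
  if (tmax <= 0.0) return;
  double h = 0.001;
  int ng = (int)std::ceil(tmax / h) + 1;
  std::vector<double> cum(ng + 1);
  cum[0] = 0.0;
  double fprev = 0.0;
  for (int i = 1; i <= ng; ++i) {
    double t = i * h;
    double f = upper ? wfpt_upper(t, v, a, z, s) : wfpt_lower(t, v, a, z, s);
    cum[i] = cum[i - 1] + 0.5 * (fprev + f) * h;
    fprev = f;
  }
  for (int i = 0; i < m; ++i) {
    double e = edges[i];
    if (e <= 0.0) { out[i] = 0.0; continue; }
    double idx = e / h;
    int i0 = (int)std::floor(idx);
    if (i0 >= ng) { out[i] = cum[ng]; continue; }
    double frac = idx - i0;
    out[i] = cum[i0] * (1.0 - frac) + cum[i0 + 1] * frac;
  }
}

// 7-point Gauss-Hermite nodes/weights (physicists' convention)
static const double GH_X[7] = {
  -2.6519613568352334, -1.6735516287674714, -0.8162878828589647, 0.0,
   0.8162878828589647,  1.6735516287674714,  2.6519613568352334 };
static const double GH_W[7] = {
  0.0009717812450995192, 0.05451558281912703, 0.4256072526101278,
  0.8102646175568073, 0.4256072526101278, 0.05451558281912703,
  0.0009717812450995192 };

// expected bin probabilities for one cell under constant bounds.
// edges are on the RT scale (include t0). Returns concatenated
// upper-bin probabilities (length m_up + 1) then either lower-bin
// probabilities (m_lo + 1) or a single total-lower probability.
// [[Rcpp::export]]
NumericVector cpp_expected_probs(double mu, double sv, double a, double z_rel,
                                 double t0, double s,
                                 NumericVector edges_up,
                                 NumericVector edges_lo,
                                 bool lower_collapsed) {
  int mu_n = edges_up.size(), ml_n = edges_lo.size();
  int n_up = mu_n + 1;
  int n_lo = lower_collapsed ? 1 : (ml_n + 1);
  NumericVector out(n_up + n_lo);
  double z = z_rel * a;
  int nq = (sv > 1e-8) ? 7 : 1;
  const double SQRT_PI = std::sqrt(M_PI);
  std::vector<double> eu(mu_n), el(ml_n);
  for (int i = 0; i < mu_n; ++i) eu[i] = edges_up[i] - t0;
  for (int i = 0; i < ml_n; ++i) el[i] = edges_lo[i] - t0;
  std::vector<double> Fu, Fl;
  for (int q = 0; q < nq; ++q) {
    double w = (nq == 1) ? 1.0 : GH_W[q] / SQRT_PI;
    double v = (nq == 1) ? mu : mu + std::sqrt(2.0) * sv * GH_X[q];
    double pu = cpp_fp_upper_prob(v, a, z, s);
    defective_cdf(eu, v, a, z, s, true, Fu);
    double prev = 0.0;
    for (int i = 0; i < mu_n; ++i) {
      out[i] += w * (Fu[i] - prev);
      prev = Fu[i];
    }
    out[mu_n] += w * (pu - prev);
    if (lower_collapsed) {
      out[n_up] += w * (1.0 - pu);
    } else {
      defective_cdf(el, v, a, z, s, false, Fl);
      prev = 0.0;
      for (int i = 0; i < ml_n; ++i) {
        out[n_up + i] += w * (Fl[i] - prev);
        prev = Fl[i];
      }
      out[n_up + ml_n] += w * ((1.0 - pu) - prev);
    }
  }
  return out;
}

// expected bin probabilities by common-random-number simulation (used when
// bounds collapse, where no series solution applies)
// [[Rcpp::export]]
NumericVector cpp_expected_probs_sim(double mu, double sv, double a,
                                     double z_rel, double t0, double tau,
                                     double s, double dt,
                                     NumericVector edges_up,
                                     NumericVector edges_lo,
                                     bool lower_collapsed,
                                     int n_sim, int seed) {
  NumericVector muv(n_sim, mu);
  List sim = cpp_simulate_ddm(muv, sv, a, z_rel, t0, tau, s, dt, 20.0,
                              seed, true);
  IntegerVector ch = sim["choice"];
  NumericVector rt = sim["rt"];
  int mu_n = edges_up.size(), ml_n = edges_lo.size();
  int n_up = mu_n + 1;
  int n_lo = lower_collapsed ? 1 : (ml_n + 1);
  NumericVector out(n_up + n_lo);
  for (int i = 0; i < n_sim; ++i) {
    if (ch[i] == NA_INTEGER) continue;
    if (ch[i] == 1) {
      int b = 0;
      while (b < mu_n && rt[i] > edges_up[b]) ++b;
      out[b] += 1.0;
    } else if (lower_collapsed) {
      out[n_up] += 1.0;
    } else {
      int b = 0;
      while (b < ml_n && rt[i] > edges_lo[b]) ++b;
      out[n_up + b] += 1.0;
    }
  }
  for (int i = 0; i < out.size(); ++i) out[i] /= n_sim;
  return out;
}

// G-square contribution of one cell given observed counts and expected
// probabilities: 2 * sum O * log(O / (N * p)), 0 log 0 == 0, p floored
// [[Rcpp::export]]
double cpp_gsq(NumericVector observed, NumericVector expected_p) {
  double n = 0.0;
  for (int i = 0; i < observed.size(); ++i) {
    if (observed[i] < 0) stop("negative count");
    n += observed[i];
  }
  double g = 0.0;
  for (int i = 0; i < observed.size(); ++i) {
    double o = observed[i];
    if (o > 0) {
      double p = expected_p[i];
      if (p < 1e-10) p = 1e-10;
      g += o * std::log(o / (n * p));
    }
  }
  return 2.0 * g;
}
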