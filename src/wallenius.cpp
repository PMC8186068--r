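#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Wallenius' noncentral hypergeometric distribution.
//
// pmf via the integral representation (after the substitution that moves the
// draw-depletion factor into the exponent of s):
//
//   P(X = x) = C(m1, x) C(m2, n - x) * D * I(x),
//   I(x)     = \int_0^1 (1 - s^w)^x (1 - s)^(n - x) s^(D - 1) ds,
//   D        = w * (m1 - x) + (m2 - (n - x)),
//
// where w is the odds of sampling a white ball.  The integrand is evaluated
// in log space and integrated with level-refined tanh-sinh quadrature, which
// tolerates both the s^(D-1) endpoint singularity (D < 1 can occur when the
// urn is nearly exhausted) and the sharply peaked interior mode that appears
// for large n.  Upper tails are obtained by summing pmf terms over the
// shorter side of the support.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(1 - exp(a)) for a <= 0, stable near both ends
static inline double log_one_minus_exp(double a) {
  if (a >= 0.0) return NEG_INF;
  return (a > -M_LN2) ? std::log(-std::expm1(a)) : std::log1p(-std::exp(a));
}

// log(cosh(z)) without overflow
static inline double lcosh(double z) {
  double az = std::fabs(z);
  return az + std::log1p(std::exp(-2.0 * az)) - M_LN2;
}

// Incremental log-sum-exp accumulator
struct LogSum {
  double M, S;
  LogSum() : M(NEG_INF), S(0.0) {}
  void add(double l) {
    if (l == NEG_INF) return;
    if (l > M) {
      S = (M == NEG_INF) ? 1.0 : S * std::exp(M - l) + 1.0;
      M = l;
    } else {
      S += std::exp(l - M);
    }
  }
  double value() const { return (M == NEG_INF) ? NEG_INF : M + std::log(S); }
};

// log integrand (including the tanh-sinh Jacobian) at abscissa t, where
// s = 1 / (1 + exp(-2u)), u = (pi/2) sinh(t)
static double log_term(double t, double x, double nmx, double Dm1, double w) {
  double u = M_PI_2 * std::sinh(t);
  double log_s, log_1ms;
  if (u >= 0.0) {
    log_s = -std::log1p(std::exp(-2.0 * u));
    log_1ms = -2.0 * u - std::log1p(std::exp(-2.0 * u));
  } else {
    log_s = 2.0 * u - std::log1p(std::exp(2.0 * u));
    log_1ms = -std::log1p(std::exp(2.0 * u));
  }
  double lh = Dm1 * log_s;
  if (x > 0.0) {
    double a = w * log_s;  // <= 0
    double l1msw = log_one_minus_exp(a);
    if (l1msw == NEG_INF) return NEG_INF;
    lh += x * l1msw;
  }
  if (nmx > 0.0) lh += nmx * log_1ms;
  double ljac = std::log(M_PI / 4.0) + lcosh(t) - 2.0 * lcosh(u);
  return lh + ljac;
}

// derivative of the log s-integrand: d/ds [x log(1-s^w) + nmx log(1-s)
// + Dm1 log s]; strictly decreasing on (0,1) when Dm1 > 0
static double dlog_integrand(double s, double x, double nmx, double Dm1,
                             double w) {
  double res = Dm1 / s - nmx / (1.0 - s);
  if (x > 0.0) {
    double ls = std::log(s);
    double one_m_sw = -std::expm1(w * ls);  // 1 - s^w
    res -= x * w * std::exp((w - 1.0) * ls) / one_m_sw;
  }
  return res;
}

// log of I(x) by tanh-sinh quadrature: locate the peak of the transformed
// integrand, expand a window until the tails are ~55 nats below it, then
// refine by step-halving until the trapezoid sums agree
static double log_integral(double x, double nmx, double Dm1, double w) {
  const double TMAX = 4.5;
  double tstar;
  if (Dm1 > 0.0 && (x > 0.0 || nmx > 0.0)) {
    // interior mode in s: bisect the monotone derivative
    double lo = 0.0, hi = 1.0;
    for (int it = 0; it < 100 && hi - lo > 1e-15; ++it) {
      double mid = 0.5 * (lo + hi);
      if (dlog_integrand(mid, x, nmx, Dm1, w) > 0.0) lo = mid; else hi = mid;
    }
    double sstar = 0.5 * (lo + hi);
    double ustar = 0.5 * (std::log(sstar) - std::log1p(-sstar));
    tstar = std::asinh(ustar / M_PI_2);
  } else {
    // boundary mode in s: the transformed peak is O(1) wide, scan for it
    tstar = 0.0;
    double best = NEG_INF;
    for (double t = -TMAX; t <= TMAX; t += 0.11) {
      double v = log_term(t, x, nmx, Dm1, w);
      if (v > best) { best = v; tstar = t; }
    }
  }
  if (tstar > TMAX - 0.05) tstar = TMAX - 0.05;
  if (tstar < -TMAX + 0.05) tstar = -TMAX + 0.05;

  double h = 0.25;
  LogSum acc;
  acc.add(log_term(tstar, x, nmx, Dm1, w));
  double tlo = tstar, thi = tstar;
  int below = 0;
  for (double t = tstar + h; t <= TMAX; t += h) {
    double v = log_term(t, x, nmx, Dm1, w);
    acc.add(v);
    thi = t;
    if (v < acc.M - 55.0) { if (++below >= 2) break; } else below = 0;
  }
  below = 0;
  for (double t = tstar - h; t >= -TMAX; t -= h) {
    double v = log_term(t, x, nmx, Dm1, w);
    acc.add(v);
    tlo = t;
    if (v < acc.M - 55.0) { if (++below >= 2) break; } else below = 0;
  }
  double prev = acc.value() + std::log(h);
  const int MAXLEV = 12;
  for (int lev = 1; lev <= MAXLEV; ++lev) {
    h *= 0.5;
    for (double t = tlo + h; t < thi; t += 2.0 * h)
      acc.add(log_term(t, x, nmx, Dm1, w));
    double cur = acc.value() + std::log(h);
    if (lev >= 3 && std::fabs(cur - prev) < 1e-13) return cur;
    prev = cur;
  }
  return prev;
}

// log P(X = x)
static double log_pmf(double x, double m1, double m2, double n, double w) {
  double xmin = std::max(0.0, n - m2), xmax = std::min(n, m1);
  if (x < xmin || x > xmax) return NEG_INF;
  if (n == 0.0) return 0.0;                        // X = 0 surely
  if (n == m1 + m2) return (x == m1) ? 0.0 : NEG_INF;  // urn exhausted
  double D = w * (m1 - x) + (m2 - (n - x));
  double lI = log_integral(x, n - x, D - 1.0, w);
  return ::Rf_lchoose(m1, x) + ::Rf_lchoose(m2, n - x) + std::log(D) + lI;
}

// P(X >= x), inclusive upper tail
static double upper_tail(double x, double m1, double m2, double n, double w) {
  double xmin = std::max(0.0, n - m2), xmax = std::min(n, m1);
  if (x <= xmin) return 1.0;
  if (x > xmax) return 0.0;
  double nUp = xmax - x + 1.0, nLo = x - xmin;
  LogSum acc;
  if (nUp <= nLo) {
    for (double k = x; k <= xmax; k += 1.0) acc.add(log_pmf(k, m1, m2, n, w));
    double p = std::exp(acc.value());
    return std::min(p, 1.0);
  }
  for (double k = xmin; k < x; k += 1.0) acc.add(log_pmf(k, m1, m2, n, w));
  double ls = acc.value();
  double p = (ls >= 0.0) ? 0.0 : -std::expm1(ls);
  if (p <= 0.0) p = std::numeric_limits<double>::epsilon();
  return std::min(p, 1.0);
}

// [[Rcpp::export(name = ".wnchgUpperTailCpp")]]
NumericVector wnchg_upper_tail_cpp(NumericVector x, NumericVector m1,
                                   NumericVector m2, NumericVector n,
                                   NumericVector odds) {
  R_xlen_t N = x.size();
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    out[i] = upper_tail(x[i], m1[i], m2[i], n[i], odds[i]);
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".wnchgPmfCpp")]]
NumericVector wnchg_pmf_cpp(NumericVector x, NumericVector m1,
                            NumericVector m2, NumericVector n,
                            NumericVector odds) {
  R_xlen_t N = x.size();
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = std::exp(log_pmf(x[i], m1[i], m2[i], n[i], odds[i]));
  return out;
}
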