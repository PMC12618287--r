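#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-transverse-stress residual g(z) of the uniaxial strip problem with
// the hydrostatic multiplier eliminated (p = mu / (lam^2 z^2)), and its
// derivative. w_load / w_trans are cos^2/sin^2 projections of the four
// fiber families onto the loading and in-plane transverse axes.
static inline double gfun(double z, double lam2, double mu,
                          const double* k1, const double* k2,
                          const double* wl, const double* wt,
                          bool tension_only, double* gp) {
  double z2 = z * z, fib = 0.0, dfib = 0.0;
  for (int j = 0; j < 4; j++) {
    double kw = k1[j] * wt[j];
    if (kw == 0.0) continue;
    double x = lam2 * wl[j] + z2 * wt[j] - 1.0;
    if (tension_only && x < 0.0) x = 0.0;
    double x2 = x * x;
    double e = k2[j] * x2;
    if (e > 700.0) e = 700.0;
    double E = std::exp(e);
    fib += kw * x * E;
    if (gp) dfib += kw * E * (x + 2.0 * z2 * wt[j] * (1.0 + 2.0 * k2[j] * x2));
  }
  double g = mu * z + z * fib - mu / (lam2 * z2 * z);
  if (gp) *gp = mu + dfib + 3.0 * mu / (lam2 * z2 * z2);
  return g;
}

// Nominal stress along the loading axis once z is known.
static inline double pload(double z, double L, double mu,
                           const double* k1, const double* k2,
                           const double* wl, const double* wt,
                           bool tension_only) {
  double lam2 = L * L, z2 = z * z, fib = 0.0;
  for (int j = 0; j < 4; j++) {
    double kw = k1[j] * wl[j];
    if (kw == 0.0) continue;
    double x = lam2 * wl[j] + z2 * wt[j] - 1.0;
    if (tension_only && x < 0.0) x = 0.0;
    double e = k2[j] * x * x;
    if (e > 700.0) e = 700.0;
    fib += kw * x * std::exp(e);
  }
  return mu * L + L * fib - mu / (lam2 * L * z2);
}

static inline double sgn(double v) {
  return (v > 0.0) ? 1.0 : ((v < 0.0) ? -1.0 : 0.0);
}

// Safeguarded Newton/bisection for the transverse stretch at each loading
// stretch. Bracket [1/lam, 1], widened once to [0.3, 1.5]. Status per
// point: 1 converged, 0 iteration cap, -1 no sign change in the widened
// bracket.
// [[Rcpp::export]]
List C_solve_transverse(NumericVector lam, double mu,
                        NumericVector k1, NumericVector k2,
                        NumericVector w_load, NumericVector w_trans,
                        bool tension_only, double tol, int max_iter) {
  int n = lam.size();
  NumericVector z(n), P(n), res(n);
  IntegerVector status(n);
  const double *pk1 = k1.begin(), *pk2 = k2.begin(),
               *wl = w_load.begin(), *wt = w_trans.begin();
  for (int i = 0; i < n; i++) {
    double L = lam[i], lam2 = L * L;
    if (L <= 1.0 + 1e-15) {
      z[i] = 1.0; P[i] = 0.0; res[i] = 0.0; status[i] = 1;
      continue;
    }
    double lo = 1.0 / L, hi = 1.0;
    double glo = gfun(lo, lam2, mu, pk1, pk2, wl, wt, tension_only, 0);
    double ghi = gfun(hi, lam2, mu, pk1, pk2, wl, wt, tension_only, 0);
    if (!(glo * ghi < 0.0)) {
      lo = 0.3; hi = 1.5;
      glo = gfun(lo, lam2, mu, pk1, pk2, wl, wt, tension_only, 0);
      ghi = gfun(hi, lam2, mu, pk1, pk2, wl, wt, tension_only, 0);
      if (!(glo * ghi < 0.0) || !std::isfinite(glo) || !std::isfinite(ghi)) {
        z[i] = NA_REAL; P[i] = NA_REAL; res[i] = NA_REAL; status[i] = -1;
        continue;
      }
    }
    double sign_lo = sgn(glo);
    double zi = 1.0 / std::sqrt(L);
    if (zi <= lo || zi >= hi) zi = 0.5 * (lo + hi);
    int st = 0;
    for (int it = 0; it < max_iter; it++) {
      double gp;
      double g = gfun(zi, lam2, mu, pk1, pk2, wl, wt, tension_only, &gp);
      if (sgn(g) == sign_lo) lo = zi; else hi = zi;
      double znew = zi - g / gp;
      if (!std::isfinite(znew) || znew <= lo || znew >= hi)
        znew = 0.5 * (lo + hi);
      bool done = std::fabs(znew - zi) <= tol * znew ||
                  (hi - lo) <= tol * znew;
      zi = znew;
      if (done) { st = 1; break; }
    }
    z[i] = zi;
    status[i] = st;
    P[i] = pload(zi, L, mu, pk1, pk2, wl, wt, tension_only);
    res[i] = std::fabs(gfun(zi, lam2, mu, pk1, pk2, wl, wt, tension_only, 0));
  }
  return List::create(_["z"] = z, _["P_load"] = P, _["residual"] = res,
                      _["status"] = status);
}
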