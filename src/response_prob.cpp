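#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Response probabilities for the boundary-based observer family.
//
// The decision variable is quadratic in the measurement coordinates
// u = x_L - x_R and v = (x_L + x_R)/2:
//
//   d*(u, v) = K - A u^2 + cv (v - y)^2,   A > 0, cv > 0
//
// so at fixed v the accept ("collinear") region is |u| <= b(v) with
// b(v)^2 = (K + cv (v - y)^2) / A (empty where negative).  Measurements
// under the true stimulus give u ~ N(delta, su^2), v ~ N(m, tau^2),
// independent.  The v-integral has a cusp of width ~sqrt(|K|/cv) around
// v = y (and hard zeros at the roots when K < 0), so we integrate with
// piecewise Gauss-Legendre panels split at those features; plain global
// rules lose several digits there.

static inline double phi_pdf(double z) {
  return M_1_SQRT_2PI * std::exp(-0.5 * z * z);
}
static inline double Phi(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

// knots for the v integral; returns number of knots written to kn (size >= 10)
static int v_knots(double m, double tau, double y, double K, double cv,
                   double *kn) {
  double lo = m - 8.5 * tau, hi = m + 8.5 * tau;
  double tmp[9];
  int nt = 0;
  tmp[nt++] = lo;
  tmp[nt++] = hi;
  double w = std::sqrt(std::fabs(K) / cv);
  tmp[nt++] = y;
  tmp[nt++] = y - w;
  tmp[nt++] = y + w;
  if (K < 0) {
    double r = std::sqrt(-K / cv);
    tmp[nt++] = y - r;
    tmp[nt++] = y + r;
  }
  for (int i = 0; i < nt; i++) {
    if (tmp[i] < lo) tmp[i] = lo;
    if (tmp[i] > hi) tmp[i] = hi;
  }
  std::sort(tmp, tmp + nt);
  int n = 0;
  for (int i = 0; i < nt; i++) {
    if (n == 0 || tmp[i] > kn[n - 1] + 1e-12) kn[n++] = tmp[i];
  }
  return n;
}

// P(|u| <= b(v)) integrated over v, one value per trial.
// [[Rcpp::export(name = ".cpp_p_boundary")]]
NumericVector cpp_p_boundary(NumericVector m, NumericVector delta,
                             NumericVector y, NumericVector K,
                             NumericVector A, NumericVector cv,
                             NumericVector tau, NumericVector su,
                             NumericVector glx, NumericVector glw) {
  int n = m.size(), nq = glx.size();
  NumericVector out(n);
  double kn[10];
  for (int i = 0; i < n; i++) {
    double Ki = K[i], Ai = A[i], ci = cv[i], yi = y[i];
    double mi = m[i], ti = tau[i], di = delta[i], si = su[i];
    int nk = v_knots(mi, ti, yi, Ki, ci, kn);
    double r = (Ki < 0) ? std::sqrt(-Ki / ci) : -1.0;
    double acc = 0.0;
    for (int s = 0; s + 1 < nk; s++) {
      double a = kn[s], b = kn[s + 1];
      if (b - a < 1e-14) continue;
      double mid = 0.5 * (a + b);
      if (r > 0 && mid > yi - r && mid < yi + r) continue;  // empty region
      double half = 0.5 * (b - a);
      double seg = 0.0;
      for (int j = 0; j < nq; j++) {
        double v = mid + half * glx[j];
        double t = v - yi;
        double b2 = (Ki + ci * t * t) / Ai;
        double bb = b2 > 0.0 ? std::sqrt(b2) : 0.0;
        double g = Phi((bb - di) / si) - Phi((-bb - di) / si);
        seg += glw[j] * phi_pdf((v - mi) / ti) / ti * g;
      }
      acc += half * seg;
    }
    out[i] = acc;
  }
  return out;
}

// E[Phi(d*(u, v) / sigma_d)] over the measurement distribution; used by the
// decision-noise observers.  Outer piecewise panels in v; inner piecewise
// panels in u split where Phi(d*/sigma_d) transitions.
// [[Rcpp::export(name = ".cpp_p_decision_noise")]]
NumericVector cpp_p_decision_noise(NumericVector m, NumericVector delta,
                                   NumericVector y, NumericVector K,
                                   NumericVector A, NumericVector cv,
                                   NumericVector tau, NumericVector su,
                                   NumericVector sigma_d, NumericVector glx,
                                   NumericVector glw, NumericVector glxu,
                                   NumericVector glwu) {
  int n = m.size(), nq = glx.size(), nqu = glxu.size();
  NumericVector out(n);
  double kn[10], knu[12];
  for (int i = 0; i < n; i++) {
    double Ki = K[i], Ai = A[i], ci = cv[i], yi = y[i];
    double mi = m[i], ti = tau[i], di = delta[i], si = su[i], sd = sigma_d[i];
    int nk = v_knots(mi, ti, yi, Ki, ci, kn);
    double acc = 0.0;
    for (int s = 0; s + 1 < nk; s++) {
      double a = kn[s], b = kn[s + 1];
      if (b - a < 1e-14) continue;
      double half = 0.5 * (b - a), mid = 0.5 * (a + b);
      double seg = 0.0;
      for (int j = 0; j < nq; j++) {
        double v = mid + half * glx[j];
        double t = v - yi;
        double kv = Ki + ci * t * t;  // d* = kv - A u^2
        // inner integral over u in [di - 8.5 si, di + 8.5 si]
        double ulo = di - 8.5 * si, uhi = di + 8.5 * si;
        double tu[12];
        int ntu = 0;
        tu[ntu++] = ulo;
        tu[ntu++] = uhi;
        double b1 = (kv - 6.0 * sd) / Ai, b2 = (kv + 6.0 * sd) / Ai;
        double bc = kv / Ai;
        if (bc > 0) {
          double rb = std::sqrt(bc);
          tu[ntu++] = rb;
          tu[ntu++] = -rb;
        }
        if (b1 > 0) {
          double r1 = std::sqrt(b1);
          tu[ntu++] = r1;
          tu[ntu++] = -r1;
        }
        if (b2 > 0) {
          double r2 = std::sqrt(b2);
          tu[ntu++] = r2;
          tu[ntu++] = -r2;
        }
        for (int q = 0; q < ntu; q++) {
          if (tu[q] < ulo) tu[q] = ulo;
          if (tu[q] > uhi) tu[q] = uhi;
        }
        std::sort(tu, tu + ntu);
        int nu = 0;
        for (int q = 0; q < ntu; q++) {
          if (nu == 0 || tu[q] > knu[nu - 1] + 1e-12) knu[nu++] = tu[q];
        }
        double inner = 0.0;
        for (int su_i = 0; su_i + 1 < nu; su_i++) {
          double ua = knu[su_i], ub = knu[su_i + 1];
          if (ub - ua < 1e-14) continue;
          double uh = 0.5 * (ub - ua), um = 0.5 * (ua + ub);
          double segu = 0.0;
          for (int q = 0; q < nqu; q++) {
            double u = um + uh * glxu[q];
            double dstar = kv - Ai * u * u;
            segu += glwu[q] * Phi(dstar / sd) * phi_pdf((u - di) / si) / si;
          }
          inner += uh * segu;
        }
        seg += glw[j] * phi_pdf((v - mi) / ti) / ti * inner;
      }
      acc += half * seg;
    }
    out[i] = acc;
  }
  return out;
}
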