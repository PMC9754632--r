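#include <Rcpp.h>
#include <cmath>

// Axisymmetric Young-Laplace profile under a uniform body force, arc-length
// (Bashforth-Adams) form, all quantities dimensionless:
//   dX/dS = cos(phi)
//   dZ/dS = sin(phi)
//   dphi/dS = (2*bhat + bo*Z) - sin(phi)/X
//   dV/dS = pi * X^2 * sin(phi)        (solid-of-revolution volume)
// Apex limit: sin(phi)/X -> dphi/dS, hence dphi/dS|0 = bhat. The first step
// leaves the apex on the series expansion; integration stops at phi = pi
// (non-wetting contact, tangent angle 180 deg), located by bisection inside
// the crossing step.

namespace {

struct State {
  double x, z, phi, v;
};

inline void rhs(const State &y, double bhat, double bo, State &dy) {
  double sphi = std::sin(y.phi);
  dy.x = std::cos(y.phi);
  dy.z = sphi;
  // X > 0 always holds after the series start
  dy.phi = (2.0 * bhat + bo * y.z) - sphi / y.x;
  dy.v = M_PI * y.x * y.x * sphi;
}

inline State rk4_step(const State &y, double h, double bhat, double bo) {
  State k1, k2, k3, k4, tmp;
  rhs(y, bhat, bo, k1);
  tmp.x = y.x + 0.5 * h * k1.x;
  tmp.z = y.z + 0.5 * h * k1.z;
  tmp.phi = y.phi + 0.5 * h * k1.phi;
  tmp.v = y.v + 0.5 * h * k1.v;
  rhs(tmp, bhat, bo, k2);
  tmp.x = y.x + 0.5 * h * k2.x;
  tmp.z = y.z + 0.5 * h * k2.z;
  tmp.phi = y.phi + 0.5 * h * k2.phi;
  tmp.v = y.v + 0.5 * h * k2.v;
  rhs(tmp, bhat, bo, k3);
  tmp.x = y.x + h * k3.x;
  tmp.z = y.z + h * k3.z;
  tmp.phi = y.phi + h * k3.phi;
  tmp.v = y.v + h * k3.v;
  rhs(tmp, bhat, bo, k4);
  State out;
  out.x = y.x + h / 6.0 * (k1.x + 2.0 * k2.x + 2.0 * k3.x + k4.x);
  out.z = y.z + h / 6.0 * (k1.z + 2.0 * k2.z + 2.0 * k3.z + k4.z);
  out.phi = y.phi + h / 6.0 * (k1.phi + 2.0 * k2.phi + 2.0 * k3.phi + k4.phi);
  out.v = y.v + h / 6.0 * (k1.v + 2.0 * k2.v + 2.0 * k3.v + k4.v);
  return out;
}

// Leading-order series about the apex: phi = b s + O(s^3), x = s - b^2 s^3/6,
// z = b s^2 / 2, v = pi b s^4 / 4.  The start point s0 <= 1e-4 length units
// keeps the truncated O(s^3) phi term below double rounding in the metrics.
inline State apex_series(double s, double bhat) {
  State y;
  double b = bhat;
  y.phi = b * s;
  y.x = s - b * b * s * s * s / 6.0;
  y.z = 0.5 * b * s * s;
  y.v = M_PI * b * s * s * s * s / 4.0;
  return y;
}

} // namespace

// [[Rcpp::export(name = ".ba_integrate")]]
Rcpp::List ba_integrate(double bhat, double bo, double step,
                        double s_max, bool keep_path) {
  if (!(bhat > 0.0) || bo < 0.0 || !(step > 0.0))
    Rcpp::stop("invalid dimensionless parameters (bhat > 0, bo >= 0, step > 0 required)");

  const double phi_stop = M_PI;
  double s0 = std::min(step, 1e-4);
  State y = apex_series(s0, bhat);
  double s = s0;

  std::vector<double> S, X, Z, PHI;
  if (keep_path) {
    size_t cap = (size_t)std::min(s_max / step + 16.0, 4e6);
    S.reserve(cap); X.reserve(cap); Z.reserve(cap); PHI.reserve(cap);
    S.push_back(0.0); X.push_back(0.0); Z.push_back(0.0); PHI.push_back(0.0);
    S.push_back(s); X.push_back(y.x); Z.push_back(y.z); PHI.push_back(y.phi);
  }

  double wmax = y.x;
  bool terminated = false;
  bool equator_found = false;
  long max_steps = (long)(s_max / step) + 8;

  for (long i = 0; i < max_steps; ++i) {
    State ynew = rk4_step(y, step, bhat, bo);
    if (!equator_found && ynew.phi >= M_PI_2 && ynew.phi < phi_stop) {
      // the width is attained exactly at phi = pi/2; bisect onto it
      double lo = 0.0, hi = step;
      State yeq = ynew;
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        State ymid = rk4_step(y, mid, bhat, bo);
        if (ymid.phi >= M_PI_2) { hi = mid; yeq = ymid; }
        else lo = mid;
        if (hi - lo < 1e-16 * step) break;
      }
      if (yeq.x > wmax) wmax = yeq.x;
      equator_found = true;
    }
    if (!std::isfinite(ynew.phi) || !std::isfinite(ynew.x))
      Rcpp::stop("integration diverged (step too large to resolve the profile)");
    if (ynew.phi >= phi_stop) {
      // bisect the partial step to land on phi = pi
      double lo = 0.0, hi = step;
      State yend = ynew;
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        State ymid = rk4_step(y, mid, bhat, bo);
        if (ymid.phi >= phi_stop) { hi = mid; yend = ymid; }
        else lo = mid;
        if (hi - lo < 1e-16 * step) break;
      }
      s += hi;
      y = yend;
      if (y.x > wmax) wmax = y.x;
      if (keep_path) {
        S.push_back(s); X.push_back(y.x); Z.push_back(y.z); PHI.push_back(y.phi);
      }
      terminated = true;
      break;
    }
    y = ynew;
    s += step;
    if (y.x > wmax) wmax = y.x;
    if (keep_path) {
      S.push_back(s); X.push_back(y.x); Z.push_back(y.z); PHI.push_back(y.phi);
    }
  }

  if (!terminated)
    Rcpp::stop("profile never reached a tangent angle of 180 degrees within the arc-length budget");

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("h") = y.z,
      Rcpp::Named("w") = 2.0 * wmax,
      Rcpp::Named("V") = y.v,
      Rcpp::Named("L") = y.x,
      Rcpp::Named("s_end") = s);
  if (keep_path) {
    out["s"] = Rcpp::NumericVector(S.begin(), S.end());
    out["x"] = Rcpp::NumericVector(X.begin(), X.end());
    out["z"] = Rcpp::NumericVector(Z.begin(), Z.end());
    out["phi"] = Rcpp::NumericVector(PHI.begin(), PHI.end());
  }
  return out;
}
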