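// Compiled core of the forward gas-exchange simulation: the damped-Newton
// solve of the two-compartment alveolar steady state and the inversion of
// the dissociation curves to arterial pressures. Mirrors the reference R
// implementation (solve_alveolar_state + o2_pressure/co2_pressure) to the
// same tolerances; the R path remains the behavioural oracle in the tests.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ctx {
  double fio2, feto2, fetco2, fa;
  double vent1, vent2, ko1, ko2;   // ventilation shares, 1000*vent/perf
  double pdry, hb, alpha, shift, kb, kc;
};

// Severinghaus saturation at Kelman-corrected virtual pressure
inline double sat(double po2, double pco2, const Ctx &c) {
  if (po2 <= 0.0) return 0.0;
  double pc = pco2 > 1e-9 ? pco2 : 1e-9;
  double x = po2 * c.shift * std::pow(pc, -0.06);
  return 1.0 / (23400.0 / (x * x * x + 150.0 * x) + 1.0);
}

inline double co2k(double so2, const Ctx &c) {
  return c.kb * (1.0 - c.kc / (3.352 - 0.456 * so2));
}

// venous-equality residuals at low-V/Q alveolar fractions u = (FAO2, FACO2)
inline void resid(const double u[2], const Ctx &c, double r[2]) {
  double f1o, f1c;
  if (c.fa > 0.0) {
    f1o = (c.feto2 - c.fa * u[0]) / (1.0 - c.fa);
    f1c = (c.fetco2 - c.fa * u[1]) / (1.0 - c.fa);
  } else {
    f1o = c.feto2; f1c = c.fetco2;
  }
  double fo[2] = {f1o, u[0]}, fc[2] = {f1c, u[1]};
  double cvo[2], cvc[2];
  double ko[2] = {c.ko1, c.ko2}, vent_fio[2];
  vent_fio[0] = c.fio2 - fo[0]; vent_fio[1] = c.fio2 - fo[1];
  for (int i = 0; i < 2; ++i) {
    double po2 = c.pdry * (fo[i] > 0.0 ? fo[i] : 0.0);
    double pco2 = c.pdry * (fc[i] > 0.0 ? fc[i] : 0.0) + 1e-12;
    double s = sat(po2, pco2, c);
    double cco = c.hb * s + c.alpha * po2;
    double ccc = co2k(s, c) * pco2;
    cvo[i] = cco - ko[i] * vent_fio[i];
    cvc[i] = ccc + ko[i] * fc[i];
  }
  r[0] = cvo[0] - cvo[1];
  r[1] = cvc[0] - cvc[1];
}

inline double clamp(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bracketed secant inversion of the O2 content curve at fixed PCO2
double o2_invert(double target, double pco2, const Ctx &c, double init) {
  double lo = 0.0, hi = 800.0;
  double sf = c.shift * std::pow(pco2 > 1e-9 ? pco2 : 1e-9, -0.06);
  auto f = [&](double p) {
    double x = p * sf;
    return c.hb / (23400.0 / (x * x * x + 150.0 * x) + 1.0) +
           c.alpha * p - target;
  };
  if (f(hi) < 0.0) stop("O2 content not representable below 800 mmHg");
  double p0 = (init > lo && init < hi) ? init : 100.0;
  double f0 = f(p0);
  if (f0 > 0.0) hi = p0; else lo = p0;
  double p1 = clamp(p0 * 1.02 + 0.01, lo + 1e-6, hi - 1e-6);
  double f1 = f(p1);
  for (int k = 0; k < 100 && std::fabs(f1) >= 1e-10; ++k) {
    if (f1 > 0.0) hi = p1; else lo = p1;
    double pn = p1 - f1 * (p1 - p0) / (f1 - f0);
    if (!std::isfinite(pn) || pn <= lo || pn >= hi) pn = 0.5 * (lo + hi);
    p0 = p1; f0 = f1;
    p1 = pn; f1 = f(p1);
  }
  return p1;
}

} // namespace

// [[Rcpp::export(name = ".forward_cpp")]]
NumericVector forward_cpp(double fs, double fa, double fio2, double feto2,
                          double fetco2, double va, double perf1,
                          double perf2, double pdry, double hb,
                          double alpha, double shift, double kb, double kc,
                          double fq, double tol, int maxit) {
  Ctx c;
  c.fio2 = fio2; c.feto2 = feto2; c.fetco2 = fetco2; c.fa = fa;
  c.vent1 = (1.0 - fa) * va; c.vent2 = fa * va;
  c.ko1 = 1000.0 * c.vent1 / perf1; c.ko2 = 1000.0 * c.vent2 / perf2;
  c.pdry = pdry; c.hb = hb; c.alpha = alpha; c.shift = shift;
  c.kb = kb; c.kc = kc;

  if (feto2 <= 0.0) stop("infeasible end-tidal closure: FetO2 <= 0");
  if (feto2 >= fio2) stop("need FetO2 < FiO2 for net oxygen uptake");

  // feasibility box for the low-V/Q fractions
  double lo[2] = {0.0, 0.0}, hi[2] = {1.0, 1.0};
  if (fa > 0.0) {
    lo[0] = std::max(0.0, (feto2 - (1.0 - fa)) / fa);
    lo[1] = std::max(0.0, (fetco2 - (1.0 - fa)) / fa);
    hi[0] = std::min(1.0, feto2 / fa);
    hi[1] = std::min(1.0, fetco2 / fa);
  }
  double u[2] = {clamp(feto2, lo[0], hi[0]), clamp(fetco2, lo[1], hi[1])};
  double r[2];
  resid(u, c, r);

  int it = 0;
  while (std::max(std::fabs(r[0]), std::fabs(r[1])) >= tol && it < maxit) {
    ++it;
    double h = 1e-7;
    double h1 = (u[0] + h > hi[0] + 1e-3) ? -h : h;
    double h2 = (u[1] + h > hi[1] + 1e-3) ? -h : h;
    double up[2], r1[2], r2[2];
    up[0] = u[0] + h1; up[1] = u[1]; resid(up, c, r1);
    up[0] = u[0]; up[1] = u[1] + h2; resid(up, c, r2);
    double J[2][2] = {{(r1[0] - r[0]) / h1, (r2[0] - r[0]) / h2},
                      {(r1[1] - r[1]) / h1, (r2[1] - r[1]) / h2}};
    double det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
    if (!std::isfinite(det) || std::fabs(det) < 1e-300)
      stop("alveolar solver: singular Jacobian");
    double d0 = -(J[1][1] * r[0] - J[0][1] * r[1]) / det;
    double d1 = -(-J[1][0] * r[0] + J[0][0] * r[1]) / det;
    double n2 = r[0] * r[0] + r[1] * r[1];
    double t = 1.0, un[2], rn[2];
    for (;;) {
      un[0] = clamp(u[0] + t * d0, lo[0], hi[0]);
      un[1] = clamp(u[1] + t * d1, lo[1], hi[1]);
      resid(un, c, rn);
      if (rn[0] * rn[0] + rn[1] * rn[1] <= n2 || t < 1.0 / 256.0) break;
      t *= 0.5;
    }
    if (un[0] == u[0] && un[1] == u[1] &&
        rn[0] * rn[0] + rn[1] * rn[1] > n2)
      stop("alveolar solver stalled at the feasibility boundary");
    u[0] = un[0]; u[1] = un[1]; r[0] = rn[0]; r[1] = rn[1];
  }
  if (std::max(std::fabs(r[0]), std::fabs(r[1])) >= tol)
    stop("alveolar solver did not converge");

  double f1o, f1c;
  if (fa > 0.0) {
    f1o = (feto2 - fa * u[0]) / (1.0 - fa);
    f1c = (fetco2 - fa * u[1]) / (1.0 - fa);
  } else {
    f1o = feto2; f1c = fetco2;
  }
  double fo[2] = {f1o, u[0]}, fc[2] = {f1c, u[1]};
  if (fo[0] < -1e-8 || fo[0] > 1 + 1e-8 || fc[0] < -1e-8 || fc[0] > 1 + 1e-8)
    stop("infeasible alveolar state: gas fraction outside [0, 1]");

  double cc_o2[2], cc_co2[2], cv_o2[2], cv_co2[2];
  double ko[2] = {c.ko1, c.ko2};
  for (int i = 0; i < 2; ++i) {
    double po2 = c.pdry * (fo[i] > 0.0 ? fo[i] : 0.0);
    double pco2 = c.pdry * (fc[i] > 0.0 ? fc[i] : 0.0) + 1e-12;
    double s = sat(po2, pco2, c);
    cc_o2[i] = c.hb * s + c.alpha * po2;
    cc_co2[i] = co2k(s, c) * pco2;
    cv_o2[i] = cc_o2[i] - ko[i] * (c.fio2 - fo[i]);
    cv_co2[i] = cc_co2[i] + ko[i] * fc[i];
  }

  double w1 = (1.0 - fq) * (1.0 - fs), w2 = fq * (1.0 - fs);
  double cao2 = cc_o2[0] * w1 + cc_o2[1] * w2 + cv_o2[0] * fs;
  double caco2 = cc_co2[0] * w1 + cc_co2[1] * w2 + cv_co2[0] * fs;
  if (!(cao2 > 0.0) || !(caco2 > 0.0))
    stop("arterial gas content non-positive: infeasible parameters");

  double paco2 = 40.0, pao2 = 100.0;
  for (int k = 0; k < 60; ++k) {
    pao2 = o2_invert(cao2, paco2, c, pao2);
    double s = sat(pao2, paco2, c);
    double pc = caco2 / co2k(s, c);
    if (std::fabs(pc - paco2) < 1e-10) { paco2 = pc; break; }
    paco2 = pc;
  }
  pao2 = o2_invert(cao2, paco2, c, pao2);

  return NumericVector::create(pao2, paco2, cao2, caco2);
}
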