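#include <Rcpp.h>
using namespace Rcpp;

// Per-individual joint negative log-likelihood of (observations, u, v) for the
// von Bertalanffy model with log-link random effects:
//   log k    = a + sigma_u * u
//   log Linf = b + sigma_v * v
//   L(t)     = Linf * (1 - exp(-k * (t - t0)))
//   obs      ~ N(L(t), sigma_eps^2),  u, v ~ N(0, 1)
// The inner problem (posterior mode of (u, v)) is solved by damped Newton with
// analytic gradient and Hessian; d = 2 makes exact Newton cheap.

static const double LOG2PI = 1.8378770664093454836;

struct FishEval {
  double f, gu, gv, huu, huv, hvv;
  bool finite;
};

// value-only evaluation
static double fish_value(const double* age, const double* len, int m,
                         double u, double v, double a, double b, double t0,
                         double su, double sv, double se) {
  double k = std::exp(a + su * u);
  double Linf = std::exp(b + sv * v);
  if (!R_finite(k) || !R_finite(Linf)) return R_PosInf;
  double se2 = se * se;
  double f = 0.5 * (u * u + v * v) + LOG2PI;
  for (int l = 0; l < m; ++l) {
    double tau = age[l] - t0;
    double E = std::exp(-k * tau);
    double mu = Linf * (1.0 - E);
    double r = len[l] - mu;
    f += 0.5 * r * r / se2;
  }
  f += m * (std::log(se) + 0.5 * LOG2PI);
  if (!R_finite(f)) return R_PosInf;
  return f;
}

// full evaluation: value, gradient and Hessian in (u, v)
static FishEval fish_eval(const double* age, const double* len, int m,
                          double u, double v, double a, double b, double t0,
                          double su, double sv, double se) {
  FishEval e = {0, 0, 0, 0, 0, 0, true};
  double k = std::exp(a + su * u);
  double Linf = std::exp(b + sv * v);
  double se2 = se * se;
  e.f = 0.5 * (u * u + v * v) + LOG2PI;
  e.gu = u; e.gv = v;
  e.huu = 1.0; e.hvv = 1.0; e.huv = 0.0;
  if (!R_finite(k) || !R_finite(Linf)) { e.finite = false; return e; }
  for (int l = 0; l < m; ++l) {
    double tau = age[l] - t0;
    double E = std::exp(-k * tau);
    double mu = Linf * (1.0 - E);
    double r = len[l] - mu;
    // dmu/du, dmu/dv and second derivatives via the chain rule through the links
    double P = su * k * tau * Linf * E;          // dmu/du
    double Q = sv * mu;                          // dmu/dv
    double Puu = su * su * k * tau * Linf * E * (1.0 - k * tau);  // d2mu/du2
    double Puv = sv * P;                         // d2mu/dudv
    double Qvv = sv * Q;                         // d2mu/dv2
    e.f += 0.5 * r * r / se2;
    e.gu -= r * P / se2;
    e.gv -= r * Q / se2;
    e.huu += (P * P - r * Puu) / se2;
    e.huv += (P * Q - r * Puv) / se2;
    e.hvv += (Q * Q - r * Qvv) / se2;
  }
  e.f += m * (std::log(se) + 0.5 * LOG2PI);
  if (!R_finite(e.f) || !R_finite(e.gu) || !R_finite(e.gv)) e.finite = false;
  return e;
}

// [[Rcpp::export]]
double joint_nll_cpp(NumericVector age, NumericVector len,
                     double u, double v, double a, double b, double t0,
                     double su, double sv, double se) {
  if (se <= 0.0) return R_PosInf;
  return fish_value(REAL(age), REAL(len), age.size(), u, v, a, b, t0, su, sv, se);
}

// Damped Newton minimization of the per-fish joint NLL over (u, v).
// Returns mode, Hessian at the mode, value at the mode and a convergence flag.
static bool inner_newton(const double* age, const double* len, int m,
                         double a, double b, double t0,
                         double su, double sv, double se,
                         double tol, int max_iter,
                         double& u, double& v, FishEval& out) {
  FishEval e = fish_eval(age, len, m, u, v, a, b, t0, su, sv, se);
  if (!e.finite) {  // bad warm start: reset to the prior mean
    u = 0.0; v = 0.0;
    e = fish_eval(age, len, m, u, v, a, b, t0, su, sv, se);
    if (!e.finite) { out = e; return false; }
  }
  bool ok = false;
  for (int it = 0; it < max_iter; ++it) {
    double gmax = std::max(std::fabs(e.gu), std::fabs(e.gv));
    if (gmax < tol) { ok = true; break; }
    // positive-definite safeguard: ridge the Hessian until PD
    double lambda = 0.0;
    double huu = e.huu, huv = e.huv, hvv = e.hvv;
    for (int r = 0; r < 60; ++r) {
      huu = e.huu + lambda; hvv = e.hvv + lambda;
      double det = huu * hvv - huv * huv;
      if (huu > 0.0 && det > 1e-12) break;
      lambda = (lambda == 0.0) ? 1e-4 : lambda * 10.0;
    }
    double det = huu * hvv - huv * huv;
    double du = -( hvv * e.gu - huv * e.gv) / det;
    double dv = -(-huv * e.gu + huu * e.gv) / det;
    // backtracking line search on the value; the acceptance slack admits
    // final Newton steps whose true decrease is below rounding of f
    double step = 1.0;
    bool accepted = false;
    double slack = 1e-11 * (1.0 + std::fabs(e.f));
    for (int h = 0; h < 50; ++h) {
      double un = u + step * du, vn = v + step * dv;
      double fn = fish_value(age, len, m, un, vn, a, b, t0, su, sv, se);
      if (R_finite(fn) && fn <= e.f + slack) {
        u = un; v = vn;
        e = fish_eval(age, len, m, u, v, a, b, t0, su, sv, se);
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;  // stuck: report current point, not converged
  }
  if (!ok) {
    double gmax = std::max(std::fabs(e.gu), std::fabs(e.gv));
    if (gmax < tol) ok = true;
  }
  // One undamped polishing step: the Laplace log-det term is only linearly
  // accurate in the mode error, so push the inner gradient to ~machine eps
  // (quadratic convergence) to keep outer finite differences clean.
  if (ok) {
    for (int extra = 0; extra < 2; ++extra) {
      double det = e.huu * e.hvv - e.huv * e.huv;
      if (!(det > 0.0) || e.huu <= 0.0) break;
      double du = -( e.hvv * e.gu - e.huv * e.gv) / det;
      double dv = -(-e.huv * e.gu + e.huu * e.gv) / det;
      double un = u + du, vn = v + dv;
      FishEval en = fish_eval(age, len, m, un, vn, a, b, t0, su, sv, se);
      if (!en.finite || en.f > e.f + 1e-12) break;
      u = un; v = vn; e = en;
      if (std::max(std::fabs(e.gu), std::fabs(e.gv)) < 1e-13) break;
    }
  }
  out = e;
  return ok;
}

// Laplace-approximated marginal negative log-likelihood over all individuals.
// fish_start: 0-based offsets (length n_fish + 1) into the obs arrays, which
// are sorted by fish. a, b: per-fish linear predictors for log k and log Linf.
// u0, v0: warm starts, updated in place by returning the modes.
// [[Rcpp::export]]
List laplace_nll_cpp(IntegerVector fish_start, NumericVector age, NumericVector len,
                     NumericVector a, NumericVector b,
                     double t0, double su, double sv, double se,
                     NumericVector u0, NumericVector v0,
                     double inner_tol, int max_iter) {
  int n = fish_start.size() - 1;
  NumericVector u(n), v(n), per(n), huu(n), huv(n), hvv(n);
  int n_fail = 0;
  double total = 0.0;
  bool all_finite = true;
  if (se <= 0.0) {
    return List::create(_["value"] = R_PosInf, _["u"] = u, _["v"] = v,
                        _["per_fish"] = per, _["huu"] = huu, _["huv"] = huv,
                        _["hvv"] = hvv, _["n_fail"] = n, _["finite"] = false);
  }
  const double* pa = REAL(age);
  const double* pl = REAL(len);
  for (int i = 0; i < n; ++i) {
    int s = fish_start[i], m = fish_start[i + 1] - s;
    double ui = u0[i], vi = v0[i];
    FishEval e;
    bool ok = inner_newton(pa + s, pl + s, m, a[i], b[i], t0, su, sv, se,
                           inner_tol, max_iter, ui, vi, e);
    if (!ok) ++n_fail;
    if (!e.finite) { all_finite = false; per[i] = R_PosInf; continue; }
    double det = e.huu * e.hvv - e.huv * e.huv;
    if (!(det > 0.0)) { det = 1e-10; ++n_fail; }
    // log integral: f(mode) - (d/2) log(2*pi) + (1/2) log det H, d = 2
    per[i] = e.f - LOG2PI + 0.5 * std::log(det);
    u[i] = ui; v[i] = vi;
    huu[i] = e.huu; huv[i] = e.huv; hvv[i] = e.hvv;
    total += per[i];
  }
  if (!all_finite) total = R_PosInf;
  return List::create(_["value"] = total, _["u"] = u, _["v"] = v,
                      _["per_fish"] = per, _["huu"] = huu, _["huv"] = huv,
                      _["hvv"] = hvv, _["n_fail"] = n_fail,
                      _["finite"] = all_finite);
}

// Single-fish posterior mode, for the exported inner_mode() surface.
// [[Rcpp::export]]
List inner_mode_cpp(NumericVector age, NumericVector len,
                    double a, double b, double t0,
                    double su, double sv, double se,
                    double u_start, double v_start,
                    double tol, int max_iter) {
  double u = u_start, v = v_start;
  FishEval e;
  bool ok = inner_newton(REAL(age), REAL(len), age.size(), a, b, t0,
                         su, sv, se, tol, max_iter, u, v, e);
  NumericMatrix H(2, 2);
  H(0, 0) = e.huu; H(0, 1) = e.huv; H(1, 0) = e.huv; H(1, 1) = e.hvv;
  return List::create(_["mode"] = NumericVector::create(u, v),
                      _["hessian"] = H, _["value"] = e.f,
                      _["gradient"] = NumericVector::create(e.gu, e.gv),
                      _["converged"] = ok);
}
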