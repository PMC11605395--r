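#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First-order depot input response term: convolution of ka*exp(-ka*t) with
// exp(-l*t). Series fallback guards the ka -> l cancellation.
static inline double hterm(double ka, double l, double dt) {
  double d = ka - l;
  if (std::fabs(d) < 1e-9 * (ka + l)) {
    return ka * dt * std::exp(-l * dt);
  }
  return ka * (std::exp(-l * dt) - std::exp(-ka * dt)) / d;
}

// Closed-form two-compartment concentrations under linear superposition.
// Units: amounts mg -> ug, volumes L, times h => concentration ug/L == ng/mL.
// route: 0 oral (zero-order input over dur), 1 IM (dual first-order depots).
// kap: per-dose log-scale IOV deviation on CL.
static void conc_core(int nd, const double* dtim, const double* damt,
                      const int* route, const double* dur, const double* kap,
                      int nt, const double* t, double CL, double V3, double Q,
                      double V4, double kaf, double kas, double Ff, double For,
                      double* out) {
  for (int i = 0; i < nt; ++i) out[i] = 0.0;
  for (int d = 0; d < nd; ++d) {
    const double cl = CL * std::exp(kap[d]);
    const double k10 = cl / V3, k12 = Q / V3, k21 = Q / V4;
    const double s = k10 + k12 + k21;
    const double disc = std::sqrt(std::max(s * s - 4.0 * k10 * k21, 0.0));
    const double l1 = 0.5 * (s + disc), l2 = 0.5 * (s - disc);
    const double A = (l1 - k21) / (l1 - l2), B = (k21 - l2) / (l1 - l2);
    const double amt = damt[d] * 1000.0;
    if (route[d] == 0) {
      const double D = dur[d];
      const double R0 = amt * For / D;
      for (int i = 0; i < nt; ++i) {
        const double dt = t[i] - dtim[d];
        if (dt <= 0.0) continue;
        const double te = dt < D ? dt : D;
        const double tp = dt > D ? dt - D : 0.0;
        const double g1 = (1.0 - std::exp(-l1 * te)) * std::exp(-l1 * tp) / l1;
        const double g2 = (1.0 - std::exp(-l2 * te)) * std::exp(-l2 * tp) / l2;
        out[i] += R0 * (A * g1 + B * g2) / V3;
      }
    } else {
      const double af = amt * Ff, as = amt * (1.0 - Ff);
      for (int i = 0; i < nt; ++i) {
        const double dt = t[i] - dtim[d];
        if (dt <= 0.0) continue;
        const double cf = A * hterm(kaf, l1, dt) + B * hterm(kaf, l2, dt);
        const double cs = A * hterm(kas, l1, dt) + B * hterm(kas, l2, dt);
        out[i] += (af * cf + as * cs) / V3;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conc_profile_cpp(NumericVector dose_time, NumericVector dose_amt,
                               IntegerVector route, NumericVector duration,
                               NumericVector kappa_dose, NumericVector times,
                               double CL, double V3, double Q, double V4,
                               double ka_fast, double ka_slow,
                               double F_im_fast, double F_oral) {
  const int nd = dose_time.size(), nt = times.size();
  NumericVector out(nt);
  if (nd == 0 || nt == 0) return out;
  conc_core(nd, &dose_time[0], &dose_amt[0], &route[0], &duration[0],
            &kappa_dose[0], nt, &times[0], CL, V3, Q, V4, ka_fast, ka_slow,
            F_im_fast, F_oral, &out[0]);
  return out;
}

// Cholesky factorisation (in place, lower). Returns false if not PD.
static bool chol_lower(std::vector<double>& a, int n) {
  for (int j = 0; j < n; ++j) {
    double diag = a[j * n + j];
    for (int k = 0; k < j; ++k) diag -= a[j * n + k] * a[j * n + k];
    if (diag <= 0.0 || !std::isfinite(diag)) return false;
    const double lj = std::sqrt(diag);
    a[j * n + j] = lj;
    for (int i = j + 1; i < n; ++i) {
      double v = a[i * n + j];
      for (int k = 0; k < j; ++k) v -= a[i * n + k] * a[j * n + k];
      a[i * n + j] = v / lj;
    }
  }
  return true;
}

static void chol_solve(const std::vector<double>& L, int n,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) {
    double v = b[i];
    for (int k = 0; k < i; ++k) v -= L[i * n + k] * z[k];
    z[i] = v / L[i * n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = z[i];
    for (int k = i + 1; k < n; ++k) v -= L[k * n + i] * x[k];
    x[i] = v / L[i * n + i];
  }
}

// Per-subject data unpacked from R once per OFV evaluation
struct SubData {
  std::vector<double> dtim, damt, dur, ot, y;
  std::vector<int> route, oi, oral;
  double lgth;      // covariate-adjusted logit of F_im_fast
  int nocc;         // number of IOV occasions with free kappas
};

// Penalised inner objective: -log p(y|eta) - log-prior kernel.
// active codes: 0 CL, 1 F_oral, 2 ka_slow, 3 F_im_fast.
struct InnerObj {
  const SubData* s;
  double CL, V3, Q, V4, kaf, kas, For;
  double sig2_add, sig2_prop;
  const std::vector<int>* active;
  const std::vector<double>* w2;  // prior variances, length nb + nk
  int nb, nk;
  mutable std::vector<double> kap, f;

  double operator()(const std::vector<double>& eta) const {
    double eCL = 0, eFor = 0, eKas = 0, eFf = 0;
    for (int k = 0; k < nb; ++k) {
      switch ((*active)[k]) {
        case 0: eCL = eta[k]; break;
        case 1: eFor = eta[k]; break;
        case 2: eKas = eta[k]; break;
        case 3: eFf = eta[k]; break;
      }
    }
    const int nd = (int) s->dtim.size(), nt = (int) s->ot.size();
    kap.resize(nd);
    for (int d = 0; d < nd; ++d) {
      kap[d] = (nk > 0 && s->oi[d] > 0) ? eta[nb + s->oi[d] - 1] : 0.0;
    }
    f.resize(nt);
    const double ff = 1.0 / (1.0 + std::exp(-(s->lgth + eFf)));
    conc_core(nd, s->dtim.data(), s->damt.data(), s->route.data(),
              s->dur.data(), kap.data(), nt, s->ot.data(),
              CL * std::exp(eCL), V3, Q, V4, kaf, kas * std::exp(eKas),
              ff, For * std::exp(eFor), f.data());
    double ll = 0.0;
    for (int i = 0; i < nt; ++i) {
      const double v0 = s->oral[i] ? sig2_add : sig2_prop * f[i] * f[i];
      const double v = v0 > 1e-10 ? v0 : 1e-10;
      const double r = s->y[i] - f[i];
      ll += std::log(2.0 * M_PI * v) + r * r / v;
    }
    double pen = 0.0;
    const int d = nb + nk;
    for (int k = 0; k < d; ++k) pen += eta[k] * eta[k] / (*w2)[k];
    return 0.5 * (ll + pen);
  }
};

static void fd_gradient(const InnerObj& obj, std::vector<double>& eta,
                        std::vector<double>& g, double h) {
  const int d = (int) eta.size();
  for (int k = 0; k < d; ++k) {
    const double e0 = eta[k];
    eta[k] = e0 + h; const double fp = obj(eta);
    eta[k] = e0 - h; const double fm = obj(eta);
    eta[k] = e0;
    g[k] = (fp - fm) / (2.0 * h);
  }
}

static void fd_hessian(const InnerObj& obj, std::vector<double>& eta,
                       double f0, std::vector<double>& H, double h) {
  const int d = (int) eta.size();
  std::vector<double> fp(d), fm(d);
  for (int k = 0; k < d; ++k) {
    const double e0 = eta[k];
    eta[k] = e0 + h; fp[k] = obj(eta);
    eta[k] = e0 - h; fm[k] = obj(eta);
    eta[k] = e0;
    H[k * d + k] = (fp[k] - 2.0 * f0 + fm[k]) / (h * h);
  }
  for (int i = 0; i < d; ++i) {
    for (int j = i + 1; j < d; ++j) {
      const double ei = eta[i], ej = eta[j];
      eta[i] = ei + h; eta[j] = ej + h; const double fpp = obj(eta);
      eta[j] = ej - h; const double fpm = obj(eta);
      eta[i] = ei - h; const double fmm = obj(eta);
      eta[j] = ej + h; const double fmp = obj(eta);
      eta[i] = ei; eta[j] = ej;
      H[i * d + j] = H[j * d + i] = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
    }
  }
}

// Damped Newton minimisation of the inner objective from eta = 0.
// Returns the mode, the objective there, and log|H| at the mode.
static bool inner_newton(const InnerObj& obj, int d, std::vector<double>& eta,
                         double& fmode, double& logdetH,
                         const std::vector<double>& w2) {
  const double hg = 1e-5, hH = 1e-3;
  eta.assign(d, 0.0);
  double f0 = obj(eta);
  if (!std::isfinite(f0)) return false;
  std::vector<double> g(d), H(d * d), L(d * d), step(d), trial(d);
  for (int iter = 0; iter < 100; ++iter) {
    fd_gradient(obj, eta, g, hg);
    double gmax = 0.0;
    for (int k = 0; k < d; ++k) gmax = std::max(gmax, std::fabs(g[k]));
    if (gmax < 1e-7 * std::max(1.0, std::fabs(f0))) break;
    fd_hessian(obj, eta, f0, H, hH);
    double lambda = 0.0;
    bool ok = false;
    for (int tries = 0; tries < 12 && !ok; ++tries) {
      L = H;
      for (int k = 0; k < d; ++k) L[k * d + k] += lambda;
      ok = chol_lower(L, d);
      if (!ok) lambda = lambda == 0.0 ? 1e-4 : lambda * 10.0;
    }
    if (!ok) return false;
    chol_solve(L, d, g, step);
    double t = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int k = 0; k < d; ++k) trial[k] = eta[k] - t * step[k];
      const double ft = obj(trial);
      if (std::isfinite(ft) && ft <= f0 - 1e-12) {
        eta = trial; f0 = ft; moved = true; break;
      }
      t *= 0.5;
    }
    if (!moved) break;
  }
  fmode = f0;
  fd_hessian(obj, eta, f0, H, hH);
  std::vector<double> Hc = H;
  if (!chol_lower(Hc, d)) {
    Hc = H;
    for (int k = 0; k < d; ++k) {
      Hc[k * d + k] += 1e-8 + 1e-8 * std::fabs(H[k * d + k]);
    }
    if (!chol_lower(Hc, d)) {
      // fall back to the prior precision (conservative)
      logdetH = 0.0;
      for (int k = 0; k < d; ++k) logdetH += std::log(1.0 / w2[k]);
      return true;
    }
  }
  logdetH = 0.0;
  for (int k = 0; k < d; ++k) logdetH += 2.0 * std::log(Hc[k * d + k]);
  return true;
}

// Laplace -2 log marginal likelihood over subjects.
// subjects: list of lists with fields dt, da, rc, du, oi, nocc, ot, y,
// oral, lgth (see prep in R). Returns +Inf on failure.
// [[Rcpp::export]]
List ofv_cpp(List subjects, NumericVector lgth_s,
             double CL, double V3, double Q, double V4,
             double ka_fast, double ka_slow, double F_oral,
             double sig2_add, double sig2_prop,
             IntegerVector active_codes, NumericVector w2_bsv,
             bool iov, double w2_iov, bool want_eta) {
  const int ns = subjects.size();
  const int nb = active_codes.size();
  double total = 0.0;
  NumericMatrix eb(want_eta ? ns : 0, want_eta ? nb : 0);
  std::vector<int> act(active_codes.begin(), active_codes.end());
  bool failed = false;

  for (int i = 0; i < ns && !failed; ++i) {
    List sl = subjects[i];
    SubData s;
    NumericVector dt = sl["dt"], da = sl["da"], du = sl["du"],
                  ot = sl["ot"], y = sl["y"];
    IntegerVector rc = sl["rc"], oi = sl["oi"], oral = sl["oral"];
    s.dtim.assign(dt.begin(), dt.end());
    s.damt.assign(da.begin(), da.end());
    s.dur.assign(du.begin(), du.end());
    s.ot.assign(ot.begin(), ot.end());
    s.y.assign(y.begin(), y.end());
    s.route.assign(rc.begin(), rc.end());
    s.oi.assign(oi.begin(), oi.end());
    s.oral.assign(oral.begin(), oral.end());
    s.lgth = lgth_s[i];
    s.nocc = as<int>(sl["nocc"]);
    if (s.ot.empty()) {
      if (want_eta) for (int k = 0; k < nb; ++k) eb(i, k) = NA_REAL;
      continue;
    }
    const int nk = iov ? s.nocc : 0;
    const int d = nb + nk;
    std::vector<double> w2(d);
    for (int k = 0; k < nb; ++k) w2[k] = w2_bsv[k];
    for (int k = 0; k < nk; ++k) w2[nb + k] = w2_iov;

    InnerObj obj;
    obj.s = &s; obj.CL = CL; obj.V3 = V3; obj.Q = Q; obj.V4 = V4;
    obj.kaf = ka_fast; obj.kas = ka_slow; obj.For = F_oral;
    obj.sig2_add = sig2_add; obj.sig2_prop = sig2_prop;
    obj.active = &act; obj.w2 = &w2; obj.nb = nb; obj.nk = nk;

    if (d == 0) {
      std::vector<double> empty;
      const double f0 = obj(empty);
      if (!std::isfinite(f0)) { failed = true; break; }
      total += 2.0 * f0;
      continue;
    }
    std::vector<double> eta;
    double fmode, logdetH;
    if (!inner_newton(obj, d, eta, fmode, logdetH, w2)) {
      failed = true; break;
    }
    double logw2 = 0.0;
    for (int k = 0; k < d; ++k) logw2 += std::log(w2[k]);
    total += 2.0 * fmode + logw2 + logdetH;
    if (want_eta) for (int k = 0; k < nb; ++k) eb(i, k) = eta[k];
  }
  if (failed || !std::isfinite(total)) {
    return List::create(_["ofv"] = R_PosInf, _["eta"] = eb);
  }
  return List::create(_["ofv"] = total, _["eta"] = eb);
}
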