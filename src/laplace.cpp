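// Nonlinear mixed-effects marginal likelihood via the Laplace approximation.
//
// Per subject the -2 log joint density
//   g(eta) = sum_j [ log(2 pi v_j) + (y_j - f_j(eta))^2 / v_j ]
//          + log|Omega| + q log(2 pi) + eta' Omega^-1 eta
// is minimised over eta (Newton with finite-difference derivatives) and the
// marginal -2 log-likelihood contribution is
//   ofv_i = g(eta_hat) - q log(2 pi) + log| H/2 |,  H = hessian of g.
// For a linear-Gaussian model this is exact.
//
// Residual variance: v = sig_add^2 + sig_prop^2 * f^2 (additive,
// proportional or combined, depending on which sigmas are zero).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PENALTY = 1e10;

// ---------------------------------------------------------------------------
// structural models
// ---------------------------------------------------------------------------

// two-compartment, first-order oral absorption, closed form; superposed over
// the dose history. par = (CL/F, V1/F, Q/F, V2/F, Ka); amounts in mg,
// volumes in L, output ng/mL (mg -> ng is 1e6, L -> mL is 1e3, net 1e3).
static void pred_twocomp(const std::vector<double>& par,
                         const NumericVector& t,
                         const NumericVector& dose_t,
                         const NumericVector& dose_amt,
                         std::vector<double>& out) {
  double cl = par[0], v1 = par[1], q = par[2], v2 = par[3], ka = par[4];
  double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  double a1 = k10 + k12 + k21;
  double disc = a1 * a1 - 4.0 * k10 * k21;
  if (disc < 0) disc = 0;
  double sq = std::sqrt(disc);
  double alpha = 0.5 * (a1 + sq);
  double beta  = 0.5 * (a1 - sq);
  // rate collisions: nudge ka off alpha/beta (continuous limit)
  if (std::fabs(ka - alpha) < 1e-10 * std::max(1.0, alpha)) ka *= 1.0 + 1e-8;
  if (std::fabs(ka - beta)  < 1e-10 * std::max(1.0, beta))  ka *= 1.0 + 1e-8;
  if (std::fabs(alpha - beta) < 1e-12 * std::max(1.0, alpha))
    alpha *= 1.0 + 1e-8;
  double A = (k21 - alpha) / ((ka - alpha) * (beta - alpha));
  double B = (k21 - beta)  / ((ka - beta)  * (alpha - beta));
  double C = (k21 - ka)    / ((alpha - ka) * (beta - ka));
  double scale = 1000.0 * ka / v1;  // mg -> ng/mL
  int n = t.size(), nd = dose_t.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int d = 0; d < nd; ++d) {
      double dt = t[i] - dose_t[d];
      if (dt < 0) continue;
      s += dose_amt[d] * (A * std::exp(-alpha * dt) +
                          B * std::exp(-beta  * dt) +
                          C * std::exp(-ka    * dt));
    }
    out[i] = scale * s;
  }
}

// one-compartment oral (Bateman); par = (CL/F, V/F, Ka)
static void pred_onecomp(const std::vector<double>& par,
                         const NumericVector& t,
                         const NumericVector& dose_t,
                         const NumericVector& dose_amt,
                         std::vector<double>& out) {
  double cl = par[0], v = par[1], ka = par[2];
  double ke = cl / v;
  if (std::fabs(ka - ke) < 1e-10 * std::max(1.0, ke)) ka *= 1.0 + 1e-8;
  double scale = 1000.0 * ka / (v * (ka - ke));
  int n = t.size(), nd = dose_t.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int d = 0; d < nd; ++d) {
      double dt = t[i] - dose_t[d];
      if (dt < 0) continue;
      s += dose_amt[d] * (std::exp(-ke * dt) - std::exp(-ka * dt));
    }
    out[i] = scale * s;
  }
}

// sigmoid Emax on a per-observation input x (concentration);
// par = (Emax, EC50, gamma)
static void pred_emax(const std::vector<double>& par,
                      const NumericVector& x,
                      std::vector<double>& out) {
  double emax = par[0], ec50 = par[1], gam = par[2];
  double eg = std::pow(ec50, gam);
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (x[i] <= 0) { out[i] = 0.0; continue; }
    double cg = std::pow(x[i], gam);
    out[i] = emax * cg / (eg + cg);
  }
}

// linear in the per-observation input: f = par[0] + par[1] * x
// (oracle model used to test the Laplace machinery against closed forms)
static void pred_linear(const std::vector<double>& par,
                        const NumericVector& x,
                        std::vector<double>& out) {
  int n = x.size();
  for (int i = 0; i < n; ++i) out[i] = par[0] + par[1] * x[i];
}

// ---------------------------------------------------------------------------
// per-subject objective
// ---------------------------------------------------------------------------

struct Subject {
  NumericVector y, t, dose_t, dose_amt, x;
  int n;
};

struct Engine {
  int model_id;           // 1 twocomp, 2 onecomp, 3 emax, 4 linear, 0 R fn
  int q;                  // number of random effects
  std::vector<int> iiv_idx;      // parameter slot per eta component
  std::vector<double> omega2;    // diagonal variances
  double logdet_omega;
  double sa2, sp2;
  Function* rfun;
  int subj_index;         // 1-based, for R callbacks

  // structural prediction for one subject at the given random effects
  bool predict(const Subject& s, const std::vector<double>& base,
               const std::vector<double>& eta, std::vector<double>& f) const {
    std::vector<double> par(base);
    for (int k = 0; k < q; ++k) {
      double e = eta[k];
      if (e > 30) e = 30; if (e < -30) e = -30;
      par[iiv_idx[k]] *= std::exp(e);
    }
    int n = s.n;
    if (model_id == 1) pred_twocomp(par, s.t, s.dose_t, s.dose_amt, f);
    else if (model_id == 2) pred_onecomp(par, s.t, s.dose_t, s.dose_amt, f);
    else if (model_id == 3) pred_emax(par, s.x, f);
    else if (model_id == 4) pred_linear(par, s.x, f);
    else {
      NumericVector etaR(eta.begin(), eta.end());
      NumericVector fr = (*rfun)(subj_index, etaR);
      for (int j = 0; j < n; ++j) f[j] = fr[j];
    }
    for (int j = 0; j < n; ++j) if (!std::isfinite(f[j])) return false;
    return true;
  }

  // -2 log joint density from a prediction vector
  double g_of(const Subject& s, const std::vector<double>& f,
              const std::vector<double>& eta) const {
    const double LOG2PI = std::log(2.0 * M_PI);
    double g = 0.0;
    for (int j = 0; j < s.n; ++j) {
      double v = sa2 + sp2 * f[j] * f[j];
      if (v < 1e-12) v = 1e-12;
      double r = s.y[j] - f[j];
      g += std::log(v) + LOG2PI + r * r / v;
    }
    if (q > 0) {
      g += logdet_omega + q * LOG2PI;
      for (int k = 0; k < q; ++k) g += eta[k] * eta[k] / omega2[k];
    }
    if (!std::isfinite(g)) return PENALTY;
    return g;
  }

  double eval(const Subject& s, const std::vector<double>& base,
              const std::vector<double>& eta) const {
    std::vector<double> f(s.n);
    if (!predict(s, base, eta, f)) return PENALTY;
    return g_of(s, f, eta);
  }
};

// small dense Cholesky; returns false if not PD
static bool cholesky(std::vector<double>& a, int n) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * n + j];
      for (int k = 0; k < j; ++k) s -= a[i * n + k] * a[j * n + k];
      if (i == j) {
        if (s <= 0) return false;
        a[i * n + i] = std::sqrt(s);
      } else {
        a[i * n + j] = s / a[j * n + j];
      }
    }
  }
  return true;
}

// solve L L' x = b with L lower-triangular from cholesky()
static void chol_solve(const std::vector<double>& L, int n,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> ytmp(n);
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * n + k] * ytmp[k];
    ytmp[i] = s / L[i * n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = ytmp[i];
    for (int k = i + 1; k < n; ++k) s -= L[k * n + i] * x[k];
    x[i] = s / L[i * n + i];
  }
}

// analytic gradient and Gauss-Newton Hessian of g(eta) from a central
// finite-difference Jacobian of the prediction. Second derivatives of the
// structural prediction are dropped (exact for models linear in eta, the
// standard expected-Hessian approximation otherwise).
// Returns false if any prediction is non-finite.
static bool grad_hess_gn(const Engine& eng, const Subject& s,
                         const std::vector<double>& base,
                         std::vector<double>& eta,
                         const std::vector<double>& f0,
                         std::vector<double>& grad,
                         std::vector<double>& H) {
  int q = eng.q, n = s.n;
  const double h = 1e-4;
  std::vector<double> J(n * q);       // J[j*q + k]
  std::vector<double> fp(n), fm(n);
  for (int k = 0; k < q; ++k) {
    double e0 = eta[k];
    eta[k] = e0 + h;
    bool ok1 = eng.predict(s, base, eta, fp);
    eta[k] = e0 - h;
    bool ok2 = eng.predict(s, base, eta, fm);
    eta[k] = e0;
    if (!ok1 || !ok2) return false;
    for (int j = 0; j < n; ++j) J[j * q + k] = (fp[j] - fm[j]) / (2.0 * h);
  }
  std::fill(grad.begin(), grad.end(), 0.0);
  std::fill(H.begin(), H.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    double f = f0[j];
    double v = eng.sa2 + eng.sp2 * f * f;
    if (v < 1e-12) v = 1e-12;
    double r = s.y[j] - f;
    double iv = 1.0 / v;
    double sp2f = 2.0 * eng.sp2 * f;
    // d/df of log v + r^2/v
    double c1 = sp2f * iv * (1.0 - r * r * iv) - 2.0 * r * iv;
    // d2/df2, holding the Jacobian fixed (drop f'')
    double dc1 = 2.0 * eng.sp2 * iv * (1.0 - r * r * iv)
      + sp2f * (-sp2f * iv * iv + 2.0 * r * iv * iv
                + 2.0 * sp2f * r * r * iv * iv * iv)
      + 2.0 * iv + 2.0 * sp2f * r * iv * iv;
    for (int k = 0; k < q; ++k) {
      double ajk = J[j * q + k];
      grad[k] += c1 * ajk;
      for (int l = 0; l <= k; ++l) {
        H[k * q + l] += dc1 * ajk * J[j * q + l];
      }
    }
  }
  for (int k = 0; k < q; ++k) {
    grad[k] += 2.0 * eta[k] / eng.omega2[k];
    H[k * q + k] += 2.0 / eng.omega2[k];
    for (int l = 0; l < k; ++l) H[l * q + k] = H[k * q + l];
  }
  return true;
}

// [[Rcpp::export]]
List ofv_laplace_cpp(List subjects, NumericMatrix base_params,
                     IntegerVector iiv_idx, NumericVector omega2,
                     double sig_add, double sig_prop, int model_id,
                     NumericMatrix eta_start,
                     Nullable<Function> rfun = R_NilValue,
                     double grad_tol = 1e-8, int max_iter = 80) {
  int nsub = subjects.size();
  int q = omega2.size();
  Engine eng;
  eng.model_id = model_id;
  eng.q = q;
  eng.sa2 = sig_add * sig_add;
  eng.sp2 = sig_prop * sig_prop;
  eng.iiv_idx.resize(q);
  eng.omega2.resize(q);
  eng.logdet_omega = 0.0;
  for (int k = 0; k < q; ++k) {
    eng.iiv_idx[k] = iiv_idx[k] - 1;   // R is 1-based
    eng.omega2[k] = omega2[k];
    eng.logdet_omega += std::log(omega2[k]);
  }
  Function rf = rfun.isNotNull() ? Function(rfun.get()) : Function("identity");
  eng.rfun = &rf;

  NumericVector ofv_i(nsub);
  NumericMatrix eta_hat(nsub, std::max(q, 1));
  double total = 0.0;
  int n_ridge = 0;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (int i = 0; i < nsub; ++i) {
    List sl = subjects[i];
    Subject s;
    s.y = sl["y"];
    s.t = sl["t"];
    s.dose_t = sl["dose_t"];
    s.dose_amt = sl["dose_amt"];
    s.x = sl["x"];
    s.n = s.y.size();
    eng.subj_index = i + 1;
    std::vector<double> base(base_params.ncol());
    for (int j = 0; j < base_params.ncol(); ++j) base[j] = base_params(i, j);

    if (q == 0 || s.n == 0) {
      std::vector<double> eta0(std::max(q, 1), 0.0);
      double g0;
      if (q == 0) {
        g0 = eng.eval(s, base, eta0);
        ofv_i[i] = g0;        // pure fixed-effects -2LL
      } else {
        ofv_i[i] = 0.0;       // no data: marginal likelihood is 1
      }
      total += ofv_i[i];
      continue;
    }

    std::vector<double> eta(q);
    for (int k = 0; k < q; ++k) eta[k] = eta_start(i, k);
    std::vector<double> f0(s.n);
    bool pred_ok = eng.predict(s, base, eta, f0);
    double g0 = pred_ok ? eng.g_of(s, f0, eta) : PENALTY;
    if (g0 >= PENALTY) {  // bad warm start; retry from the prior mode
      std::fill(eta.begin(), eta.end(), 0.0);
      pred_ok = eng.predict(s, base, eta, f0);
      g0 = pred_ok ? eng.g_of(s, f0, eta) : PENALTY;
      if (g0 >= PENALTY) { ofv_i[i] = PENALTY; total += PENALTY; continue; }
    }
    std::vector<double> grad(q), H(q * q), L(q * q), step(q), neg(q);
    for (int it = 0; it < max_iter; ++it) {
      if (!grad_hess_gn(eng, s, base, eta, f0, grad, H)) break;
      double gmax = 0.0;
      for (int k = 0; k < q; ++k) gmax = std::max(gmax, std::fabs(grad[k]));
      if (gmax < grad_tol * (1.0 + std::fabs(g0))) break;
      double ridge = 0.0;
      for (;;) {
        L = H;
        if (ridge > 0) for (int k = 0; k < q; ++k) L[k * q + k] += ridge;
        if (cholesky(L, q)) break;
        ridge = (ridge == 0) ? 1e-6 : ridge * 10.0;
        ++n_ridge;
        if (ridge > 1e12) break;
      }
      for (int k = 0; k < q; ++k) neg[k] = -grad[k];
      chol_solve(L, q, neg, step);
      // backtracking line search
      double alpha = 1.0;
      double gnew = g0;
      std::vector<double> trial(q), ftrial(s.n);
      bool improved = false;
      for (int ls = 0; ls < 40; ++ls) {
        for (int k = 0; k < q; ++k) trial[k] = eta[k] + alpha * step[k];
        gnew = eng.predict(s, base, trial, ftrial) ?
          eng.g_of(s, ftrial, trial) : PENALTY;
        if (gnew < g0 - 1e-14 * (1.0 + std::fabs(g0))) { improved = true; break; }
        alpha *= 0.5;
      }
      if (!improved) break;  // numerical floor; H is current for this eta
      eta = trial;
      f0 = ftrial;
      g0 = gnew;
      if (it == max_iter - 1) grad_hess_gn(eng, s, base, eta, f0, grad, H);
    }
    // Laplace curvature correction: H from the final sweep at the mode
    double ridge = 0.0;
    for (;;) {
      L = H;
      if (ridge > 0) for (int k = 0; k < q; ++k) L[k * q + k] += ridge;
      if (cholesky(L, q)) break;
      ridge = (ridge == 0) ? 1e-8 : ridge * 10.0;
      ++n_ridge;
      if (ridge > 1e12) { ofv_i[i] = PENALTY; break; }
    }
    double logdetH = 0.0;
    for (int k = 0; k < q; ++k) logdetH += 2.0 * std::log(L[k * q + k]);
    ofv_i[i] = g0 - q * LOG2PI + logdetH - q * std::log(2.0);
    total += ofv_i[i];
    for (int k = 0; k < q; ++k) eta_hat(i, k) = eta[k];
  }

  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                      _["eta"] = eta_hat, _["n_ridge"] = n_ridge);
}

// [[Rcpp::export]]
NumericVector pred_pk_cpp(NumericVector par, NumericVector t,
                          NumericVector dose_t, NumericVector dose_amt,
                          int model_id) {
  if (dose_amt.size() != dose_t.size())
    stop("dose_t and dose_amt must have equal length");
  int n = t.size();
  std::vector<double> p(par.begin(), par.end());
  std::vector<double> out(n);
  if (model_id == 1) pred_twocomp(p, t, dose_t, dose_amt, out);
  else if (model_id == 2) pred_onecomp(p, t, dose_t, dose_amt, out);
  else stop("unknown PK model id");
  return NumericVector(out.begin(), out.end());
}
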