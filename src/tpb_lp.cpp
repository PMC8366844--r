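#include <Rcpp.h>
using namespace Rcpp;

// Joint log-posterior and gradient kernels for the two-part binomial
// hierarchical models, on the unconstrained scale (logit psi, log scales,
// non-centered record and species effects). Layouts must match the index
// maps built in R/likelihood.R.

static const double LOG_SQRT_2PI = 0.9189385332046727; // log(sqrt(2*pi))

// Student-t(3, 0, 5) log-density constant
static inline double t35_const() {
  return R::lgammafn(2.0) - R::lgammafn(1.5) - 0.5 * std::log(3.0 * M_PI) -
         std::log(5.0);
}

static inline double t35_lpdf(double x) {
  return t35_const() - 2.0 * std::log1p(x * x / 75.0);
}

static inline double t35_grad(double x) { return -4.0 * x / (75.0 + x * x); }

// numerically stable log(1 + exp(x))
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log(1+e^eta) and p = e^eta/(1+e^eta) sharing one exp
static inline void softplus_p(double eta, double &sp, double &p) {
  if (eta > 35.0) { sp = eta; p = 1.0; }
  else if (eta < -35.0) { double e = std::exp(eta); sp = e; p = e; }
  else { double e = std::exp(eta); sp = std::log1p(e); p = e / (1.0 + e); }
}

// shared tail: binomial likelihood given eta, plus the per-record
// hierarchy tau_raw ~ N(0,1) and theta ~ Exp(1) terms; accumulates
// d loglik / d eta into r.
// reported[i] == 1 when y[i] is observed.

// [[Rcpp::export(name = ".model1_lp_grad_cpp")]]
List model1_lp_grad_cpp(NumericVector q, IntegerVector j0, NumericVector y,
                        NumericVector N, LogicalVector reported, int J,
                        bool est_psi, double psi_fixed, double sum_lchoose) {
  const int n = j0.size();
  const int npar = q.size();
  NumericVector g(npar);
  double lp = 0.0;

  int off = est_psi ? 1 : 0;
  const int i_alpha = off, i_lt = off + J, i_tau = off + 2 * J;

  int R_n = 0;
  for (int i = 0; i < n; ++i) if (reported[i]) ++R_n;
  const int U_n = n - R_n;

  double psi;
  if (est_psi) {
    psi = inv_logit(q[0]);
    lp += R_n * std::log(psi) + U_n * std::log1p(-psi);
    lp += std::log(psi) + std::log1p(-psi); // uniform prior + logit Jacobian
    g[0] = R_n * (1.0 - psi) - U_n * psi + (1.0 - 2.0 * psi);
  } else {
    psi = psi_fixed;
    lp += R_n * std::log(psi) + U_n * std::log1p(-psi);
  }

  std::vector<double> theta(J);
  for (int k = 0; k < J; ++k) {
    double a = q[i_alpha + k];
    lp += t35_lpdf(a);
    g[i_alpha + k] = t35_grad(a);
    double lt = q[i_lt + k];
    theta[k] = std::exp(lt);
    lp += -theta[k] + lt;          // Exp(1) prior + log-Jacobian
    g[i_lt + k] = 1.0 - theta[k];
  }

  lp += sum_lchoose;
  for (int i = 0; i < n; ++i) {
    const int k = j0[i];
    const double traw = q[i_tau + i];
    const double tau = theta[k] * traw;
    lp += -0.5 * traw * traw - LOG_SQRT_2PI;  // tau_raw ~ N(0,1)
    double gtau = -traw;
    if (reported[i]) {
      const double eta = q[i_alpha + k] + tau;
      double sp, p;
      softplus_p(eta, sp, p);
      lp += y[i] * eta - N[i] * sp;
      const double r = y[i] - N[i] * p;
      g[i_alpha + k] += r;
      g[i_lt + k] += r * tau;
      gtau += r * theta[k];
    }
    g[i_tau + i] = gtau;
  }
  return List::create(_["lp"] = lp, _["grad"] = g);
}

// [[Rcpp::export(name = ".model2_lp_grad_cpp")]]
List model2_lp_grad_cpp(NumericVector q, IntegerVector j0, NumericVector y,
                        NumericVector N, LogicalVector reported,
                        NumericMatrix Xenv, NumericMatrix Xsp, int J,
                        bool est_psi, double psi_fixed, double sum_lchoose) {
  const int n = j0.size();
  const int s = Xenv.ncol();
  const int t = Xsp.ncol();
  const int npar = q.size();
  NumericVector g(npar);
  double lp = 0.0;

  int off = est_psi ? 1 : 0;
  const int i_I = off, i_beta = off + 1, i_eps = i_beta + s,
            i_lo = i_eps + t, i_phi = i_lo + 1, i_lt = i_phi + J,
            i_tau = i_lt + J;

  int R_n = 0;
  for (int i = 0; i < n; ++i) if (reported[i]) ++R_n;
  const int U_n = n - R_n;

  double psi;
  if (est_psi) {
    psi = inv_logit(q[0]);
    lp += R_n * std::log(psi) + U_n * std::log1p(-psi);
    lp += std::log(psi) + std::log1p(-psi);
    g[0] = R_n * (1.0 - psi) - U_n * psi + (1.0 - 2.0 * psi);
  } else {
    psi = psi_fixed;
    lp += R_n * std::log(psi) + U_n * std::log1p(-psi);
  }

  const double I0 = q[i_I];
  lp += t35_lpdf(I0);
  g[i_I] = t35_grad(I0);
  for (int k = 0; k < s; ++k) {
    lp += t35_lpdf(q[i_beta + k]);
    g[i_beta + k] = t35_grad(q[i_beta + k]);
  }
  for (int l = 0; l < t; ++l) {
    lp += t35_lpdf(q[i_eps + l]);
    g[i_eps + l] = t35_grad(q[i_eps + l]);
  }
  const double lo = q[i_lo];
  const double omega = std::exp(lo);
  lp += -omega + lo;
  g[i_lo] = 1.0 - omega;

  std::vector<double> alpha(J), theta(J), g_alpha(J, 0.0);
  for (int k = 0; k < J; ++k) {
    const double phir = q[i_phi + k];
    lp += -0.5 * phir * phir - LOG_SQRT_2PI;
    double a = I0 + omega * phir;
    for (int l = 0; l < t; ++l) a += Xsp(k, l) * q[i_eps + l];
    alpha[k] = a;
    const double lt = q[i_lt + k];
    theta[k] = std::exp(lt);
    lp += -theta[k] + lt;
    g[i_lt + k] = 1.0 - theta[k];
  }

  // record-level linear predictor contributions, column-major passes
  const double *X = &Xenv(0, 0);
  std::vector<double> xb(n, 0.0), r(n, 0.0);
  for (int c = 0; c < s; ++c) {
    const double bc = q[i_beta + c];
    const double *col = X + (size_t)c * n;
    for (int i = 0; i < n; ++i) xb[i] += col[i] * bc;
  }

  lp += sum_lchoose;
  for (int i = 0; i < n; ++i) {
    const int k = j0[i];
    const double traw = q[i_tau + i];
    const double tau = theta[k] * traw;
    lp += -0.5 * traw * traw - LOG_SQRT_2PI;
    double gtau = -traw;
    if (reported[i]) {
      const double eta = alpha[k] + tau + xb[i];
      double sp, p;
      softplus_p(eta, sp, p);
      lp += y[i] * eta - N[i] * sp;
      const double ri = y[i] - N[i] * p;
      r[i] = ri;
      g_alpha[k] += ri;
      g[i_lt + k] += ri * tau;
      gtau += ri * theta[k];
    }
    g[i_tau + i] = gtau;
  }
  for (int c = 0; c < s; ++c) {
    const double *col = X + (size_t)c * n;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += col[i] * r[i];
    g[i_beta + c] += acc;
  }

  double sum_ga = 0.0, sum_gaphi = 0.0;
  for (int k = 0; k < J; ++k) {
    sum_ga += g_alpha[k];
    sum_gaphi += g_alpha[k] * q[i_phi + k];
    g[i_phi + k] = omega * g_alpha[k] - q[i_phi + k];
    for (int l = 0; l < t; ++l) g[i_eps + l] += Xsp(k, l) * g_alpha[k];
  }
  g[i_I] += sum_ga;
  g[i_lo] += omega * sum_gaphi;
  return List::create(_["lp"] = lp, _["grad"] = g);
}
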