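#include <Rcpp.h>
using namespace Rcpp;

static inline double softplus(double e) {
  // log(1 + exp(e)), overflow-safe
  if (e > 35.0) return e + std::exp(-e);
  if (e < -35.0) return std::exp(e);
  return std::log1p(std::exp(e));
}


// h(u) = sum_i [y*eta - softplus(eta)] - u^2/(2 sigma^2) for one cluster
static inline double h_at(double u, const double* eta0, const double* y,
                          int s, int m, double inv_s2) {
  double h = -0.5 * u * u * inv_s2;
  for (int i = s; i < s + m; ++i) {
    double e = eta0[i] + u;
    h += y[i] * e - softplus(e);
  }
  return h;
}

// Safeguarded Newton for the mode of the concave h(u): step-halving keeps
// the iteration monotone, so the mode (and with it the marginal likelihood)
// is a continuous function of the parameters.
static inline double cluster_mode(const double* eta0, const double* y,
                                  int s, int m, double inv_s2) {
  double u = 0.0;
  double h_cur = h_at(u, eta0, y, s, m, inv_s2);
  for (int it = 0; it < 100; ++it) {
    double g1 = -u * inv_s2, g2 = -inv_s2;
    for (int i = s; i < s + m; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-(eta0[i] + u)));
      g1 += y[i] - pr;
      g2 -= pr * (1.0 - pr);
    }
    double step = -g1 / g2;
    if (std::fabs(step) < 1e-12) break;
    double u_new = u + step;
    double h_new = h_at(u_new, eta0, y, s, m, inv_s2);
    int halvings = 0;
    while (h_new < h_cur && halvings < 40) {
      step *= 0.5;
      u_new = u + step;
      h_new = h_at(u_new, eta0, y, s, m, inv_s2);
      ++halvings;
    }
    if (h_new < h_cur) break;
    u = u_new;
    h_cur = h_new;
    if (std::fabs(step) < 1e-12) break;
  }
  return u;
}

// Negative marginal log-likelihood of a Bernoulli-logit model with one
// Gaussian random intercept per cluster, by adaptive Gauss-Hermite
// quadrature. Per cluster the integrand's mode is located by Newton's
// method and the quadrature grid is centred and scaled there, so a modest
// node count is accurate even for large clusters or sigma.
//
// par = (beta[0..p-1], sigma); X is n x p; y in {0,1}; clusters are
// contiguous row blocks given by start (0-based) and len; gh_x / gh_w are
// Gauss-Hermite nodes and weights for the weight function exp(-x^2).
// [[Rcpp::export]]
double glmm_nll_cpp(NumericVector par, NumericMatrix X, NumericVector y,
                    IntegerVector start, IntegerVector len,
                    NumericVector gh_x, NumericVector gh_w) {
  const int p = X.ncol();
  const int G = start.size();
  const int K = gh_x.size();
  const double sigma = par[p];
  if (sigma <= 0.0 || !std::isfinite(sigma)) return R_PosInf;
  const double inv_s2 = 1.0 / (sigma * sigma);

  const int n = X.nrow();
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }

  double nll = 0.0;
  for (int g = 0; g < G; ++g) {
    const int s = start[g], m = len[g];
    const double u = cluster_mode(eta0.data(), &y[0], s, m, inv_s2);
    double h2 = -inv_s2;
    for (int i = s; i < s + m; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-(eta0[i] + u)));
      h2 -= pr * (1.0 - pr);
    }
    const double tau = 1.0 / std::sqrt(-h2);

    // h at the mode, for stabilisation
    const double h_mode = h_at(u, eta0.data(), &y[0], s, m, inv_s2);

    double acc = 0.0;
    const double sq2tau = std::sqrt(2.0) * tau;
    for (int k = 0; k < K; ++k) {
      const double uk = u + sq2tau * gh_x[k];
      double h = -0.5 * uk * uk * inv_s2;
      for (int i = s; i < s + m; ++i) {
        double e = eta0[i] + uk;
        h += y[i] * e - softplus(e);
      }
      acc += gh_w[k] * std::exp(h - h_mode + gh_x[k] * gh_x[k]);
    }
    // log integral = log(sqrt(2) tau) + h_mode + log(acc) - log(sqrt(2 pi) sigma)
    nll -= std::log(sq2tau) + h_mode + std::log(acc) -
           0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  }
  if (!std::isfinite(nll)) return R_PosInf;
  return nll;
}

// Gradient of the negative marginal log-likelihood. Uses the identity
// d/dtheta log L_i = E_post[ d/dtheta g(u; theta) ], with the posterior
// expectation evaluated by the same adaptive Gauss-Hermite rule; accurate
// to quadrature error, which is far below optimiser tolerance here.
// [[Rcpp::export]]
NumericVector glmm_nll_grad_cpp(NumericVector par, NumericMatrix X,
                                NumericVector y, IntegerVector start,
                                IntegerVector len, NumericVector gh_x,
                                NumericVector gh_w) {
  const int p = X.ncol();
  const int G = start.size();
  const int K = gh_x.size();
  const double sigma = par[p];
  const double inv_s2 = 1.0 / (sigma * sigma);

  const int n = X.nrow();
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }

  NumericVector grad(p + 1);
  std::vector<double> score(p);
  for (int g = 0; g < G; ++g) {
    const int s = start[g], m = len[g];
    const double u = cluster_mode(eta0.data(), &y[0], s, m, inv_s2);
    double h2 = -inv_s2;
    for (int i = s; i < s + m; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-(eta0[i] + u)));
      h2 -= pr * (1.0 - pr);
    }
    const double tau = 1.0 / std::sqrt(-h2);
    const double h_mode = h_at(u, eta0.data(), &y[0], s, m, inv_s2);

    double denom = 0.0, num_sig = 0.0;
    std::vector<double> num_beta(p, 0.0);
    const double sq2tau = std::sqrt(2.0) * tau;
    for (int k = 0; k < K; ++k) {
      const double uk = u + sq2tau * gh_x[k];
      double h = -0.5 * uk * uk * inv_s2;
      for (int j = 0; j < p; ++j) score[j] = 0.0;
      for (int i = s; i < s + m; ++i) {
        double e = eta0[i] + uk;
        double pr, sp;   // logistic(e), softplus(e) from one exp
        if (e > 35.0) { pr = 1.0; sp = e; }
        else if (e < -35.0) { pr = std::exp(e); sp = pr; }
        else { double ex = std::exp(e); pr = ex / (1.0 + ex); sp = std::log1p(ex); }
        h += y[i] * e - sp;
        double resid = y[i] - pr;
        for (int j = 0; j < p; ++j) score[j] += X(i, j) * resid;
      }
      const double a = gh_w[k] * std::exp(h - h_mode + gh_x[k] * gh_x[k]);
      denom += a;
      for (int j = 0; j < p; ++j) num_beta[j] += a * score[j];
      num_sig += a * (uk * uk * inv_s2 / sigma - 1.0 / sigma);
    }
    for (int j = 0; j < p; ++j) grad[j] -= num_beta[j] / denom;
    grad[p] -= num_sig / denom;
  }
  return grad;
}

// Value and gradient in one pass (one mode search per cluster instead of
// two); used by the optimiser through a small cache on the R side.
// [[Rcpp::export]]
List glmm_nll_vg_cpp(NumericVector par, NumericMatrix X, NumericVector y,
                     IntegerVector start, IntegerVector len,
                     NumericVector gh_x, NumericVector gh_w) {
  const int p = X.ncol();
  const int G = start.size();
  const int K = gh_x.size();
  const double sigma = par[p];
  NumericVector grad(p + 1);
  if (sigma <= 0.0 || !std::isfinite(sigma)) {
    return List::create(Named("value") = R_PosInf, Named("grad") = grad);
  }
  const double inv_s2 = 1.0 / (sigma * sigma);

  const int n = X.nrow();
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }

  double nll = 0.0;
  std::vector<double> score(p);
  for (int g = 0; g < G; ++g) {
    const int s = start[g], m = len[g];
    const double u = cluster_mode(eta0.data(), &y[0], s, m, inv_s2);
    double h2 = -inv_s2;
    for (int i = s; i < s + m; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-(eta0[i] + u)));
      h2 -= pr * (1.0 - pr);
    }
    const double tau = 1.0 / std::sqrt(-h2);
    const double h_mode = h_at(u, eta0.data(), &y[0], s, m, inv_s2);

    double denom = 0.0, num_sig = 0.0;
    std::vector<double> num_beta(p, 0.0);
    const double sq2tau = std::sqrt(2.0) * tau;
    for (int k = 0; k < K; ++k) {
      const double uk = u + sq2tau * gh_x[k];
      double h = -0.5 * uk * uk * inv_s2;
      for (int j = 0; j < p; ++j) score[j] = 0.0;
      for (int i = s; i < s + m; ++i) {
        double e = eta0[i] + uk;
        double pr, sp;   // logistic(e), softplus(e) from one exp
        if (e > 35.0) { pr = 1.0; sp = e; }
        else if (e < -35.0) { pr = std::exp(e); sp = pr; }
        else { double ex = std::exp(e); pr = ex / (1.0 + ex); sp = std::log1p(ex); }
        h += y[i] * e - sp;
        double resid = y[i] - pr;
        for (int j = 0; j < p; ++j) score[j] += X(i, j) * resid;
      }
      const double a = gh_w[k] * std::exp(h - h_mode + gh_x[k] * gh_x[k]);
      denom += a;
      for (int j = 0; j < p; ++j) num_beta[j] += a * score[j];
      num_sig += a * (uk * uk * inv_s2 / sigma - 1.0 / sigma);
    }
    nll -= std::log(sq2tau) + h_mode + std::log(denom) -
           0.5 * std::log(2.0 * M_PI) - std::log(sigma);
    for (int j = 0; j < p; ++j) grad[j] -= num_beta[j] / denom;
    grad[p] -= num_sig / denom;
  }
  if (!std::isfinite(nll)) nll = R_PosInf;
  return List::create(Named("value") = nll, Named("grad") = grad);
}
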