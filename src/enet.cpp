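#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Elastic-net penalized logistic loss on 1:1 matched-pair differences,
// no intercept (the pair-level nuisance intercepts are conditioned out):
//   f(b) = (1/n) sum_i log(1 + exp(-d_i' b))
//          + lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)
// Solved by cyclic coordinate descent on a fixed quadratic majorization
// (curvature bound 1/4), refreshed in an outer loop.
// [[Rcpp::export(name = ".cd_binomial_pairdiff")]]
NumericVector cd_binomial_pairdiff(const NumericMatrix& D,
                                   double alpha, double lambda,
                                   NumericVector beta_init,
                                   double tol = 1e-7,
                                   int max_outer = 30,
                                   int max_inner = 50) {
  const int n = D.nrow(), p = D.ncol();
  NumericVector beta = clone(beta_init);
  std::vector<double> eta(n, 0.0);
  for (int g = 0; g < p; ++g)
    if (beta[g] != 0.0)
      for (int i = 0; i < n; ++i) eta[i] += D(i, g) * beta[g];

  // precompute (w/n) * sum d_ig^2 with w = 1/4
  std::vector<double> xsq(p);
  for (int g = 0; g < p; ++g) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, g) * D(i, g);
    xsq[g] = 0.25 * s / n;
  }
  const double l1 = lambda * alpha, l2 = lambda * (1.0 - alpha);
  std::vector<double> z(n);

  for (int outer = 0; outer < max_outer; ++outer) {
    // working response from current eta: z = eta + 4 * (1 - sigmoid(eta))
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-eta[i]));
      z[i] = eta[i] + 4.0 * (1.0 - pr);
    }
    NumericVector beta_start = clone(beta);
    for (int inner = 0; inner < max_inner; ++inner) {
      double max_delta = 0.0;
      for (int g = 0; g < p; ++g) {
        double num = 0.0;
        for (int i = 0; i < n; ++i)
          num += D(i, g) * (z[i] - eta[i]);
        num = 0.25 * num / n + xsq[g] * beta[g];
        double bnew = soft_threshold(num, l1) / (xsq[g] + l2);
        double d = bnew - beta[g];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) eta[i] += D(i, g) * d;
          beta[g] = bnew;
          double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) break;
    }
    double outer_delta = 0.0;
    for (int g = 0; g < p; ++g)
      outer_delta = std::max(outer_delta, std::fabs(beta[g] - beta_start[g]));
    if (outer_delta < tol) break;
  }
  return beta;
}

// Breslow-ties score residual (delta - P) and diagonal curvature (P - Q)
// of the Cox partial log-likelihood at linear predictor eta.
// time must be sorted ascending; status in {0,1}.
static void cox_pq(const std::vector<double>& time,
                   const std::vector<int>& status,
                   const std::vector<double>& eta,
                   std::vector<double>& P, std::vector<double>& Q) {
  const int n = (int) time.size();
  std::vector<double> e(n);
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += eta[i];
  m /= n; // centre for numerical stability; P, Q invariant to shifts
  for (int i = 0; i < n; ++i) e[i] = std::exp(eta[i] - m);

  // risk-set sums from the largest time down
  std::vector<double> rs(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    acc += e[i];
    rs[i] = acc;
  }
  // cumulative d_k / R_k and d_k / R_k^2 over event times <= t_i,
  // walking tie groups of identical time
  double c1 = 0.0, c2 = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0;
    while (j < n && time[j] == time[i]) { d += status[j]; ++j; }
    if (d > 0) {
      double R = rs[i]; // risk set at this (entry) time
      c1 += (double) d / R;
      c2 += (double) d / (R * R);
    }
    for (int k = i; k < j; ++k) {
      P[k] = e[k] * c1;
      Q[k] = e[k] * e[k] * c2;
    }
    i = j;
  }
}

// [[Rcpp::export(name = ".cox_score_info0")]]
List cox_score_info0(NumericVector time, IntegerVector status,
                     NumericVector eta) {
  const int n = time.size();
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> s(status.begin(), status.end());
  std::vector<double> et(eta.begin(), eta.end());
  std::vector<double> P(n), Q(n);
  cox_pq(t, s, et, P, Q);
  NumericVector u(n), w(n);
  for (int i = 0; i < n; ++i) {
    u[i] = status[i] - P[i];
    w[i] = P[i] - Q[i];
  }
  return List::create(_["resid"] = u, _["weight"] = w);
}

// Elastic-net penalized Cox regression (Breslow ties) by coordinate
// descent on the iteratively reweighted least-squares working problem:
//   f(b) = -(1/n) * pl(b) + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
// time must be sorted ascending (caller sorts and unsorts X rows).
// [[Rcpp::export(name = ".cd_cox")]]
NumericVector cd_cox(const NumericMatrix& X,
                     NumericVector time, IntegerVector status,
                     double alpha, double lambda,
                     NumericVector beta_init,
                     double tol = 1e-7,
                     int max_outer = 30,
                     int max_inner = 50) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta_init);
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> s(status.begin(), status.end());
  std::vector<double> eta(n, 0.0);
  for (int g = 0; g < p; ++g)
    if (beta[g] != 0.0)
      for (int i = 0; i < n; ++i) eta[i] += X(i, g) * beta[g];

  const double l1 = lambda * alpha, l2 = lambda * (1.0 - alpha);
  const double wfloor = 1e-8;
  std::vector<double> P(n), Q(n), w(n), z(n);

  for (int outer = 0; outer < max_outer; ++outer) {
    cox_pq(t, s, eta, P, Q);
    for (int i = 0; i < n; ++i) {
      double wi = P[i] - Q[i];
      if (wi < wfloor) wi = wfloor;
      w[i] = wi;
      z[i] = eta[i] + (s[i] - P[i]) / wi;
    }
    NumericVector beta_start = clone(beta);
    for (int inner = 0; inner < max_inner; ++inner) {
      double max_delta = 0.0;
      for (int g = 0; g < p; ++g) {
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          double x = X(i, g);
          num += w[i] * x * (z[i] - eta[i] + x * beta[g]);
          den += w[i] * x * x;
        }
        num /= n; den /= n;
        double bnew = soft_threshold(num, l1) / (den + l2);
        double d = bnew - beta[g];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) eta[i] += X(i, g) * d;
          beta[g] = bnew;
          double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) break;
    }
    double outer_delta = 0.0;
    for (int g = 0; g < p; ++g)
      outer_delta = std::max(outer_delta, std::fabs(beta[g] - beta_start[g]));
    if (outer_delta < tol) break;
  }
  return beta;
}
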