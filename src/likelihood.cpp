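// Two-group multivariate-normal likelihood kernels for the ACE cross-lagged
// and correlated-factors twin models.  All vectors/matrices use the internal
// wave-major variable order: within twin (trait1 w1, trait2 w1, trait1 w2,
// trait2 w2, trait1 w3, trait2 w3), twin 1 then twin 2.
//
// ACE cross-lagged parameter vector (length 57), per component A, C, E
// (offset 17 each):
//   [0..2]   wave-1 covariance Cholesky: l11, l21, l22
//   [3..6]   transmission wave1->wave2, column-major: t11, t21, t12, t22
//            (row = target trait, column = source trait)
//   [7..9]   wave-2 innovation Cholesky
//   [10..13] transmission wave2->wave3
//   [14..16] wave-3 innovation Cholesky
// then [51..56] means (trait1 w1, trait2 w1, ..., trait2 w3), shared by both
// twins and both zygosity groups.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;
static const double BIG = 1e12; // optimizer-safe value for non-PD proposals

static mat chol2cov(double l11, double l21, double l22) {
  mat L(2, 2, fill::zeros);
  L(0, 0) = l11; L(1, 0) = l21; L(1, 1) = l22;
  return L * L.t();
}

// within-twin 6x6 covariance of one variance component
static mat lambda_one(const vec& th, int off) {
  mat W1 = chol2cov(th[off], th[off + 1], th[off + 2]);
  mat T1(2, 2), T2(2, 2);
  T1(0, 0) = th[off + 3]; T1(1, 0) = th[off + 4];
  T1(0, 1) = th[off + 5]; T1(1, 1) = th[off + 6];
  mat P2 = chol2cov(th[off + 7], th[off + 8], th[off + 9]);
  T2(0, 0) = th[off + 10]; T2(1, 0) = th[off + 11];
  T2(0, 1) = th[off + 12]; T2(1, 1) = th[off + 13];
  mat P3 = chol2cov(th[off + 14], th[off + 15], th[off + 16]);

  mat B(6, 6, fill::zeros);
  B.submat(2, 0, 3, 1) = T1;
  B.submat(4, 2, 5, 3) = T2;
  mat Psi(6, 6, fill::zeros);
  Psi.submat(0, 0, 1, 1) = W1;
  Psi.submat(2, 2, 3, 3) = P2;
  Psi.submat(4, 4, 5, 5) = P3;
  mat M = eye(6, 6) + B + B * B; // (I - B)^{-1}, B nilpotent of order 3
  return M * Psi * M.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_ace_lambda(const arma::vec& theta) {
  return Rcpp::List::create(lambda_one(theta, 0),
                            lambda_one(theta, 17),
                            lambda_one(theta, 34));
}

// 12x12 implied covariance for one zygosity group; rho = cross-twin
// correlations of the three components in that group
static mat sigma_group(const cube& lam, const vec& rho) {
  mat SW(6, 6, fill::zeros), SX(6, 6, fill::zeros);
  for (int k = 0; k < 3; k++) {
    SW += lam.slice(k);
    SX += rho[k] * lam.slice(k);
  }
  mat S(12, 12);
  S.submat(0, 0, 5, 5) = SW;
  S.submat(6, 6, 11, 11) = SW;
  S.submat(0, 6, 5, 11) = SX;
  S.submat(6, 0, 11, 5) = SX;
  return S;
}

// [[Rcpp::export]]
arma::mat cpp_ace_sigma(const arma::vec& theta, const arma::vec& rho) {
  cube lam(6, 6, 3);
  lam.slice(0) = lambda_one(theta, 0);
  lam.slice(1) = lambda_one(theta, 17);
  lam.slice(2) = lambda_one(theta, 34);
  return sigma_group(lam, rho);
}

// -2 log L of N(mu, Sigma) from sufficient statistics (S uses divisor n)
static double mvn_neg2ll(double n, const vec& xbar, const mat& S,
                         const vec& mu, const mat& Sigma) {
  mat R;
  if (!chol(R, Sigma)) return BIG;
  double logdet = 2.0 * accu(log(R.diag()));
  vec d = xbar - mu;
  mat Sinv;
  if (!inv_sympd(Sinv, Sigma)) return BIG;
  double quad = as_scalar(d.t() * Sinv * d);
  return n * (Sigma.n_rows * LOG2PI + logdet + trace(Sinv * S) + quad);
}

// complete-data two-group -2 log L.
// stats: list of 2 groups (MZ, DZ), each list(n, xbar (12), S (12x12, ML))
// rho: 3x2 matrix, rows A, C, E; columns MZ, DZ
// [[Rcpp::export]]
double cpp_ace_neg2ll(const arma::vec& theta, const arma::mat& rho,
                      const Rcpp::List& stats) {
  cube lam(6, 6, 3);
  lam.slice(0) = lambda_one(theta, 0);
  lam.slice(1) = lambda_one(theta, 17);
  lam.slice(2) = lambda_one(theta, 34);
  vec mu6 = theta.subvec(51, 56);
  vec mu = join_cols(mu6, mu6);
  double out = 0.0;
  for (int g = 0; g < 2; g++) {
    Rcpp::List st = stats[g];
    double n = Rcpp::as<double>(st["n"]);
    if (n <= 0) continue;
    vec xbar = Rcpp::as<vec>(st["xbar"]);
    mat S = Rcpp::as<mat>(st["S"]);
    mat Sigma = sigma_group(lam, rho.col(g));
    double v = mvn_neg2ll(n, xbar, S, mu, Sigma);
    if (v >= BIG) return BIG;
    out += v;
  }
  return out;
}

// pattern-wise FIML two-group -2 log L for data with missing values.
// stats: list of 2 groups; each group is a list of patterns, each
// list(n, idx (0-based observed columns), xbar, S)
// [[Rcpp::export]]
double cpp_ace_neg2ll_fiml(const arma::vec& theta, const arma::mat& rho,
                           const Rcpp::List& stats) {
  cube lam(6, 6, 3);
  lam.slice(0) = lambda_one(theta, 0);
  lam.slice(1) = lambda_one(theta, 17);
  lam.slice(2) = lambda_one(theta, 34);
  vec mu6 = theta.subvec(51, 56);
  vec mu = join_cols(mu6, mu6);
  double out = 0.0;
  for (int g = 0; g < 2; g++) {
    Rcpp::List pats = stats[g];
    if (pats.size() == 0) continue;
    mat Sigma = sigma_group(lam, rho.col(g));
    for (int p = 0; p < pats.size(); p++) {
      Rcpp::List st = pats[p];
      double n = Rcpp::as<double>(st["n"]);
      uvec idx = Rcpp::as<uvec>(st["idx"]);
      vec xbar = Rcpp::as<vec>(st["xbar"]);
      mat S = Rcpp::as<mat>(st["S"]);
      double v = mvn_neg2ll(n, xbar, S, mu.elem(idx), Sigma.submat(idx, idx));
      if (v >= BIG) return BIG;
      out += v;
    }
  }
  return out;
}

// Correlated-factors model: per component a free 6x6 lower-triangular
// Cholesky factor (column-major lower triangle, 21 entries), then 6 means.
// theta length 3*21 + 6 = 69.
static mat chol6(const vec& th, int off) {
  mat L(6, 6, fill::zeros);
  int p = off;
  for (int j = 0; j < 6; j++)
    for (int i = j; i < 6; i++) L(i, j) = th[p++];
  return L * L.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_cf_lambda(const arma::vec& theta) {
  return Rcpp::List::create(chol6(theta, 0), chol6(theta, 21),
                            chol6(theta, 42));
}

// [[Rcpp::export]]
double cpp_cf_neg2ll(const arma::vec& theta, const arma::mat& rho,
                     const Rcpp::List& stats) {
  cube lam(6, 6, 3);
  lam.slice(0) = chol6(theta, 0);
  lam.slice(1) = chol6(theta, 21);
  lam.slice(2) = chol6(theta, 42);
  vec mu6 = theta.subvec(63, 68);
  vec mu = join_cols(mu6, mu6);
  double out = 0.0;
  for (int g = 0; g < 2; g++) {
    Rcpp::List st = stats[g];
    double n = Rcpp::as<double>(st["n"]);
    if (n <= 0) continue;
    vec xbar = Rcpp::as<vec>(st["xbar"]);
    mat S = Rcpp::as<mat>(st["S"]);
    mat Sigma = sigma_group(lam, rho.col(g));
    double v = mvn_neg2ll(n, xbar, S, mu, Sigma);
    if (v >= BIG) return BIG;
    out += v;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_cf_neg2ll_fiml(const arma::vec& theta, const arma::mat& rho,
                          const Rcpp::List& stats) {
  cube lam(6, 6, 3);
  lam.slice(0) = chol6(theta, 0);
  lam.slice(1) = chol6(theta, 21);
  lam.slice(2) = chol6(theta, 42);
  vec mu6 = theta.subvec(63, 68);
  vec mu = join_cols(mu6, mu6);
  double out = 0.0;
  for (int g = 0; g < 2; g++) {
    Rcpp::List pats = stats[g];
    if (pats.size() == 0) continue;
    mat Sigma = sigma_group(lam, rho.col(g));
    for (int p = 0; p < pats.size(); p++) {
      Rcpp::List st = pats[p];
      double n = Rcpp::as<double>(st["n"]);
      uvec idx = Rcpp::as<uvec>(st["idx"]);
      vec xbar = Rcpp::as<vec>(st["xbar"]);
      mat S = Rcpp::as<mat>(st["S"]);
      double v = mvn_neg2ll(n, xbar, S, mu.elem(idx), Sigma.submat(idx, idx));
      if (v >= BIG) return BIG;
      out += v;
    }
  }
  return out;
}
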