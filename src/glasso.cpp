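#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Graphical lasso by block coordinate descent (Friedman/Hastie/Tibshirani-style).
// Solves max log det(Theta) - tr(S Theta) - rho * ||Theta||_1(offdiag) by cycling
// over columns of the working covariance W, each column update an L1-penalized
// quadratic program solved by coordinate descent.
//
// S must be symmetric; rho >= 0. Returns W (estimated covariance = Theta^{-1})
// and Theta (sparse precision), plus convergence information.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho, double tol, int max_iter) {
  const int p = S.n_rows;
  mat W = S;
  W.diag() += rho;
  mat B(p - 1, p, fill::zeros); // per-column lasso coefficients

  // convergence threshold on mean absolute off-diagonal change of W
  double off_mean = 0.0;
  if (p > 1) {
    off_mean = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  }
  double thr = tol * std::max(off_mean, 1e-12);

  bool converged = false;
  int iters = 0;
  std::vector<uvec> rest(p);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    int c = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    rest[j] = idx;
  }

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      const uvec& idx = rest[j];
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);

      // coordinate descent on 0.5 b'W11 b - s12'b + rho|b|_1
      for (int inner = 0; inner < 200; ++inner) {
        double dbeta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double grad = s12(k) - dot(W11.row(k), beta) + W11(k, k) * beta(k);
          double b;
          if (grad > rho)       b = (grad - rho) / W11(k, k);
          else if (grad < -rho) b = (grad + rho) / W11(k, k);
          else                  b = 0.0;
          dbeta = std::max(dbeta, std::fabs(b - beta(k)));
          beta(k) = b;
        }
        if (dbeta < thr * 0.1) break;
      }
      B.col(j) = beta;

      vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        double wi = w12(k);
        dw = std::max(dw, std::fabs(wi - W(idx(k), j)));
        W(idx(k), j) = wi;
        W(j, idx(k)) = wi;
      }
    }
    if (dw < thr) { converged = true; break; }
  }

  // recover the precision matrix from W and the column solutions
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    const uvec& idx = rest[j];
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k) {
      // exact zeros in beta stay exact zeros in the precision
      double v = (beta(k) == 0.0) ? 0.0 : -beta(k) * t22;
      Theta(idx(k), j) = v;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("w") = W,
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iters);
}
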