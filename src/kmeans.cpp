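#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// k-means with cityblock (L1, median update) or squared-euclidean (mean update)
// distance, from a given initial centroid matrix. Empty clusters are re-seeded
// at the point farthest from its current centroid. Deterministic given init.
//
// metric: 0 = euclidean (inertia = sum of squared distances),
//         1 = cityblock (inertia = sum of L1 distances).
// [[Rcpp::export]]
Rcpp::List kmeans_core(const arma::mat& X, arma::mat cent, int metric,
                       int max_iter) {
  const int n = X.n_rows, k = cent.n_rows;
  uvec assign(n, fill::zeros);
  vec dmin(n);
  mat D(n, k);
  int iters = 0;
  bool changed = true;

  for (int it = 0; it < max_iter && changed; ++it) {
    iters = it + 1;
    // assignment step
    for (int c = 0; c < k; ++c) {
      rowvec cc = cent.row(c);
      if (metric == 1) D.col(c) = sum(abs(X.each_row() - cc), 1);
      else {
        mat R = X.each_row() - cc;
        D.col(c) = sum(R % R, 1);
      }
    }
    changed = false;
    for (int i = 0; i < n; ++i) {
      uword a;
      dmin(i) = D.row(i).min(a);
      if (a != assign(i)) { assign(i) = a; changed = true; }
    }
    // re-seed empty clusters at the globally farthest point; repeat in case
    // a reseed empties another cluster
    for (int pass = 0; pass < k; ++pass) {
      bool any_empty = false;
      for (int c = 0; c < k; ++c) {
        if (!any(assign == (uword)c)) {
          any_empty = true;
          uword far;
          if (dmin.max(far) <= 0) break;
          assign(far) = c;
          dmin(far) = 0.0;
          changed = true;
        }
      }
      if (!any_empty) break;
    }
    // update step (a still-empty cluster keeps its centroid)
    for (int c = 0; c < k; ++c) {
      uvec members = find(assign == (uword)c);
      if (members.n_elem == 0) continue;
      mat sub = X.rows(members);
      if (metric == 1) cent.row(c) = median(sub, 0);
      else cent.row(c) = mean(sub, 0);
    }
  }

  // final assignment and inertia under the updated centroids
  for (int c = 0; c < k; ++c) {
    rowvec cc = cent.row(c);
    if (metric == 1) D.col(c) = sum(abs(X.each_row() - cc), 1);
    else {
      mat R = X.each_row() - cc;
      D.col(c) = sum(R % R, 1);
    }
  }
  double inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    uword a;
    inertia += D.row(i).min(a);
    assign(i) = a;
  }

  return Rcpp::List::create(
    Rcpp::Named("assignment") = Rcpp::IntegerVector(assign.begin(), assign.end()),
    Rcpp::Named("centroids") = cent,
    Rcpp::Named("inertia") = inertia,
    Rcpp::Named("iterations") = iters);
}
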