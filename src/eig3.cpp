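// Batch eigen-decomposition of symmetric 3x3 tensors.
// Tensors arrive as an N x 6 matrix in the package-wide lower-triangular
// component order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Canonical sign: first component of magnitude > tol positive.
static inline void canonical_sign(arma::vec &v) {
  for (int i = 0; i < 3; ++i) {
    if (std::abs(v[i]) > 1e-12) {
      if (v[i] < 0) v = -v;
      return;
    }
  }
}

// [[Rcpp::export(name = ".eig_sym3_batch")]]
List eig_sym3_batch(const NumericMatrix &comp) {
  const int n = comp.nrow();
  NumericMatrix lambdas(n, 3);   // descending
  NumericMatrix vectors(n, 9);   // columns e1, e2, e3 flattened column-major
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    const double xx = comp(i, 0), xy = comp(i, 1), yy = comp(i, 2);
    const double xz = comp(i, 3), yz = comp(i, 4), zz = comp(i, 5);
    D(0, 0) = xx; D(0, 1) = xy; D(0, 2) = xz;
    D(1, 0) = xy; D(1, 1) = yy; D(1, 2) = yz;
    D(2, 0) = xz; D(2, 1) = yz; D(2, 2) = zz;
    if (!D.is_finite()) {
      for (int j = 0; j < 3; ++j) lambdas(i, j) = NA_REAL;
      for (int j = 0; j < 9; ++j) vectors(i, j) = NA_REAL;
      continue;
    }
    arma::eig_sym(ev, V, D);     // ascending
    for (int j = 0; j < 3; ++j) {
      arma::vec v = V.col(2 - j);
      canonical_sign(v);
      lambdas(i, j) = ev[2 - j];
      vectors(i, 3 * j + 0) = v[0];
      vectors(i, 3 * j + 1) = v[1];
      vectors(i, 3 * j + 2) = v[2];
    }
  }
  return List::create(_["lambdas"] = lambdas, _["vectors"] = vectors);
}
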