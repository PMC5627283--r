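// Batch tensor reorientation for warped tensor volumes.
// comp: N x 6 sampled tensors (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
// jac:  N x 9 local Jacobians F = I + du/dx of the pull-back map
//       (column-major 3x3 per row).
// method: 0 = finite strain (polar-decomposition rotation),
//         1 = preservation of principal directions (PPD).
// Pull-back convention: the output tensor is R' D R with R the rotation
// part of F (finite strain), or the PPD rotation built from F^-1 acting
// on the eigenvectors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat33 unpack6(const NumericMatrix &comp, int i) {
  arma::mat33 D;
  D(0, 0) = comp(i, 0); D(0, 1) = comp(i, 1); D(0, 2) = comp(i, 3);
  D(1, 0) = comp(i, 1); D(1, 1) = comp(i, 2); D(1, 2) = comp(i, 4);
  D(2, 0) = comp(i, 3); D(2, 1) = comp(i, 4); D(2, 2) = comp(i, 5);
  return D;
}

// [[Rcpp::export(name = ".reorient_batch")]]
NumericMatrix reorient_batch(const NumericMatrix &comp,
                             const NumericMatrix &jac,
                             const int method) {
  const int n = comp.nrow();
  NumericMatrix out(n, 6);
  arma::mat33 F, D, R, U, V;
  arma::vec3 s;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 9; ++c) F(c % 3, c / 3) = jac(i, c);
    D = unpack6(comp, i);
    bool ok = D.is_finite() && F.is_finite();
    if (ok) {
      if (method == 0) {
        ok = arma::svd(U, s, V, F);
        if (ok) {
          R = U * V.t();
          if (arma::det(R) < 0) {      // guard against reflections
            U.col(2) *= -1.0;
            R = U * V.t();
          }
          D = R.t() * D * R;
        }
      } else {
        arma::vec3 ev;
        arma::mat33 E;
        ok = arma::eig_sym(ev, E, D);  // ascending
        if (ok) {
          arma::mat33 Finv;
          ok = arma::inv(Finv, F);
          if (ok) {
            arma::vec3 e1 = E.col(2), e2 = E.col(1), e3 = E.col(0);
            arma::vec3 v1 = arma::normalise(Finv * e1);
            arma::vec3 w2 = Finv * e2;
            w2 -= arma::dot(w2, v1) * v1;
            double n2 = arma::norm(w2);
            arma::vec3 v2 = (n2 > 1e-12) ? arma::vec3(w2 / n2)
                                         : arma::vec3(arma::normalise(
                                               arma::cross(v1, e3)));
            arma::vec3 v3 = arma::cross(v1, v2);
            arma::mat33 Vnew, Eold;
            Vnew.col(0) = v1; Vnew.col(1) = v2; Vnew.col(2) = v3;
            Eold.col(0) = e1; Eold.col(1) = e2; Eold.col(2) = e3;
            arma::mat33 Rp = Vnew * Eold.t();
            D = Rp * D * Rp.t();
          }
        }
      }
    }
    if (!ok) {
      for (int c = 0; c < 6; ++c) out(i, c) = NA_REAL;
      continue;
    }
    out(i, 0) = D(0, 0); out(i, 1) = D(0, 1); out(i, 2) = D(1, 1);
    out(i, 3) = D(0, 2); out(i, 4) = D(1, 2); out(i, 5) = D(2, 2);
  }
  return out;
}
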