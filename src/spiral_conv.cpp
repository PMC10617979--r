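// Inner loops of the spiral convolution: per-neighbor gather + linear
// accumulation (forward) and the matching scatter-add (backward).
// gidx is (Bn x L), 1-based batched vertex indices; entries > Bn mark
// padding and contribute nothing. W is (L*Cin) x Cout, neighbor-major:
// rows ((l-1)*Cin+1):(l*Cin) belong to spiral position l.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
arma::mat conv_gather_mm(const arma::mat& X, const arma::imat& gidx,
                         const arma::mat& W, const arma::vec& b) {
  const arma::uword Bn = X.n_rows, Cin = X.n_cols;
  const arma::uword L = gidx.n_cols, Cout = W.n_cols;
  arma::mat Z(Bn, Cout);
  Z.each_row() = b.t();
  arma::mat G(Bn, Cin, arma::fill::none);
  for (arma::uword l = 0; l < L; ++l) {
    G.zeros();
    for (arma::uword i = 0; i < Bn; ++i) {
      const arma::sword t = gidx(i, l) - 1;
      if (t >= 0 && (arma::uword)t < Bn) G.row(i) = X.row(t);
    }
    Z += G * W.rows(l * Cin, (l + 1) * Cin - 1);
  }
  return Z;
}

// [[Rcpp::export(rng = false)]]
List conv_gather_bwd(const arma::mat& X, const arma::imat& gidx,
                     const arma::mat& W, const arma::mat& dZ) {
  const arma::uword Bn = X.n_rows, Cin = X.n_cols;
  const arma::uword L = gidx.n_cols, Cout = W.n_cols;
  arma::mat dX(Bn, Cin, arma::fill::zeros);
  arma::mat dW(L * Cin, Cout, arma::fill::zeros);
  arma::mat G(Bn, Cin, arma::fill::none);
  for (arma::uword l = 0; l < L; ++l) {
    G.zeros();
    for (arma::uword i = 0; i < Bn; ++i) {
      const arma::sword t = gidx(i, l) - 1;
      if (t >= 0 && (arma::uword)t < Bn) G.row(i) = X.row(t);
    }
    dW.rows(l * Cin, (l + 1) * Cin - 1) = G.t() * dZ;
    arma::mat Sl = dZ * W.rows(l * Cin, (l + 1) * Cin - 1).t();
    for (arma::uword i = 0; i < Bn; ++i) {
      const arma::sword t = gidx(i, l) - 1;
      if (t >= 0 && (arma::uword)t < Bn) dX.row(t) += Sl.row(i);
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW);
}
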