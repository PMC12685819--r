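// Batched multi-head self-attention forward/backward. Layout convention:
// activations arrive as (T, D, B) cubes (time x channels x sample) so each
// sample is a contiguous slice; attention probabilities are stored as a
// (T, T, B * heads) cube with slice index (b * heads + h). Row r of an
// attention matrix is the softmax over key positions for query position r,
// matching the R reference implementation bit-for-bit up to BLAS ordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void softmax_rows_inplace(arma::mat &S) {
  for (arma::uword r = 0; r < S.n_rows; ++r) {
    double m = S.row(r).max();
    arma::rowvec e = arma::exp(S.row(r) - m);
    S.row(r) = e / arma::accu(e);
  }
}

// [[Rcpp::export(name = ".cpp_att_forward")]]
List cpp_att_forward(const arma::cube &Q, const arma::cube &K,
                     const arma::cube &V, const int heads) {
  const arma::uword T = Q.n_rows, D = Q.n_cols, B = Q.n_slices;
  const arma::uword dk = D / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::cube O(T, D, B), P(T, T, B * heads);
  for (arma::uword b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      arma::mat S = Q.slice(b).cols(c0, c1) * K.slice(b).cols(c0, c1).t() * scale;
      softmax_rows_inplace(S);
      P.slice(b * heads + h) = S;
      O.slice(b).cols(c0, c1) = S * V.slice(b).cols(c0, c1);
    }
  }
  return List::create(Named("O") = O, Named("P") = P);
}

// [[Rcpp::export(name = ".cpp_att_backward")]]
List cpp_att_backward(const arma::cube &Q, const arma::cube &K,
                      const arma::cube &V, const arma::cube &P,
                      const arma::cube &dO, const int heads) {
  const arma::uword T = Q.n_rows, D = Q.n_cols, B = Q.n_slices;
  const arma::uword dk = D / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::cube dQ(T, D, B, arma::fill::zeros), dK(T, D, B, arma::fill::zeros),
      dV(T, D, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      const arma::mat &Pb = P.slice(b * heads + h);
      arma::mat dOh = dO.slice(b).cols(c0, c1);
      arma::mat dP = dOh * V.slice(b).cols(c0, c1).t();
      dV.slice(b).cols(c0, c1) = Pb.t() * dOh;
      arma::vec rs = arma::sum(dP % Pb, 1);   // per-query row sums
      dP.each_col() -= rs;
      arma::mat dS = (Pb % dP) * scale;
      dQ.slice(b).cols(c0, c1) = dS * K.slice(b).cols(c0, c1);
      dK.slice(b).cols(c0, c1) = dS.t() * Q.slice(b).cols(c0, c1);
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
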