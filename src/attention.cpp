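// Hot kernels for the hand-written encoders: per-image multi-head attention
// (forward and backward) and the quick-GELU nonlinearity. Everything else
// stays in R; these loops dominate the training step there.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Q, K, V: (B * Tn) x D matrices, rows grouped by image; heads split D into
// contiguous dh-column slabs. Returns the attention output O and the
// attention weights A (Tn x Tn x (B * heads)) needed for the backward pass.
// [[Rcpp::export(name = ".cpp_mha_fwd")]]
List cpp_mha_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 int B, int Tn, int heads) {
  const int D = Q.n_cols;
  const int dh = D / heads;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat O(Q.n_rows, D, arma::fill::zeros);
  arma::cube A(Tn, Tn, (size_t) B * heads);
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword) b * Tn;
    const arma::uword r1 = r0 + Tn - 1;
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = (arma::uword) h * dh;
      const arma::uword c1 = c0 + dh - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t();
      S *= sc;
      // row-wise softmax
      arma::vec m = arma::max(S, 1);
      S.each_col() -= m;
      S = arma::exp(S);
      arma::vec rs = arma::sum(S, 1);
      S.each_col() /= rs;
      A.slice((size_t) b * heads + h) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(name = ".cpp_mha_bwd")]]
List cpp_mha_bwd(const arma::mat& dO, const arma::mat& Q, const arma::mat& K,
                 const arma::mat& V, const arma::cube& A,
                 int B, int Tn, int heads) {
  const int D = Q.n_cols;
  const int dh = D / heads;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat dQ(Q.n_rows, D, arma::fill::zeros);
  arma::mat dK(Q.n_rows, D, arma::fill::zeros);
  arma::mat dV(Q.n_rows, D, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword) b * Tn;
    const arma::uword r1 = r0 + Tn - 1;
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = (arma::uword) h * dh;
      const arma::uword c1 = c0 + dh - 1;
      const arma::mat& Ah = A.slice((size_t) b * heads + h);
      arma::mat dOb = dO.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat dA = dOb * Vb.t();
      dV.submat(r0, c0, r1, c1) = Ah.t() * dOb;
      // softmax backward: dS = A o (dA - rowsum(dA o A))
      arma::vec rs = arma::sum(dA % Ah, 1);
      arma::mat dS = Ah % (dA.each_col() - rs);
      dS *= sc;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// quick-GELU: x * sigmoid(1.702 x)
// [[Rcpp::export(name = ".cpp_gelu_fwd")]]
List cpp_gelu_fwd(const arma::mat& X) {
  arma::mat s = 1.0 / (1.0 + arma::exp(-1.702 * X));
  return List::create(_["out"] = X % s, _["s"] = s);
}

// [[Rcpp::export(name = ".cpp_gelu_bwd")]]
arma::mat cpp_gelu_bwd(const arma::mat& G, const arma::mat& X,
                       const arma::mat& s) {
  return G % (s + 1.702 * X % s % (1.0 - s));
}
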