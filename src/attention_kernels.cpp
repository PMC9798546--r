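// Masked multi-head attention kernels.
//
// Layout conventions shared with the R side:
//  * Stacked matrices: a batch of B molecules padded to N atoms is stored as a
//    (B*N) x d matrix, molecule b occupying rows b*N .. b*N + n_b - 1
//    (0-based); padded rows are zero and are never read or written.
//  * Per-molecule square matrices (adjacency, exp(-D)) come in as N x N x B
//    cubes; only the leading n_b x n_b block of each slice is used.
//  * Encoder softmax matrices are returned as an N x N x (B*H) cube, slice
//    b*H + h holding head h of molecule b.
//
// Masking semantics follow the model definition exactly: the softmax is taken
// over real atoms only, and the multiplicative mask (adjacency or exp(-D)) is
// applied AFTER the softmax with no renormalization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::span;
using arma::uword;

static void softmax_rows(mat& S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    rowvec e = arma::exp(S.row(i) - m);
    S.row(i) = e / arma::accu(e);
  }
}

// mode 0: ctx_h = (P % M) * V_h          (proposed branches, adj_only, dist_only)
// mode 1: ctx_h = (l1*P + l2*M + l3*M2) * V_h   (MAT attention; M = g(D), M2 = A)
// [[Rcpp::export(name = ".enc_attn_fwd")]]
List enc_attn_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const arma::cube& M, const arma::cube& M2,
                  const arma::ivec& nat, int H, int mode,
                  double l1, double l2, double l3) {
  const int B = nat.n_elem;
  const uword N = M.n_rows;
  const uword dm = Q.n_cols;
  const uword dk = dm / H;
  const double sc = 1.0 / std::sqrt((double)dk);

  mat ctx(Q.n_rows, dm, arma::fill::zeros);
  cube P(N, N, (uword)B * H, arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    const uword n = nat(b);
    if (n == 0) continue;
    const uword r0 = (uword)b * N;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dk;
      mat Qh = Q(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Kh = K(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Vh = V(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat S = Qh * Kh.t() * sc;
      softmax_rows(S);
      P.slice((uword)b * H + h)(span(0, n - 1), span(0, n - 1)) = S;
      mat W;
      if (mode == 0) {
        W = S % M.slice(b)(span(0, n - 1), span(0, n - 1));
      } else {
        W = l1 * S + l2 * M.slice(b)(span(0, n - 1), span(0, n - 1)) +
            l3 * M2.slice(b)(span(0, n - 1), span(0, n - 1));
      }
      ctx(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) = W * Vh;
    }
  }
  return List::create(_["ctx"] = ctx, _["P"] = P);
}

// [[Rcpp::export(name = ".enc_attn_bwd")]]
List enc_attn_bwd(const arma::mat& dctx, const arma::cube& P,
                  const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const arma::cube& M, const arma::cube& M2,
                  const arma::ivec& nat, int H, int mode,
                  double l1, double l2, double l3) {
  const int B = nat.n_elem;
  const uword N = M.n_rows;
  const uword dm = Q.n_cols;
  const uword dk = dm / H;
  const double sc = 1.0 / std::sqrt((double)dk);

  mat dQ(Q.n_rows, dm, arma::fill::zeros);
  mat dK(Q.n_rows, dm, arma::fill::zeros);
  mat dV(Q.n_rows, dm, arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    const uword n = nat(b);
    if (n == 0) continue;
    const uword r0 = (uword)b * N;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dk;
      mat Qh = Q(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Kh = K(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Vh = V(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat dctxh = dctx(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Ph = P.slice((uword)b * H + h)(span(0, n - 1), span(0, n - 1));
      mat dP;
      if (mode == 0) {
        mat Mh = M.slice(b)(span(0, n - 1), span(0, n - 1));
        mat Wm = Ph % Mh;
        dV(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) = Wm.t() * dctxh;
        dP = (dctxh * Vh.t()) % Mh;
      } else {
        mat Wm = l1 * Ph + l2 * M.slice(b)(span(0, n - 1), span(0, n - 1)) +
                 l3 * M2.slice(b)(span(0, n - 1), span(0, n - 1));
        dV(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) = Wm.t() * dctxh;
        dP = l1 * (dctxh * Vh.t());
      }
      // softmax backward, rowwise
      arma::vec rs = arma::sum(dP % Ph, 1);
      mat dS = Ph % (dP - arma::repmat(rs, 1, n));
      dQ(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) = dS * Kh * sc;
      dK(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) = dS.t() * Qh * sc;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Cross-attention with a single query row per molecule (decoder-like module).
// Qr: B x dm projected queries; K, V stacked (B*N) x dm.
// Returns ctx (B x dm) and softmax weights P as an H x N x B cube.
// [[Rcpp::export(name = ".dec_attn_fwd")]]
List dec_attn_fwd(const arma::mat& Qr, const arma::mat& K, const arma::mat& V,
                  const arma::ivec& nat, int H) {
  const int B = nat.n_elem;
  const uword N = K.n_rows / B;
  const uword dm = Qr.n_cols;
  const uword dk = dm / H;
  const double sc = 1.0 / std::sqrt((double)dk);

  mat ctx(B, dm, arma::fill::zeros);
  cube P(H, N, B, arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    const uword n = nat(b);
    if (n == 0) continue;
    const uword r0 = (uword)b * N;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dk;
      rowvec qh = Qr(b, span(c0, c0 + dk - 1));
      mat Kh = K(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Vh = V(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      rowvec s = qh * Kh.t() * sc;
      s -= s.max();
      rowvec e = arma::exp(s);
      rowvec p = e / arma::accu(e);
      P.slice(b)(h, span(0, n - 1)) = p;
      ctx(b, span(c0, c0 + dk - 1)) = p * Vh;
    }
  }
  return List::create(_["ctx"] = ctx, _["P"] = P);
}

// [[Rcpp::export(name = ".dec_attn_bwd")]]
List dec_attn_bwd(const arma::mat& dctx, const arma::cube& P,
                  const arma::mat& Qr, const arma::mat& K, const arma::mat& V,
                  const arma::ivec& nat, int H) {
  const int B = nat.n_elem;
  const uword N = K.n_rows / B;
  const uword dm = Qr.n_cols;
  const uword dk = dm / H;
  const double sc = 1.0 / std::sqrt((double)dk);

  mat dQr(B, dm, arma::fill::zeros);
  mat dK(K.n_rows, dm, arma::fill::zeros);
  mat dV(K.n_rows, dm, arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    const uword n = nat(b);
    if (n == 0) continue;
    const uword r0 = (uword)b * N;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dk;
      rowvec qh = Qr(b, span(c0, c0 + dk - 1));
      mat Kh = K(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      mat Vh = V(span(r0, r0 + n - 1), span(c0, c0 + dk - 1));
      rowvec p = P.slice(b)(h, span(0, n - 1));
      rowvec dctxh = dctx(b, span(c0, c0 + dk - 1));
      dV(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) += p.t() * dctxh;
      rowvec dp = dctxh * Vh.t();
      rowvec ds = p % (dp - arma::accu(dp % p));
      dQr(b, span(c0, c0 + dk - 1)) = ds * Kh * sc;
      dK(span(r0, r0 + n - 1), span(c0, c0 + dk - 1)) += ds.t() * qh * sc;
    }
  }
  return List::create(_["dQr"] = dQr, _["dK"] = dK, _["dV"] = dV);
}
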