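// Compiled cores for the Self-ONN operational convolution and the
// scaled-dot-product multi-head attention block.  Tensors use the
// (channel, time, batch) layout: an R array dim c(C, L, B) maps onto an
// arma::cube with C rows, L columns and B slices.
//
// The operational convolution computes, per output channel k and output
// position m,
//   y[k, m] = b[k] + sum_i sum_r sum_q W[k, i, r, q] * x[i, m*s + r - p]^q
// (correlation convention, zero padding).  The powered im2col matrix has
// row index q-1 + Q*(r + K*i) so that the whole sum is one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube powered_im2col(const arma::cube& x, int K, int Q,
                                 int stride, int pad, int Lout) {
  const int Cin = x.n_rows;
  const int L = x.n_cols;
  const int B = x.n_slices;
  arma::cube cols(Cin * K * Q, Lout, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat& xs = x.slice(b);
    arma::mat& cs = cols.slice(b);
    for (int m = 0; m < Lout; ++m) {
      const int base = m * stride - pad;
      for (int i = 0; i < Cin; ++i) {
        for (int r = 0; r < K; ++r) {
          const int pos = base + r;
          if (pos < 0 || pos >= L) continue;  // zero padding: rows stay 0
          const double v = xs(i, pos);
          double p = 1.0;
          const int row0 = Q * (r + K * i);
          for (int q = 0; q < Q; ++q) {
            p *= v;
            cs(row0 + q, m) = p;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List cpp_selfonn_conv_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& bias, int K, int Q, int stride,
                          int pad, bool has_bias, bool keep_cache) {
  const int L = x.n_cols;
  const int B = x.n_slices;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  if (Lout < 1) stop("input too short for kernel: no valid output positions");
  arma::cube cols = powered_im2col(x, K, Q, stride, pad, Lout);
  arma::cube y(W.n_rows, Lout, B);
  for (int b = 0; b < B; ++b) {
    y.slice(b) = W * cols.slice(b);
    if (has_bias) y.slice(b).each_col() += bias;
  }
  if (keep_cache) return List::create(_["y"] = y, _["cols"] = cols);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_selfonn_conv_bwd(const arma::cube& x, const arma::cube& cols,
                          const arma::mat& W, const arma::cube& dy, int K,
                          int Q, int stride, int pad, bool has_bias) {
  const int Cin = x.n_rows;
  const int L = x.n_cols;
  const int B = x.n_slices;
  const int Lout = dy.n_cols;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::cube dx(Cin, L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dW += dy.slice(b) * cols.slice(b).t();
    if (has_bias) db += arma::sum(dy.slice(b), 1);
    arma::mat dcol = W.t() * dy.slice(b);  // (Cin*K*Q) x Lout
    const arma::mat& cs = cols.slice(b);
    arma::mat& dxs = dx.slice(b);
    for (int m = 0; m < Lout; ++m) {
      const int base = m * stride - pad;
      for (int i = 0; i < Cin; ++i) {
        for (int r = 0; r < K; ++r) {
          const int pos = base + r;
          if (pos < 0 || pos >= L) continue;
          const int row0 = Q * (r + K * i);
          double acc = dcol(row0, m);  // q = 1 term: d(v^1)/dv = 1
          for (int q = 2; q <= Q; ++q)
            acc += dcol(row0 + q - 1, m) * q * cs(row0 + q - 2, m);
          dxs(i, pos) += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Brute-force reference for the operational convolution: explicit nested
// loops over k, i, m, r, q with no im2col/GEMM shortcut.  Kept in C++ only
// for speed of the randomized equivalence sweeps; an additional pure-R
// reference lives in R/selfonn-core.R.
// [[Rcpp::export]]
arma::cube cpp_selfonn_conv_naive(const arma::cube& x, const arma::vec& Wv,
                                  const arma::vec& bias, int Cout, int Cin,
                                  int K, int Q, int stride, int pad,
                                  bool has_bias) {
  const int L = x.n_cols;
  const int B = x.n_slices;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  if (Lout < 1) stop("input too short for kernel: no valid output positions");
  // Wv is the R array dim c(Cout, Cin, K, Q) in column-major order.
  auto Wat = [&](int k, int i, int r, int q) {
    return Wv[k + Cout * (i + Cin * (r + K * q))];
  };
  arma::cube y(Cout, Lout, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < Cout; ++k) {
      for (int m = 0; m < Lout; ++m) {
        double acc = has_bias ? bias[k] : 0.0;
        for (int i = 0; i < Cin; ++i) {
          for (int r = 0; r < K; ++r) {
            const int pos = m * stride + r - pad;
            if (pos < 0 || pos >= L) continue;
            const double v = x(i, pos, b);
            for (int q = 1; q <= Q; ++q)
              acc += Wat(k, i, r, q - 1) * std::pow(v, q);
          }
        }
        y(k, m, b) = acc;
      }
    }
  }
  return y;
}

// Multi-head attention over time tokens.  query/key/value inputs are
// (C, T, B) cubes; projections Wq, Wk, Wv, Wo are C x C.  Head h uses the
// row block h*d .. h*d+d-1 with d = C/heads.  Attention weights are held
// key-major: A(j, m) is the weight of key/value token j for query token m,
// so the softmax runs down contiguous columns.
// [[Rcpp::export]]
List cpp_mha_fwd(const arma::cube& xq, const arma::cube& xk,
                 const arma::cube& xv, const arma::mat& Wq,
                 const arma::mat& Wk, const arma::mat& Wv, const arma::mat& Wo,
                 int heads, bool keep_cache) {
  const int C = xq.n_rows;
  const int T = xq.n_cols;
  const int B = xq.n_slices;
  const int d = C / heads;
  const double scale = 1.0 / std::sqrt((double)d);
  arma::cube y(C, T, B), Qp(C, T, B), Kp(C, T, B), Vp(C, T, B), O(C, T, B);
  arma::cube A(T, T, keep_cache ? B * heads : 0);
  arma::mat Ah(T, T);
  for (int b = 0; b < B; ++b) {
    Qp.slice(b) = Wq * xq.slice(b);
    Kp.slice(b) = Wk * xk.slice(b);
    Vp.slice(b) = Wv * xv.slice(b);
    for (int h = 0; h < heads; ++h) {
      arma::mat Qh = Qp.slice(b).rows(h * d, h * d + d - 1);
      arma::mat Kh = Kp.slice(b).rows(h * d, h * d + d - 1);
      arma::mat Vh = Vp.slice(b).rows(h * d, h * d + d - 1);
      Ah = Kh.t() * Qh * scale;               // A(j, m): key j, query m
      Ah.each_row() -= arma::max(Ah, 0);
      Ah = arma::exp(Ah);
      Ah.each_row() /= arma::sum(Ah, 0);      // each query column sums to 1
      O.slice(b).rows(h * d, h * d + d - 1) = Vh * Ah;
      if (keep_cache) A.slice(b * heads + h) = Ah;
    }
    y.slice(b) = Wo * O.slice(b);
  }
  if (!keep_cache) return List::create(_["y"] = y);
  return List::create(_["y"] = y, _["A"] = A, _["Qp"] = Qp, _["Kp"] = Kp,
                      _["Vp"] = Vp, _["O"] = O);
}

// [[Rcpp::export]]
List cpp_mha_bwd(const arma::cube& xq, const arma::cube& xk,
                 const arma::cube& xv, const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo, int heads,
                 const arma::cube& A, const arma::cube& Qp,
                 const arma::cube& Kp, const arma::cube& Vp,
                 const arma::cube& O, const arma::cube& dy) {
  const int C = xq.n_rows;
  const int T = xq.n_cols;
  const int B = xq.n_slices;
  const int d = C / heads;
  const double scale = 1.0 / std::sqrt((double)d);
  arma::mat dWq(C, C, arma::fill::zeros), dWk(C, C, arma::fill::zeros);
  arma::mat dWv(C, C, arma::fill::zeros), dWo(C, C, arma::fill::zeros);
  arma::cube dxq(C, T, B, arma::fill::zeros), dxk(C, T, B, arma::fill::zeros);
  arma::cube dxv(C, T, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dWo += dy.slice(b) * O.slice(b).t();
    arma::mat dO = Wo.t() * dy.slice(b);
    arma::mat dQp(C, T), dKp(C, T), dVp(C, T);
    for (int h = 0; h < heads; ++h) {
      const arma::mat& Ah = A.slice(b * heads + h);  // key-major: A(j, m)
      arma::mat Qh = Qp.slice(b).rows(h * d, h * d + d - 1);
      arma::mat Kh = Kp.slice(b).rows(h * d, h * d + d - 1);
      arma::mat Vh = Vp.slice(b).rows(h * d, h * d + d - 1);
      arma::mat dOh = dO.rows(h * d, h * d + d - 1);
      dVp.rows(h * d, h * d + d - 1) = dOh * Ah.t();  // from Oh = Vh * Ah
      arma::mat dA = Vh.t() * dOh;            // dA(j, m)
      arma::rowvec coldot = arma::sum(dA % Ah, 0);
      arma::mat dS = Ah % (dA.each_row() - coldot);   // softmax per column
      dQp.rows(h * d, h * d + d - 1) = Kh * dS * scale;
      dKp.rows(h * d, h * d + d - 1) = Qh * dS.t() * scale;
    }
    dWq += dQp * xq.slice(b).t();
    dWk += dKp * xk.slice(b).t();
    dWv += dVp * xv.slice(b).t();
    dxq.slice(b) = Wq.t() * dQp;
    dxk.slice(b) = Wk.t() * dKp;
    dxv.slice(b) = Wv.t() * dVp;
  }
  return List::create(_["dxq"] = dxq, _["dxk"] = dxk, _["dxv"] = dxv,
                      _["dWq"] = dWq, _["dWk"] = dWk, _["dWv"] = dWv,
                      _["dWo"] = dWo);
}
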