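// Fused forward/backward runtime for the Self-ResNet18 / Self-ResAttentioNet18
// topology.  Mirrors, layer for layer, the reference R implementation in
// R/layers.R + R/network.R (which the test suite checks it against); it
// exists so the training loop does not round-trip feature maps and caches
// through R on every mini-batch.  Parameters and batch-norm running
// statistics are read from (and, for the running stats, updated in) the R
// objects by reference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvSpec {
  int Cin, Cout, K, Q, stride, pad;
  bool bias;
};

// Flatten an R (O, I, K, Q) weight array into the (O x I*K*Q) GEMM matrix;
// column index runs q fastest, then tap, then input channel.
void flatten_W_into(const NumericVector& w, const ConvSpec& s, arma::mat& W) {
  const double* p = w.begin();
  for (int q = 0; q < s.Q; ++q)
    for (int r = 0; r < s.K; ++r)
      for (int i = 0; i < s.Cin; ++i)
        for (int k = 0; k < s.Cout; ++k)
          W(k, q + s.Q * (r + s.K * i)) = p[k + s.Cout * (i + s.Cin * (r + s.K * q))];
}

NumericVector unflatten_dW(const arma::mat& dW, const ConvSpec& s) {
  NumericVector out(s.Cout * s.Cin * s.K * s.Q);
  out.attr("dim") = IntegerVector::create(s.Cout, s.Cin, s.K, s.Q);
  double* p = out.begin();
  for (int q = 0; q < s.Q; ++q)
    for (int r = 0; r < s.K; ++r)
      for (int i = 0; i < s.Cin; ++i)
        for (int k = 0; k < s.Cout; ++k)
          p[k + s.Cout * (i + s.Cin * (r + s.K * q))] = dW(k, q + s.Q * (r + s.K * i));
  return out;
}

void im2col_pow(const arma::cube& x, const ConvSpec& s, arma::cube& cols,
                int Lout) {
  const int L = x.n_cols, B = x.n_slices;
  cols.zeros(s.Cin * s.K * s.Q, Lout, B);
  for (int b = 0; b < B; ++b) {
    const arma::mat& xs = x.slice(b);
    arma::mat& cs = cols.slice(b);
    for (int m = 0; m < Lout; ++m) {
      const int base = m * s.stride - s.pad;
      for (int i = 0; i < s.Cin; ++i)
        for (int r = 0; r < s.K; ++r) {
          const int pos = base + r;
          if (pos < 0 || pos >= L) continue;
          const double v = xs(i, pos);
          double pw = 1.0;
          const int row0 = s.Q * (r + s.K * i);
          for (int q = 0; q < s.Q; ++q) { pw *= v; cs(row0 + q, m) = pw; }
        }
    }
  }
}

struct ConvLayer {
  ConvSpec s;
  arma::mat W;
  arma::vec b;
  std::string name;
  arma::cube x, cols, y;  // caches

  void configure(const std::string& nm, ConvSpec spec) {
    s = spec;
    name = nm;
    W.set_size(s.Cout, s.Cin * s.K * s.Q);
  }
  void load(List& params) {
    flatten_W_into(params[name + ".W"], s, W);
    if (s.bias) b = as<arma::vec>(params[name + ".b"]);
  }
  void fwd(const arma::cube& xin, bool keep) {
    const int L = xin.n_cols, B = xin.n_slices;
    const int Lout = (L + 2 * s.pad - s.K) / s.stride + 1;
    if (Lout < 1) stop("input too short for kernel");
    im2col_pow(xin, s, cols, Lout);
    y.set_size(s.Cout, Lout, B);
    for (int b_ = 0; b_ < B; ++b_) {
      y.slice(b_) = W * cols.slice(b_);
      if (s.bias) y.slice(b_).each_col() += b;
    }
    if (keep) x = xin;
  }
  arma::cube bwd(const arma::cube& dy, List& grads) {
    const int B = x.n_slices, L = x.n_cols, Lout = dy.n_cols;
    arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
    arma::vec db(W.n_rows, arma::fill::zeros);
    arma::cube dx(s.Cin, L, B, arma::fill::zeros);
    for (int b_ = 0; b_ < B; ++b_) {
      dW += dy.slice(b_) * cols.slice(b_).t();
      if (s.bias) db += arma::sum(dy.slice(b_), 1);
      arma::mat dcol = W.t() * dy.slice(b_);
      const arma::mat& cs = cols.slice(b_);
      arma::mat& dxs = dx.slice(b_);
      for (int m = 0; m < Lout; ++m) {
        const int base = m * s.stride - s.pad;
        for (int i = 0; i < s.Cin; ++i)
          for (int r = 0; r < s.K; ++r) {
            const int pos = base + r;
            if (pos < 0 || pos >= L) continue;
            const int row0 = s.Q * (r + s.K * i);
            double acc = dcol(row0, m);
            for (int q = 2; q <= s.Q; ++q)
              acc += dcol(row0 + q - 1, m) * q * cs(row0 + q - 2, m);
            dxs(i, pos) += acc;
          }
      }
    }
    grads[name + ".W"] = unflatten_dW(dW, s);
    if (s.bias) grads[name + ".b"] = wrap(db);
    return dx;
  }
};

struct BNLayer {
  arma::vec gamma, beta;
  NumericVector run_mean, run_var;  // views into R buffers (updated in place)
  std::string name;
  arma::cube xhat;
  arma::vec inv;
  int n = 0;
  bool training = false;
  double momentum = 0.1, eps = 1e-5;

  void configure(const std::string& nm) { name = nm; }
  void load(List& params, Environment& buffers) {
    gamma = as<arma::vec>(params[name + ".gamma"]);
    beta = as<arma::vec>(params[name + ".beta"]);
    run_mean = buffers[name + ".running_mean"];
    run_var = buffers[name + ".running_var"];
  }
  arma::cube fwd(const arma::cube& x, bool train, bool keep) {
    training = train;
    const int C = x.n_rows;
    n = x.n_cols * x.n_slices;
    arma::vec mu(C), va(C);
    if (train) {
      mu.zeros(); va.zeros();
      for (arma::uword b = 0; b < x.n_slices; ++b) {
        mu += arma::sum(x.slice(b), 1);
        va += arma::sum(arma::square(x.slice(b)), 1);
      }
      mu /= n;
      va = va / n - arma::square(mu);
      const double unb = n > 1 ? (double)n / (n - 1) : 1.0;
      for (int c = 0; c < C; ++c) {
        run_mean[c] = (1 - momentum) * run_mean[c] + momentum * mu[c];
        run_var[c] = (1 - momentum) * run_var[c] + momentum * va[c] * unb;
      }
    } else {
      mu = as<arma::vec>(run_mean);
      va = as<arma::vec>(run_var);
    }
    inv = 1.0 / arma::sqrt(va + eps);
    arma::cube out(arma::size(x));
    arma::cube xh(arma::size(x));
    for (arma::uword b = 0; b < x.n_slices; ++b) {
      xh.slice(b) = (x.slice(b).each_col() - mu).eval().each_col() % inv;
      out.slice(b) = (xh.slice(b).each_col() % gamma).eval().each_col() + beta;
    }
    if (keep) xhat = xh;
    return out;
  }
  arma::cube bwd(const arma::cube& dy, List& grads) {
    const int C = dy.n_rows;
    arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
    arma::vec sum_dxhat(C, arma::fill::zeros), sum_dxhat_xhat(C, arma::fill::zeros);
    for (arma::uword b = 0; b < dy.n_slices; ++b) {
      dgamma += arma::sum(dy.slice(b) % xhat.slice(b), 1);
      dbeta += arma::sum(dy.slice(b), 1);
    }
    grads[name + ".gamma"] = wrap(dgamma);
    grads[name + ".beta"] = wrap(dbeta);
    arma::cube dxhat(arma::size(dy));
    for (arma::uword b = 0; b < dy.n_slices; ++b)
      dxhat.slice(b) = dy.slice(b).each_col() % gamma;
    if (!training) {
      for (arma::uword b = 0; b < dxhat.n_slices; ++b)
        dxhat.slice(b).each_col() %= inv;
      return dxhat;
    }
    for (arma::uword b = 0; b < dy.n_slices; ++b) {
      sum_dxhat += arma::sum(dxhat.slice(b), 1);
      sum_dxhat_xhat += arma::sum(dxhat.slice(b) % xhat.slice(b), 1);
    }
    arma::cube dx(arma::size(dy));
    for (arma::uword b = 0; b < dy.n_slices; ++b)
      dx.slice(b) = ((dxhat.slice(b).each_col() - sum_dxhat / n) -
                     xhat.slice(b).each_col() % (sum_dxhat_xhat / n))
                        .eval()
                        .each_col() % inv;
    return dx;
  }
};

// Fused per-query-column softmax of S (key-major), in place.
inline void softmax_cols(arma::fmat& S) {
  const arma::uword T = S.n_rows;
  for (arma::uword m = 0; m < S.n_cols; ++m) {
    float* c = S.colptr(m);
    float mx = c[0];
    for (arma::uword j = 1; j < T; ++j) mx = std::max(mx, c[j]);
    float sum = 0;
    for (arma::uword j = 0; j < T; ++j) { c[j] = std::exp(c[j] - mx); sum += c[j]; }
    const float is = 1.0f / sum;
    for (arma::uword j = 0; j < T; ++j) c[j] *= is;
  }
}

// The T x T score/weight matrices are held and processed in single
// precision (standard deep-learning practice); projections, inputs and
// accumulated gradients stay double.
struct MHALayer {
  arma::mat Wq, Wk, Wv, Wo;
  int heads = 2;
  std::string name;
  arma::cube xq, xk, Qp, Kp, Vp, O;  // caches (xv == xq by construction)
  arma::fcube A;

  void configure(const std::string& nm, int h) {
    name = nm;
    heads = h;
  }
  void load(List& params) {
    Wq = as<arma::mat>(params[name + ".Wq"]);
    Wk = as<arma::mat>(params[name + ".Wk"]);
    Wv = as<arma::mat>(params[name + ".Wv"]);
    Wo = as<arma::mat>(params[name + ".Wo"]);
  }
  // query = value = identity (block input), key = block output
  arma::cube fwd(const arma::cube& ident, const arma::cube& blk, bool keep) {
    const int C = ident.n_rows, T = ident.n_cols, B = ident.n_slices;
    const int d = C / heads;
    const float scale = 1.0f / std::sqrt((float)d);
    arma::cube y(C, T, B);
    Qp.set_size(C, T, B); Kp.set_size(C, T, B); Vp.set_size(C, T, B);
    O.set_size(C, T, B);
    if (keep) A.set_size(T, T, B * heads);
    arma::fmat Ah;
    for (int b = 0; b < B; ++b) {
      Qp.slice(b) = Wq * ident.slice(b);
      Kp.slice(b) = Wk * blk.slice(b);
      Vp.slice(b) = Wv * ident.slice(b);
      for (int h = 0; h < heads; ++h) {
        const int r0 = h * d, r1 = h * d + d - 1;
        arma::fmat Qh = arma::conv_to<arma::fmat>::from(Qp.slice(b).rows(r0, r1));
        arma::fmat Kh = arma::conv_to<arma::fmat>::from(Kp.slice(b).rows(r0, r1));
        arma::fmat Vh = arma::conv_to<arma::fmat>::from(Vp.slice(b).rows(r0, r1));
        Ah = Kh.t() * Qh * scale;
        softmax_cols(Ah);
        O.slice(b).rows(r0, r1) =
            arma::conv_to<arma::mat>::from(arma::fmat(Vh * Ah));
        if (keep) A.slice(b * heads + h) = Ah;
      }
      y.slice(b) = Wo * O.slice(b);
    }
    if (keep) { xq = ident; xk = blk; }
    return y;
  }
  // returns dident (query+value paths) and adds the key path into dblk
  arma::cube bwd(const arma::cube& dy, arma::cube& dblk, List& grads) {
    const int C = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
    const int d = C / heads;
    const float scale = 1.0f / std::sqrt((float)d);
    arma::mat dWq(C, C, arma::fill::zeros), dWk(C, C, arma::fill::zeros);
    arma::mat dWv(C, C, arma::fill::zeros), dWo(C, C, arma::fill::zeros);
    arma::cube dident(C, T, B);
    arma::mat dQp(C, T), dKp(C, T), dVp(C, T);
    for (int b = 0; b < B; ++b) {
      dWo += dy.slice(b) * O.slice(b).t();
      arma::mat dO = Wo.t() * dy.slice(b);
      for (int h = 0; h < heads; ++h) {
        const int r0 = h * d, r1 = h * d + d - 1;
        const arma::fmat& Ah = A.slice(b * heads + h);
        arma::fmat dOh = arma::conv_to<arma::fmat>::from(dO.rows(r0, r1));
        arma::fmat Vh = arma::conv_to<arma::fmat>::from(Vp.slice(b).rows(r0, r1));
        dVp.rows(r0, r1) = arma::conv_to<arma::mat>::from(arma::fmat(dOh * Ah.t()));
        arma::fmat dA = Vh.t() * dOh;
        arma::frowvec coldot = arma::sum(dA % Ah, 0);
        arma::fmat dS = Ah % (dA.each_row() - coldot);
        arma::fmat Qh = arma::conv_to<arma::fmat>::from(Qp.slice(b).rows(r0, r1));
        arma::fmat Kh = arma::conv_to<arma::fmat>::from(Kp.slice(b).rows(r0, r1));
        dQp.rows(r0, r1) = arma::conv_to<arma::mat>::from(arma::fmat(Kh * dS * scale));
        dKp.rows(r0, r1) = arma::conv_to<arma::mat>::from(arma::fmat(Qh * dS.t() * scale));
      }
      dWq += dQp * xq.slice(b).t();
      dWk += dKp * xk.slice(b).t();
      dWv += dVp * xq.slice(b).t();
      dident.slice(b) = Wq.t() * dQp + Wv.t() * dVp;
      dblk.slice(b) += Wk.t() * dKp;
    }
    grads[name + ".Wq"] = wrap(dWq);
    grads[name + ".Wk"] = wrap(dWk);
    grads[name + ".Wv"] = wrap(dWv);
    grads[name + ".Wo"] = wrap(dWo);
    return dident;
  }
};

struct Block {
  ConvLayer conv1, conv2, shortcut;
  BNLayer bn1, bn2;
  MHALayer attn;
  bool has_shortcut = false, has_attn = false;
  arma::cube x, t1, t2;  // caches: block input, tanh outputs

  arma::cube fwd(const arma::cube& xin, bool training, bool keep) {
    conv1.fwd(xin, keep);
    arma::cube h = bn1.fwd(conv1.y, training, keep);
    h = arma::tanh(h);
    if (keep) t1 = h;
    conv2.fwd(h, keep);
    h = bn2.fwd(conv2.y, training, keep);
    if (has_shortcut) {
      shortcut.fwd(xin, keep);
      h += shortcut.y;
    } else h += xin;
    h = arma::tanh(h);
    if (keep) t2 = h;
    arma::cube out = h;
    if (has_attn) out = h + attn.fwd(xin, h, keep);
    if (keep) x = xin;
    return out;
  }
  arma::cube bwd(const arma::cube& dy, List& grads) {
    arma::cube dout = dy;  // gradient reaching the post-tanh block output
    arma::cube dx_extra;
    if (has_attn) {
      dx_extra = attn.bwd(dy, dout, grads);
    }
    arma::cube dadd = dout % (1.0 - arma::square(t2));
    arma::cube dh = bn2.bwd(dadd, grads);
    dh = conv2.bwd(dh, grads);
    dh %= (1.0 - arma::square(t1));
    dh = bn1.bwd(dh, grads);
    arma::cube dx = conv1.bwd(dh, grads);
    if (has_shortcut) dx += shortcut.bwd(dadd, grads);
    else dx += dadd;
    if (has_attn) dx += dx_extra;
    return dx;
  }
};

struct Net {
  ConvLayer stem;
  BNLayer stem_bn;
  arma::cube stem_t;
  std::vector<Block> blocks;
  arma::mat headW;
  arma::vec headb;
  arma::mat feats;  // GAP output, cached
  int Ltime = 0;
  arma::mat logp, probs;

  void configure(List& arch) {
    const int Q = arch["taylor_order"];
    const int stem_ch = arch["stem_channels"];
    IntegerVector stages = arch["stage_channels"];
    const int bps = arch["blocks_per_stage"];
    const bool attn = arch["attention_enabled"];
    const int heads = arch["attention_heads"];
    stem.configure("stem.conv", {1, stem_ch, 7, Q, 2, 3, false});
    stem_bn.configure("stem.bn");
    int ich = stem_ch;
    for (int s = 0; s < stages.size(); ++s) {
      const int och = stages[s];
      for (int b = 0; b < bps; ++b) {
        Block bl;
        char buf[32];
        std::snprintf(buf, sizeof(buf), "s%d.b%d", s + 1, b + 1);
        std::string p(buf);
        const int stride = (s > 0 && b == 0) ? 2 : 1;
        const int bin = (b == 0) ? ich : och;
        bl.conv1.configure(p + ".conv1", {bin, och, 3, Q, stride, 1, false});
        bl.bn1.configure(p + ".bn1");
        bl.conv2.configure(p + ".conv2", {och, och, 3, Q, 1, 1, false});
        bl.bn2.configure(p + ".bn2");
        if (stride == 2) {
          bl.has_shortcut = true;
          bl.shortcut.configure(p + ".shortcut", {bin, och, 1, Q, 2, 0, true});
        }
        if (attn && b == bps - 1) {
          bl.has_attn = true;
          bl.attn.configure(p + ".attn", heads);
        }
        blocks.push_back(std::move(bl));
      }
      ich = och;
    }
  }

  void load(List& params, Environment& buffers) {
    stem.load(params);
    stem_bn.load(params, buffers);
    for (auto& bl : blocks) {
      bl.conv1.load(params);
      bl.bn1.load(params, buffers);
      bl.conv2.load(params);
      bl.bn2.load(params, buffers);
      if (bl.has_shortcut) bl.shortcut.load(params);
      if (bl.has_attn) bl.attn.load(params);
    }
    headW = as<arma::mat>(params["head.W"]);
    headb = as<arma::vec>(params["head.b"]);
  }

  void forward(const arma::cube& x, bool training, bool keep) {
    stem.fwd(x, keep);
    arma::cube h = stem_bn.fwd(stem.y, training, keep);
    h = arma::tanh(h);
    if (keep) stem_t = h;
    for (auto& bl : blocks) h = bl.fwd(h, training, keep);
    Ltime = h.n_cols;
    const int B = h.n_slices, C = h.n_rows;
    feats.set_size(C, B);
    for (int b = 0; b < B; ++b) feats.col(b) = arma::mean(h.slice(b), 1);
    arma::mat z = headW * feats;
    z.each_col() += headb;
    logp.set_size(z.n_rows, z.n_cols);
    for (arma::uword j = 0; j < z.n_cols; ++j) {
      const double mx = z.col(j).max();
      const double lse = std::log(arma::accu(arma::exp(z.col(j) - mx))) + mx;
      logp.col(j) = z.col(j) - lse;
    }
    probs = arma::exp(logp);
  }

  List backward(const arma::mat& dlogp) {
    List grads;
    // log-softmax backward: dz = dlogp - probs * colsum(dlogp)
    arma::mat dz = dlogp;
    arma::rowvec cs = arma::sum(dlogp, 0);
    for (arma::uword j = 0; j < dz.n_cols; ++j)
      dz.col(j) -= probs.col(j) * cs(j);
    grads["head.W"] = wrap(arma::mat(dz * feats.t()));
    grads["head.b"] = wrap(arma::vec(arma::sum(dz, 1)));
    arma::mat dfeat = headW.t() * dz;
    const int C = dfeat.n_rows, B = dfeat.n_cols;
    arma::cube dh(C, Ltime, B);
    for (int b = 0; b < B; ++b)
      dh.slice(b) = arma::repmat(dfeat.col(b) / Ltime, 1, Ltime);
    for (int i = (int)blocks.size() - 1; i >= 0; --i) dh = blocks[i].bwd(dh, grads);
    dh %= (1.0 - arma::square(stem_t));
    dh = stem_bn.bwd(dh, grads);
    stem.bwd(dh, grads);
    return grads;
  }
};

}  // namespace

// Persistent runtime handle: workspaces (im2col buffers, attention weight
// matrices, layer caches) are allocated once and reused across mini-batches.
// [[Rcpp::export]]
SEXP cpp_net_create(List arch) {
  Rcpp::XPtr<Net> p(new Net(), true);
  p->configure(arch);
  return p;
}

// [[Rcpp::export]]
arma::mat cpp_net_forward_h(SEXP handle, List params, Environment buffers,
                            const arma::cube& x, bool training) {
  Rcpp::XPtr<Net> net(handle);
  net->load(params, buffers);
  net->forward(x, training, false);
  return net->logp;
}

// One fused training step evaluation: forward in training mode, SoftM_MSE
// loss against 0-based targets, full backward.  Returns the log-probability
// matrix, the loss and the gradient list.
// [[Rcpp::export]]
List cpp_net_fwdbwd_h(SEXP handle, List params, Environment buffers,
                      const arma::cube& x, IntegerVector targets) {
  Rcpp::XPtr<Net> netp(handle);
  Net& net = *netp;
  net.load(params, buffers);
  net.forward(x, true, true);
  const int C = net.logp.n_rows, B = net.logp.n_cols;
  if (targets.size() != B) stop("one target per sample required");
  arma::mat t(C, B, arma::fill::zeros);
  for (int j = 0; j < B; ++j) {
    if (targets[j] < 0 || targets[j] >= C) stop("target class out of range");
    t(targets[j], j) = 1.0;
  }
  const double loss = arma::accu(arma::square(net.probs - t)) / (C * B);
  arma::mat dlogp = (2.0 / (C * B)) * (net.probs - t) % net.probs;
  List grads = net.backward(dlogp);
  return List::create(_["logp"] = net.logp, _["loss"] = loss,
                      _["grads"] = grads);
}
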