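// Core numerical engine for the splice-site CNN.
//
// The network is a 1-D convolutional stack over one-hot encoded DNA:
//   [conv -> ReLU -> dropout -> maxpool(2, stride 2)] x nblocks
//   -> flatten -> dense(ReLU) -> dense(softmax)
// Convolutions are unpadded ("valid"), stride 1.  Training uses mini-batch
// cross-entropy with the Adamax update.  All randomness (shuffling, dropout
// masks, weight init) flows through a single std::mt19937 seeded from R, so
// runs are reproducible on any platform.
//
// Data layout: a batch of B windows of length L with C channels is stored as
// an arma::mat of size (B*L) x C, rows grouped by sample (row b*L + t is
// position t of sample b).  im2col turns that into a (B*Lc) x (k*C) matrix so
// each convolution is a single GEMM.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::stop;

struct Net {
  std::vector<mat>    Wc;   // per conv block: (k * C_in) x F
  std::vector<rowvec> bc;   // per conv block: F
  mat W1; rowvec b1;        // flatten -> dense
  mat W2; rowvec b2;        // dense -> classes
  std::vector<int> kernels;
};

static Net parse_net(const List& w) {
  Net n;
  List cw = w["conv_W"], cb = w["conv_b"];
  IntegerVector ks = w["kernels"];
  for (int i = 0; i < cw.size(); ++i) {
    n.Wc.push_back(Rcpp::as<mat>(cw[i]));
    n.bc.push_back(Rcpp::as<rowvec>(cb[i]));
    n.kernels.push_back(ks[i]);
  }
  n.W1 = Rcpp::as<mat>(w["W1"]);
  n.b1 = Rcpp::as<rowvec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]);
  n.b2 = Rcpp::as<rowvec>(w["b2"]);
  return n;
}

static List net_to_list(const Net& n) {
  List cw(n.Wc.size()), cb(n.bc.size());
  IntegerVector ks(n.kernels.size());
  for (size_t i = 0; i < n.Wc.size(); ++i) {
    cw[i] = n.Wc[i]; cb[i] = n.bc[i]; ks[i] = n.kernels[i];
  }
  return List::create(
    Rcpp::Named("conv_W") = cw, Rcpp::Named("conv_b") = cb,
    Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
    Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
    Rcpp::Named("kernels") = ks);
}

// loops ordered so the destination is written column-contiguously
static mat im2col(const mat& In, int B, int L, int k) {
  const int C = In.n_cols, Lc = L - k + 1;
  mat out(B * Lc, k * C);
  for (int kk = 0; kk < k; ++kk)
    for (int c = 0; c < C; ++c) {
      double* dst = out.colptr(kk * C + c);
      const double* src = In.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + b * L + kk;
        double* d = dst + b * Lc;
        for (int t = 0; t < Lc; ++t) d[t] = s[t];
      }
    }
  return out;
}

static mat col2im(const mat& dCol, int B, int L, int k, int C) {
  const int Lc = L - k + 1;
  mat dIn(B * L, C, fill::zeros);
  for (int kk = 0; kk < k; ++kk)
    for (int c = 0; c < C; ++c) {
      const double* src = dCol.colptr(kk * C + c);
      double* dst = dIn.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + b * Lc;
        double* d = dst + b * L + kk;
        for (int t = 0; t < Lc; ++t) d[t] += s[t];
      }
    }
  return dIn;
}

// maxpool rows within each sample, size 2 stride 2; argm records source row
static mat maxpool(const mat& A, int B, int Lc, umat& argm) {
  const int Lp = Lc / 2, F = A.n_cols;
  mat out(B * Lp, F);
  argm.set_size(B * Lp, F);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lp; ++t) {
      const int r0 = b * Lc + 2 * t, rp = b * Lp + t;
      for (int f = 0; f < F; ++f) {
        if (A(r0, f) >= A(r0 + 1, f)) { out(rp, f) = A(r0, f); argm(rp, f) = r0; }
        else                          { out(rp, f) = A(r0 + 1, f); argm(rp, f) = r0 + 1; }
      }
    }
  return out;
}

static mat softmax_rows(mat Z) {
  Z.each_col() -= max(Z, 1);
  Z = exp(Z);
  Z.each_col() /= sum(Z, 1);
  return Z;
}

// batch cube slices (W x C) -> stacked (B*W) x C
static mat stack_batch(const cube& X, const std::vector<int>& idx) {
  const int B = idx.size(), L = X.n_rows, C = X.n_cols;
  mat In(B * L, C);
  for (int b = 0; b < B; ++b)
    In.rows(b * L, b * L + L - 1) = X.slice(idx[b]);
  return In;
}

struct Cache {
  std::vector<mat>  cols, zs, acts, masks;
  std::vector<umat> argm;
  std::vector<int>  Lcs, Lps;
  mat flat, zh, h, probs;
};

// forward pass; when training, gen supplies dropout masks (p > 0)
static void forward(const Net& net, const mat& In0, int B, int L0,
                    double dropout, std::mt19937* gen, Cache& cc) {
  const int nb = net.Wc.size();
  cc.cols.resize(nb); cc.zs.resize(nb); cc.acts.resize(nb);
  cc.masks.resize(nb); cc.argm.resize(nb); cc.Lcs.resize(nb); cc.Lps.resize(nb);
  mat In = In0;
  int L = L0;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int i = 0; i < nb; ++i) {
    const int k = net.kernels[i];
    cc.cols[i] = im2col(In, B, L, k);
    const int Lc = L - k + 1;
    cc.zs[i] = cc.cols[i] * net.Wc[i];
    cc.zs[i].each_row() += net.bc[i];
    mat act = cc.zs[i];
    act.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (dropout > 0.0 && gen != nullptr) {
      mat msk(act.n_rows, act.n_cols);
      const double keepinv = 1.0 / (1.0 - dropout);
      for (uword j = 0; j < msk.n_elem; ++j)
        msk(j) = (unif(*gen) < dropout) ? 0.0 : keepinv;
      act %= msk;
      cc.masks[i] = msk;
    }
    cc.acts[i] = act;
    cc.Lcs[i] = Lc;
    In = maxpool(act, B, Lc, cc.argm[i]);
    L = Lc / 2;
    cc.Lps[i] = L;
  }
  // flatten: flat(b, f*Lp + t) = In(b*Lp + t, f)
  const int Lp = L, F = In.n_cols;
  cc.flat.set_size(B, Lp * F);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int t = 0; t < Lp; ++t)
        cc.flat(b, f * Lp + t) = In(b * Lp + t, f);
  cc.zh = cc.flat * net.W1;
  cc.zh.each_row() += net.b1;
  cc.h = cc.zh;
  cc.h.elem(find(cc.h < 0)).zeros();
  mat z2 = cc.h * net.W2;
  z2.each_row() += net.b2;
  cc.probs = softmax_rows(z2);
}

struct Grads {
  std::vector<mat> dWc;
  std::vector<rowvec> dbc;
  mat dW1; rowvec db1; mat dW2; rowvec db2;
};

static void backward(const Net& net, const Cache& cc, const mat& In0, int B,
                     int L0, const ivec& yb, double dropout, Grads& g) {
  const int nb = net.Wc.size();
  const int ncls = net.W2.n_cols;
  mat dz2 = cc.probs;                       // softmax + cross-entropy
  for (int b = 0; b < B; ++b) dz2(b, yb[b]) -= 1.0;
  dz2 /= (double)B;
  g.dW2 = cc.h.t() * dz2;
  g.db2 = sum(dz2, 0);
  mat dh = dz2 * net.W2.t();
  dh.elem(find(cc.zh <= 0)).zeros();
  g.dW1 = cc.flat.t() * dh;
  g.db1 = sum(dh, 0);
  mat dflat = dh * net.W1.t();
  (void)ncls;

  // unflatten into pooled-gradient of last block, then walk blocks backwards
  g.dWc.resize(nb); g.dbc.resize(nb);
  mat dpooled;
  {
    const int Lp = cc.Lps[nb - 1], F = net.Wc[nb - 1].n_cols;
    dpooled.set_size(B * Lp, F);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < Lp; ++t)
          dpooled(b * Lp + t, f) = dflat(b, f * Lp + t);
  }
  for (int i = nb - 1; i >= 0; --i) {
    const int Lc = cc.Lcs[i], Lp = cc.Lps[i];
    const int F = net.Wc[i].n_cols;
    mat dact(B * Lc, F, fill::zeros);
    for (int r = 0; r < B * Lp; ++r)
      for (int f = 0; f < F; ++f)
        dact(cc.argm[i](r, f), f) += dpooled(r, f);
    if (dropout > 0.0) dact %= cc.masks[i];
    {                                          // ReLU gate, fused pass
      const double* z = cc.zs[i].memptr();
      double* d = dact.memptr();
      const uword ne = dact.n_elem;
      for (uword j = 0; j < ne; ++j) if (z[j] <= 0.0) d[j] = 0.0;
    }
    g.dWc[i] = cc.cols[i].t() * dact;
    g.dbc[i] = sum(dact, 0);
    if (i > 0) {
      mat dCol = dact * net.Wc[i].t();
      const int Lprev = cc.Lps[i - 1];
      const int Cprev = net.Wc[i - 1].n_cols;
      mat dIn = col2im(dCol, B, Lprev, net.kernels[i], Cprev);
      // dIn is gradient at pooled output of block i-1 -> becomes its dpooled
      dpooled = dIn;
    }
  }
}

// ---- Adamax state over a flat view of all parameters ----
struct Adamax {
  std::vector<mat> m, u;
  double lr, b1, b2, eps;
  long t;
  Adamax(const std::vector<mat*>& ps, double lr_)
      : lr(lr_), b1(0.9), b2(0.999), eps(1e-8), t(0) {
    for (auto p : ps) { m.push_back(zeros(size(*p))); u.push_back(zeros(size(*p))); }
  }
  void step(std::vector<mat*>& ps, const std::vector<mat*>& gs) {
    ++t;
    const double corr = 1.0 - std::pow(b1, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * (*gs[i]);
      u[i] = max(b2 * u[i], abs(*gs[i]));
      *ps[i] -= (lr / corr) * (m[i] / (u[i] + eps));
    }
  }
};

static std::vector<mat*> param_ptrs(Net& n, std::vector<mat>& bias_store) {
  // biases are rowvec; mirror them as mat references via a shared store
  std::vector<mat*> ps;
  for (auto& W : n.Wc) ps.push_back(&W);
  ps.push_back(&n.W1);
  ps.push_back(&n.W2);
  return ps;
}

// evaluate loss/accuracy without dropout, in chunks
static void eval_set(const Net& net, const cube& X, const ivec& y, int L0,
                     double& loss, double& acc) {
  const int N = X.n_slices;
  if (N == 0) { loss = NA_REAL; acc = NA_REAL; return; }
  double lsum = 0; int ncorr = 0;
  const int chunk = 512;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    mat In = stack_batch(X, idx);
    Cache cc;
    forward(net, In, idx.size(), L0, 0.0, nullptr, cc);
    for (size_t b = 0; b < idx.size(); ++b) {
      const double p = std::max(cc.probs(b, y[idx[b]]), 1e-12);
      lsum += -std::log(p);
      uword amax = cc.probs.row(b).index_max();
      if ((int)amax == y[idx[b]]) ++ncorr;
    }
  }
  loss = lsum / N;
  acc = (double)ncorr / N;
}

// [[Rcpp::export]]
List cnn_init_cpp(int input_len, IntegerVector filters, IntegerVector kernels,
                  int channels, int dense_units, int n_classes, int seed) {
  std::mt19937 gen(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  Net net;
  int L = input_len, C = channels;
  for (int i = 0; i < filters.size(); ++i) {
    const int k = kernels[i], F = filters[i];
    const int Lc = L - k + 1;
    if (Lc < 1) stop("input too short for convolution stack");
    const double sd = std::sqrt(2.0 / (k * C));
    mat W(k * C, F);
    for (uword j = 0; j < W.n_elem; ++j) W(j) = sd * norm(gen);
    net.Wc.push_back(W);
    net.bc.push_back(rowvec(F, fill::zeros));
    net.kernels.push_back(k);
    L = Lc / 2;
    if (L < 1) stop("input too short for pooling stack");
    C = F;
  }
  const int flat = L * C;
  {
    const double sd = std::sqrt(2.0 / flat);
    net.W1.set_size(flat, dense_units);
    for (uword j = 0; j < net.W1.n_elem; ++j) net.W1(j) = sd * norm(gen);
    net.b1 = rowvec(dense_units, fill::zeros);
  }
  {
    const double sd = std::sqrt(2.0 / dense_units);
    net.W2.set_size(dense_units, n_classes);
    for (uword j = 0; j < net.W2.n_elem; ++j) net.W2(j) = sd * norm(gen);
    net.b2 = rowvec(n_classes, fill::zeros);
  }
  return net_to_list(net);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, const arma::cube& X, const arma::ivec& y,
                   const arma::cube& Xval, const arma::ivec& yval,
                   int epochs, int batch_size, double lr, double dropout,
                   int seed) {
  Net net = parse_net(weights);
  const int N = X.n_slices, L0 = X.n_rows;
  std::mt19937 gen(seed);

  // parameter and gradient views (biases handled separately below)
  std::vector<mat> dummy;
  std::vector<mat*> ps = param_ptrs(net, dummy);
  Adamax optW(ps, lr);
  // bias optimiser state as rowvec-mats
  std::vector<rowvec*> bs;
  for (auto& b : net.bc) bs.push_back(&b);
  bs.push_back(&net.b1);
  bs.push_back(&net.b2);
  std::vector<rowvec> bm, bu;
  for (auto b : bs) { bm.push_back(rowvec(b->n_elem, fill::zeros));
                      bu.push_back(rowvec(b->n_elem, fill::zeros)); }
  long tstep = 0;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  mat history(epochs, 4);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double lsum = 0; int ncorr = 0;
    for (int s = 0; s < N; s += batch_size) {
      const int e = std::min(N, s + batch_size);
      std::vector<int> idx(order.begin() + s, order.begin() + e);
      const int B = idx.size();
      mat In = stack_batch(X, idx);
      ivec yb(B);
      for (int b = 0; b < B; ++b) yb[b] = y[idx[b]];
      Cache cc;
      forward(net, In, B, L0, dropout, &gen, cc);
      for (int b = 0; b < B; ++b) {
        lsum += -std::log(std::max(cc.probs(b, yb[b]), 1e-12));
        if ((int)cc.probs.row(b).index_max() == yb[b]) ++ncorr;
      }
      Grads g;
      backward(net, cc, In, B, L0, yb, dropout, g);
      // Adamax step: weights
      ++tstep;
      const double corr = 1.0 - std::pow(beta1, (double)tstep);
      std::vector<mat*> gs;
      for (auto& gw : g.dWc) gs.push_back(&gw);
      gs.push_back(&g.dW1);
      gs.push_back(&g.dW2);
      optW.t = tstep - 1;          // step() increments to tstep
      optW.step(ps, gs);
      // biases
      std::vector<rowvec*> gbs;
      for (auto& gb : g.dbc) gbs.push_back(&gb);
      gbs.push_back(&g.db1);
      gbs.push_back(&g.db2);
      for (size_t i = 0; i < bs.size(); ++i) {
        bm[i] = beta1 * bm[i] + (1.0 - beta1) * (*gbs[i]);
        bu[i] = max(beta2 * bu[i], abs(*gbs[i]));
        *bs[i] -= (lr / corr) * (bm[i] / (bu[i] + eps));
      }
    }
    double vloss, vacc;
    eval_set(net, Xval, yval, L0, vloss, vacc);
    history(ep, 0) = lsum / N;
    history(ep, 1) = (double)ncorr / N;
    history(ep, 2) = vloss;
    history(ep, 3) = vacc;
  }
  return List::create(Rcpp::Named("weights") = net_to_list(net),
                      Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List weights, const arma::cube& X) {
  Net net = parse_net(weights);
  const int N = X.n_slices, L0 = X.n_rows;
  const int ncls = net.W2.n_cols;
  mat out(N, ncls);
  const int chunk = 512;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    mat In = stack_batch(X, idx);
    Cache cc;
    forward(net, In, idx.size(), L0, 0.0, nullptr, cc);
    out.rows(s, e - 1) = cc.probs;
  }
  return out;
}

// Grad-CAM at the last convolutional block: gradient of the pre-softmax
// score of `target_class` w.r.t. the post-ReLU activation map; channel
// weights are the spatial mean of that gradient; map = ReLU(weighted sum).
// Returns one row per input window, length = spatial size of the last block.
// [[Rcpp::export]]
arma::mat cnn_gradcam_cpp(List weights, const arma::cube& X, int target_class,
                          int layer = 0, int mode = 0) {
  Net net = parse_net(weights);
  const int N = X.n_slices, L0 = X.n_rows;
  const int nb = net.Wc.size();
  const int jtarget = (layer <= 0 || layer > nb) ? nb - 1 : layer - 1;
  const int chunk = 256;
  mat out;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    const int B = idx.size();
    mat In = stack_batch(X, idx);
    Cache cc;
    forward(net, In, B, L0, 0.0, nullptr, cc);
    // gradient of the class score (single logit, or the logit difference
    // when mode >= 1) w.r.t. the dense stage
    mat dz2(B, net.W2.n_cols, fill::zeros);
    dz2.col(target_class).ones();
    if (mode >= 1) dz2.col(1 - target_class).fill(-1.0);
    mat dh = dz2 * net.W2.t();
    dh.elem(find(cc.zh <= 0)).zeros();
    mat dflat = dh * net.W1.t();
    // unflatten, then walk conv blocks backwards down to the target layer
    mat dpooled;
    {
      const int Lp = cc.Lps[nb - 1], F = net.Wc[nb - 1].n_cols;
      dpooled.set_size(B * Lp, F);
      for (int b = 0; b < B; ++b)
        for (int f = 0; f < F; ++f)
          for (int t = 0; t < Lp; ++t)
            dpooled(b * Lp + t, f) = dflat(b, f * Lp + t);
    }
    mat dact;
    for (int i = nb - 1; i >= jtarget; --i) {
      const int Lc = cc.Lcs[i], Lp = cc.Lps[i];
      const int F = net.Wc[i].n_cols;
      dact.zeros(B * Lc, F);
      for (int r = 0; r < B * Lp; ++r)
        for (int f = 0; f < F; ++f)
          dact(cc.argm[i](r, f), f) += dpooled(r, f);
      if (i > jtarget) {
        mat dz = dact;
        {
          const double* z = cc.zs[i].memptr();
          double* d = dz.memptr();
          for (uword j = 0; j < dz.n_elem; ++j) if (z[j] <= 0.0) d[j] = 0.0;
        }
        mat dCol = dz * net.Wc[i].t();
        dpooled = col2im(dCol, B, cc.Lps[i - 1], net.kernels[i],
                         net.Wc[i - 1].n_cols);
      }
    }
    const int Lc = cc.Lcs[jtarget];
    mat maps(B, Lc);
    for (int b = 0; b < B; ++b) {
      const mat A = cc.acts[jtarget].rows(b * Lc, b * Lc + Lc - 1);
      const mat G = dact.rows(b * Lc, b * Lc + Lc - 1);
      vec m;
      if (mode == 2) {
        m = sum(G % A, 1);                  // gradient x activation variant
      } else {
        rowvec alpha = mean(G, 0);          // spatially averaged gradients
        m = A * alpha.t();
      }
      m.elem(find(m < 0)).zeros();          // clip negative importance
      maps.row(b) = m.t();
    }
    out = out.n_rows == 0 ? maps : join_cols(out, maps);
  }
  return out;
}
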