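// Compact convolutional network for mel-spectrogram classification.
//
// Architecture (fixed): conv3x3(32) -> maxpool2 -> conv3x3(64) -> maxpool2
// -> conv3x3(128) -> maxpool2 -> flatten -> dense(512, ReLU) -> softmax(K),
// valid (no-padding) convolutions, ReLU after every convolution, trained
// with Adam on the categorical cross-entropy.
//
// Data layout: a C-channel feature map on an H x W grid is an arma::mat of
// size (C, H*W) with spatial index p = y + H*x (column-major spatial grid).
// A batch is an arma::mat (C*H*W, N), element (c + C*p, n).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvIdx {
  // gather indices for im2col: block k = dy + 3*dx, k = 0..8
  uvec idx[9];
  int H, W, Ho, Wo;
};

ConvIdx make_conv_idx(int H, int W) {
  ConvIdx ci;
  ci.H = H; ci.W = W; ci.Ho = H - 2; ci.Wo = W - 2;
  for (int k = 0; k < 9; ++k) {
    int dy = k % 3, dx = k / 3;
    uvec v(static_cast<uword>(ci.Ho) * ci.Wo);
    uword q = 0;
    for (int x = 0; x < ci.Wo; ++x)
      for (int y = 0; y < ci.Ho; ++y)
        v[q++] = static_cast<uword>(y + dy) + static_cast<uword>(H) * (x + dx);
    ci.idx[k] = v;
  }
  return ci;
}

struct PoolIdx {
  uvec idx[4];  // the four corners of each 2x2 patch
  int Ho, Wo;
};

PoolIdx make_pool_idx(int H, int W) {
  PoolIdx pi;
  pi.Ho = H / 2; pi.Wo = W / 2;
  for (int k = 0; k < 4; ++k) {
    int dy = k % 2, dx = k / 2;
    uvec v(static_cast<uword>(pi.Ho) * pi.Wo);
    uword q = 0;
    for (int x = 0; x < pi.Wo; ++x)
      for (int y = 0; y < pi.Ho; ++y)
        v[q++] = static_cast<uword>(2 * y + dy) + static_cast<uword>(H) * (2 * x + dx);
    pi.idx[k] = v;
  }
  return pi;
}

mat im2col(const mat& F, const ConvIdx& ci) {
  const uword C = F.n_rows;
  mat out(9 * C, ci.idx[0].n_elem);
  for (int k = 0; k < 9; ++k)
    out.rows(k * C, k * C + C - 1) = F.cols(ci.idx[k]);
  return out;
}

void col2im_add(mat& dF, const mat& dcol, const ConvIdx& ci) {
  const uword C = dF.n_rows;
  for (int k = 0; k < 9; ++k)
    dF.cols(ci.idx[k]) += dcol.rows(k * C, k * C + C - 1);
}

// max pooling; `arg` records which of the 4 corners won (for backprop)
mat maxpool(const mat& F, const PoolIdx& pi, umat& arg) {
  mat out = F.cols(pi.idx[0]);
  arg.zeros(out.n_rows, out.n_cols);
  for (int k = 1; k < 4; ++k) {
    mat cand = F.cols(pi.idx[k]);
    uvec better = find(cand > out);
    out.elem(better) = cand.elem(better);
    arg.elem(better).fill(static_cast<uword>(k));
  }
  return out;
}

void maxpool_back(mat& dF, const mat& dOut, const umat& arg, const PoolIdx& pi) {
  for (int k = 0; k < 4; ++k) {
    mat contrib = dOut % conv_to<mat>::from(arg == static_cast<uword>(k));
    dF.cols(pi.idx[k]) += contrib;
  }
}

mat glorot(int rows, int cols, double fan_in, double fan_out, std::mt19937& rng) {
  double limit = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> unif(-limit, limit);
  mat W(rows, cols);
  // column-major fill, fixed order => reproducible for a given seed
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i)
      W(i, j) = unif(rng);
  return W;
}

struct Dims {
  int h0, w0, c0, K;
  int h1, w1, hp1, wp1;
  int h2, w2, hp2, wp2;
  int h3, w3, hp3, wp3;
  int flat;
};

Dims make_dims(int h, int w, int c, int K) {
  Dims d;
  d.h0 = h; d.w0 = w; d.c0 = c; d.K = K;
  d.h1 = h - 2; d.w1 = w - 2; d.hp1 = d.h1 / 2; d.wp1 = d.w1 / 2;
  d.h2 = d.hp1 - 2; d.w2 = d.wp1 - 2; d.hp2 = d.h2 / 2; d.wp2 = d.w2 / 2;
  d.h3 = d.hp2 - 2; d.w3 = d.wp2 - 2; d.hp3 = d.h3 / 2; d.wp3 = d.w3 / 2;
  if (d.hp3 < 1 || d.wp3 < 1)
    Rcpp::stop("input %dx%d too small for three conv/pool blocks", h, w);
  d.flat = 128 * d.hp3 * d.wp3;
  return d;
}

struct Caches {
  ConvIdx c1, c2, c3;
  PoolIdx p1, p2, p3;
};

Caches make_caches(const Dims& d) {
  Caches cc;
  cc.c1 = make_conv_idx(d.h0, d.w0); cc.p1 = make_pool_idx(d.h1, d.w1);
  cc.c2 = make_conv_idx(d.hp1, d.wp1); cc.p2 = make_pool_idx(d.h2, d.w2);
  cc.c3 = make_conv_idx(d.hp2, d.wp2); cc.p3 = make_pool_idx(d.h3, d.w3);
  return cc;
}

struct Weights {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
};

Weights weights_from_list(const Rcpp::List& wl) {
  Weights w;
  w.W1 = Rcpp::as<mat>(wl["W1"]); w.b1 = Rcpp::as<vec>(wl["b1"]);
  w.W2 = Rcpp::as<mat>(wl["W2"]); w.b2 = Rcpp::as<vec>(wl["b2"]);
  w.W3 = Rcpp::as<mat>(wl["W3"]); w.b3 = Rcpp::as<vec>(wl["b3"]);
  w.W4 = Rcpp::as<mat>(wl["W4"]); w.b4 = Rcpp::as<vec>(wl["b4"]);
  w.W5 = Rcpp::as<mat>(wl["W5"]); w.b5 = Rcpp::as<vec>(wl["b5"]);
  return w;
}

Rcpp::List weights_to_list(const Weights& w) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = w.W1, Rcpp::Named("b1") = w.b1,
    Rcpp::Named("W2") = w.W2, Rcpp::Named("b2") = w.b2,
    Rcpp::Named("W3") = w.W3, Rcpp::Named("b3") = w.b3,
    Rcpp::Named("W4") = w.W4, Rcpp::Named("b4") = w.b4,
    Rcpp::Named("W5") = w.W5, Rcpp::Named("b5") = w.b5);
}

// per-image forward pass; intermediates kept only when training
struct Fwd {
  mat col1, A1; umat arg1; mat P1;
  mat col2, A2; umat arg2; mat P2;
  mat col3, A3; umat arg3; mat P3;
  vec f, a4, probs;
};

void forward_one(const Weights& w, const Dims& d, const Caches& cc,
                 const vec& x, Fwd& s, bool keep) {
  mat F0(const_cast<double*>(x.memptr()), d.c0, static_cast<uword>(d.h0) * d.w0,
         false, true);
  mat col1 = im2col(F0, cc.c1);
  mat A1 = w.W1 * col1;
  A1.each_col() += w.b1;
  A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  umat arg1;
  mat P1 = maxpool(A1, cc.p1, arg1);

  mat col2 = im2col(P1, cc.c2);
  mat A2 = w.W2 * col2;
  A2.each_col() += w.b2;
  A2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  umat arg2;
  mat P2 = maxpool(A2, cc.p2, arg2);

  mat col3 = im2col(P2, cc.c3);
  mat A3 = w.W3 * col3;
  A3.each_col() += w.b3;
  A3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  umat arg3;
  mat P3 = maxpool(A3, cc.p3, arg3);

  vec f = vectorise(P3);
  vec a4 = w.W4 * f + w.b4;
  a4.transform([](double v) { return v > 0.0 ? v : 0.0; });
  vec z5 = w.W5 * a4 + w.b5;
  z5 -= z5.max();
  vec e = exp(z5);
  s.probs = e / accu(e);

  if (keep) {
    s.col1 = std::move(col1); s.A1 = std::move(A1); s.arg1 = std::move(arg1); s.P1 = std::move(P1);
    s.col2 = std::move(col2); s.A2 = std::move(A2); s.arg2 = std::move(arg2); s.P2 = std::move(P2);
    s.col3 = std::move(col3); s.A3 = std::move(A3); s.arg3 = std::move(arg3); s.P3 = std::move(P3);
    s.f = std::move(f); s.a4 = std::move(a4);
  }
}

struct Grads {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
  void zeros_like(const Weights& w) {
    W1.zeros(size(w.W1)); b1.zeros(size(w.b1));
    W2.zeros(size(w.W2)); b2.zeros(size(w.b2));
    W3.zeros(size(w.W3)); b3.zeros(size(w.b3));
    W4.zeros(size(w.W4)); b4.zeros(size(w.b4));
    W5.zeros(size(w.W5)); b5.zeros(size(w.b5));
  }
};

void backward_one(const Weights& w, const Dims& d, const Caches& cc,
                  const Fwd& s, int label, Grads& g) {
  vec dz5 = s.probs;
  dz5[label] -= 1.0;
  g.W5 += dz5 * s.a4.t();
  g.b5 += dz5;

  vec da4 = w.W5.t() * dz5;
  da4 %= conv_to<vec>::from(s.a4 > 0);
  g.W4 += da4 * s.f.t();
  g.b4 += da4;

  vec df = w.W4.t() * da4;
  mat dP3(df.memptr(), 128, static_cast<uword>(d.hp3) * d.wp3);

  mat dA3(128, static_cast<uword>(d.h3) * d.w3, fill::zeros);
  maxpool_back(dA3, dP3, s.arg3, cc.p3);
  dA3 %= conv_to<mat>::from(s.A3 > 0);
  g.W3 += dA3 * s.col3.t();
  g.b3 += sum(dA3, 1);
  mat dcol3 = w.W3.t() * dA3;
  mat dP2(64, static_cast<uword>(d.hp2) * d.wp2, fill::zeros);
  col2im_add(dP2, dcol3, cc.c3);

  mat dA2(64, static_cast<uword>(d.h2) * d.w2, fill::zeros);
  maxpool_back(dA2, dP2, s.arg2, cc.p2);
  dA2 %= conv_to<mat>::from(s.A2 > 0);
  g.W2 += dA2 * s.col2.t();
  g.b2 += sum(dA2, 1);
  mat dcol2 = w.W2.t() * dA2;
  mat dP1(32, static_cast<uword>(d.hp1) * d.wp1, fill::zeros);
  col2im_add(dP1, dcol2, cc.c2);

  mat dA1(32, static_cast<uword>(d.h1) * d.w1, fill::zeros);
  maxpool_back(dA1, dP1, s.arg1, cc.p1);
  dA1 %= conv_to<mat>::from(s.A1 > 0);
  g.W1 += dA1 * s.col1.t();
  g.b1 += sum(dA1, 1);
  // no further propagation: input layer
}

struct AdamState {
  mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4, mW5, vW5;
  vec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4, mb5, vb5;
  long t = 0;
};

void adam_update(mat& W, const mat& dW, mat& m, mat& v,
                 double lr, double b1, double b2, double eps, long t) {
  m = b1 * m + (1.0 - b1) * dW;
  v = b2 * v + (1.0 - b2) * square(dW);
  mat mhat = m / (1.0 - std::pow(b1, static_cast<double>(t)));
  mat vhat = v / (1.0 - std::pow(b2, static_cast<double>(t)));
  W -= lr * mhat / (sqrt(vhat) + eps);
}

void adam_update(vec& W, const vec& dW, vec& m, vec& v,
                 double lr, double b1, double b2, double eps, long t) {
  m = b1 * m + (1.0 - b1) * dW;
  v = b2 * v + (1.0 - b2) * square(dW);
  vec mhat = m / (1.0 - std::pow(b1, static_cast<double>(t)));
  vec vhat = v / (1.0 - std::pow(b2, static_cast<double>(t)));
  W -= lr * mhat / (sqrt(vhat) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(int input_h, int input_w, int in_ch, int n_classes, int seed) {
  Dims d = make_dims(input_h, input_w, in_ch, n_classes);
  std::mt19937 rng(static_cast<unsigned>(seed));
  Weights w;
  w.W1 = glorot(32, 9 * in_ch, 9.0 * in_ch, 9.0 * 32, rng);   w.b1.zeros(32);
  w.W2 = glorot(64, 9 * 32, 9.0 * 32, 9.0 * 64, rng);         w.b2.zeros(64);
  w.W3 = glorot(128, 9 * 64, 9.0 * 64, 9.0 * 128, rng);       w.b3.zeros(128);
  w.W4 = glorot(512, d.flat, d.flat, 512.0, rng);             w.b4.zeros(512);
  w.W5 = glorot(n_classes, 512, 512.0, n_classes, rng);       w.b5.zeros(n_classes);
  return weights_to_list(w);
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List weights, const arma::mat& X,
                          int input_h, int input_w, int in_ch, int n_classes) {
  Dims d = make_dims(input_h, input_w, in_ch, n_classes);
  Caches cc = make_caches(d);
  Weights w = weights_from_list(weights);
  mat probs(n_classes, X.n_cols);
  Fwd s;
  for (uword i = 0; i < X.n_cols; ++i) {
    vec x = X.col(i);
    forward_one(w, d, cc, x, s, false);
    probs.col(i) = s.probs;
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, const arma::mat& X,
                         const arma::ivec& y, int input_h, int input_w,
                         int in_ch, int n_classes, int epochs, int batch_size,
                         double lr, int seed, double beta1, double beta2,
                         double eps, bool verbose) {
  Dims d = make_dims(input_h, input_w, in_ch, n_classes);
  Caches cc = make_caches(d);
  Weights w = weights_from_list(weights);
  const uword N = X.n_cols;
  if (y.n_elem != N) Rcpp::stop("label/feature count mismatch");

  AdamState a;
  a.mW1.zeros(size(w.W1)); a.vW1.zeros(size(w.W1)); a.mb1.zeros(size(w.b1)); a.vb1.zeros(size(w.b1));
  a.mW2.zeros(size(w.W2)); a.vW2.zeros(size(w.W2)); a.mb2.zeros(size(w.b2)); a.vb2.zeros(size(w.b2));
  a.mW3.zeros(size(w.W3)); a.vW3.zeros(size(w.W3)); a.mb3.zeros(size(w.b3)); a.vb3.zeros(size(w.b3));
  a.mW4.zeros(size(w.W4)); a.vW4.zeros(size(w.W4)); a.mb4.zeros(size(w.b4)); a.vb4.zeros(size(w.b4));
  a.mW5.zeros(size(w.W5)); a.vW5.zeros(size(w.W5)); a.mb5.zeros(size(w.b5)); a.vb5.zeros(size(w.b5));

  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  vec ep_loss(epochs), ep_acc(epochs);
  Fwd s;
  Grads g;
  for (int ep = 0; ep < epochs; ++ep) {
    std::mt19937 shuf(static_cast<unsigned>(seed) + 1000003u * (ep + 1));
    std::shuffle(order.begin(), order.end(), shuf);
    double loss_sum = 0.0;
    uword correct = 0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min(N, start + static_cast<uword>(batch_size));
      uword nb = stop - start;
      g.zeros_like(w);
      for (uword i = start; i < stop; ++i) {
        uword j = order[i];
        vec x = X.col(j);
        forward_one(w, d, cc, x, s, true);
        int lab = y[j];
        loss_sum += -std::log(std::max(s.probs[lab], 1e-12));
        if (s.probs.index_max() == static_cast<uword>(lab)) ++correct;
        backward_one(w, d, cc, s, lab, g);
      }
      double inv = 1.0 / static_cast<double>(nb);
      g.W1 *= inv; g.b1 *= inv; g.W2 *= inv; g.b2 *= inv; g.W3 *= inv;
      g.b3 *= inv; g.W4 *= inv; g.b4 *= inv; g.W5 *= inv; g.b5 *= inv;
      ++a.t;
      adam_update(w.W1, g.W1, a.mW1, a.vW1, lr, beta1, beta2, eps, a.t);
      adam_update(w.b1, g.b1, a.mb1, a.vb1, lr, beta1, beta2, eps, a.t);
      adam_update(w.W2, g.W2, a.mW2, a.vW2, lr, beta1, beta2, eps, a.t);
      adam_update(w.b2, g.b2, a.mb2, a.vb2, lr, beta1, beta2, eps, a.t);
      adam_update(w.W3, g.W3, a.mW3, a.vW3, lr, beta1, beta2, eps, a.t);
      adam_update(w.b3, g.b3, a.mb3, a.vb3, lr, beta1, beta2, eps, a.t);
      adam_update(w.W4, g.W4, a.mW4, a.vW4, lr, beta1, beta2, eps, a.t);
      adam_update(w.b4, g.b4, a.mb4, a.vb4, lr, beta1, beta2, eps, a.t);
      adam_update(w.W5, g.W5, a.mW5, a.vW5, lr, beta1, beta2, eps, a.t);
      adam_update(w.b5, g.b5, a.mb5, a.vb5, lr, beta1, beta2, eps, a.t);
    }
    ep_loss[ep] = loss_sum / static_cast<double>(N);
    ep_acc[ep] = static_cast<double>(correct) / static_cast<double>(N);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << "  loss " << ep_loss[ep] << "  acc " << ep_acc[ep] << "\n";
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(w),
    Rcpp::Named("loss") = ep_loss,
    Rcpp::Named("accuracy") = ep_acc);
}
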