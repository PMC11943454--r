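// Compact encoder-decoder semantic segmentation network.
//
// Architecture (fixed topology, configurable width C):
//   conv 3x3 stride 2, 3 -> C,  ReLU     (encoder block 1)
//   conv 3x3 stride 2, C -> 2C, ReLU     (encoder block 2)
//   nearest x2 upsample, conv 3x3, 2C -> C, ReLU
//   nearest x2 upsample, conv 3x3, C  -> C, ReLU
//   1x1 projection C -> 4 class scores per pixel
// Training: SGD with momentum, pixel-wise softmax cross-entropy with
// label 0 (unannotated background) excluded from the loss.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static inline int out_dim(int n, int stride) { return (n - 1) / stride + 1; }

// 3x3 convolution lowering, pad 1. Pixel order is column-major (R order).
static mat im2col(const cube &in, int stride) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  mat col(C * 9, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int r = c * 9 + kj * 3 + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - 1;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - 1;
            if (ii < 0 || ii >= H) continue;
            col(r, oj * Ho + oi) = in(ii, ij, c);
          }
        }
      }
  return col;
}

static cube col2im(const mat &dcol, int H, int W, int C, int stride) {
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  cube din(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int r = c * 9 + kj * 3 + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - 1;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - 1;
            if (ii < 0 || ii >= H) continue;
            din(ii, ij, c) += dcol(r, oj * Ho + oi);
          }
        }
      }
  return din;
}

static cube mat_to_cube(const mat &m, int H, int W) {
  // rows of m are channels over column-major pixels
  cube out(H, W, m.n_rows);
  for (uword c = 0; c < m.n_rows; ++c)
    out.slice(c) = reshape(m.row(c).t(), H, W);
  return out;
}

static mat cube_to_mat(const cube &x) {
  mat out(x.n_slices, x.n_rows * x.n_cols);
  for (uword c = 0; c < x.n_slices; ++c)
    out.row(c) = vectorise(x.slice(c)).t();
  return out;
}

static cube upsample2(const cube &x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube downsample2_sum(const cube &d) {
  cube out(d.n_rows / 2, d.n_cols / 2, d.n_slices);
  for (uword c = 0; c < d.n_slices; ++c)
    for (uword j = 0; j < out.n_cols; ++j)
      for (uword i = 0; i < out.n_rows; ++i)
        out(i, j, c) = d(2 * i, 2 * j, c) + d(2 * i + 1, 2 * j, c) +
                       d(2 * i, 2 * j + 1, c) + d(2 * i + 1, 2 * j + 1, c);
  return out;
}

struct Net {
  std::vector<mat> W;  // 5 weight matrices
  std::vector<vec> b;  // 5 biases
};

static Net net_from_list(const List &weights) {
  Net net;
  for (int l = 0; l < 5; ++l) {
    net.W.push_back(Rcpp::as<mat>(weights[l]));
    net.b.push_back(Rcpp::as<vec>(weights[5 + l]));
  }
  return net;
}

static List net_to_list(const Net &net) {
  List out(10);
  Rcpp::CharacterVector nm(10);
  for (int l = 0; l < 5; ++l) {
    out[l] = net.W[l];
    out[5 + l] = net.b[l];
    nm[l] = "W" + std::to_string(l + 1);
    nm[5 + l] = "b" + std::to_string(l + 1);
  }
  out.attr("names") = nm;
  return out;
}

struct Cache {
  mat col1, col2, col3, col4;  // im2col inputs of the conv layers
  cube c1, c2, c3, c4;         // pre-activations
  mat a4m;                     // head input (C x N)
  mat scores;                  // 4 x N
};

static void forward(const Net &net, const cube &x, Cache &K) {
  const int H = x.n_rows, W = x.n_cols;
  K.col1 = im2col(x, 2);
  mat o1 = net.W[0] * K.col1;
  o1.each_col() += net.b[0];
  K.c1 = mat_to_cube(o1, H / 2, W / 2);
  cube a1 = clamp(K.c1, 0.0, datum::inf);

  K.col2 = im2col(a1, 2);
  mat o2 = net.W[1] * K.col2;
  o2.each_col() += net.b[1];
  K.c2 = mat_to_cube(o2, H / 4, W / 4);
  cube a2 = clamp(K.c2, 0.0, datum::inf);

  cube u2 = upsample2(a2);
  K.col3 = im2col(u2, 1);
  mat o3 = net.W[2] * K.col3;
  o3.each_col() += net.b[2];
  K.c3 = mat_to_cube(o3, H / 2, W / 2);
  cube a3 = clamp(K.c3, 0.0, datum::inf);

  cube u3 = upsample2(a3);
  K.col4 = im2col(u3, 1);
  mat o4 = net.W[3] * K.col4;
  o4.each_col() += net.b[3];
  K.c4 = mat_to_cube(o4, H, W);
  cube a4 = clamp(K.c4, 0.0, datum::inf);

  K.a4m = cube_to_mat(a4);
  K.scores = net.W[4] * K.a4m;
  K.scores.each_col() += net.b[4];
}

// Softmax cross-entropy over valid (label > 0) pixels. Fills dscores,
// returns summed loss; increments n_valid / n_correct.
static double ce_grad(const mat &scores, const ivec &y, mat &dscores,
                      long &n_valid, long &n_correct) {
  const uword N = scores.n_cols;
  dscores.zeros(scores.n_rows, N);
  double loss = 0.0;
  for (uword n = 0; n < N; ++n) {
    const int lab = y(n);
    if (lab <= 0) continue;
    vec s = scores.col(n);
    s -= s.max();
    vec e = exp(s);
    e /= accu(e);
    loss += -std::log(std::max(e(lab - 1), 1e-12));
    if ((int)scores.col(n).index_max() == lab - 1) ++n_correct;
    dscores.col(n) = e;
    dscores(lab - 1, n) -= 1.0;
    ++n_valid;
  }
  return loss;
}

// Backward pass for one sample; accumulates parameter gradients.
static void backward(const Net &net, const cube &x, const Cache &K,
                     const mat &dscores, Net &grad) {
  const int H = x.n_rows, W = x.n_cols;
  grad.W[4] += dscores * K.a4m.t();
  grad.b[4] += sum(dscores, 1);
  mat da4 = net.W[4].t() * dscores;  // C x N
  cube d4 = mat_to_cube(da4, H, W);
  d4 %= conv_to<cube>::from(K.c4 > 0);
  mat d4m = cube_to_mat(d4);
  grad.W[3] += d4m * K.col4.t();
  grad.b[3] += sum(d4m, 1);
  cube du3 = col2im(net.W[3].t() * d4m, H, W, net.W[3].n_cols / 9, 1);
  cube d3 = downsample2_sum(du3);
  d3 %= conv_to<cube>::from(K.c3 > 0);
  mat d3m = cube_to_mat(d3);
  grad.W[2] += d3m * K.col3.t();
  grad.b[2] += sum(d3m, 1);
  cube du2 = col2im(net.W[2].t() * d3m, H / 2, W / 2, net.W[2].n_cols / 9, 1);
  cube d2 = downsample2_sum(du2);
  d2 %= conv_to<cube>::from(K.c2 > 0);
  mat d2m = cube_to_mat(d2);
  grad.W[1] += d2m * K.col2.t();
  grad.b[1] += sum(d2m, 1);
  cube d1 = col2im(net.W[1].t() * d2m, H / 2, W / 2, net.W[1].n_cols / 9, 2);
  d1 %= conv_to<cube>::from(K.c1 > 0);
  mat d1m = cube_to_mat(d1);
  grad.W[0] += d1m * K.col1.t();
  grad.b[0] += sum(d1m, 1);
}

// [[Rcpp::export(name = ".segnet_train_cpp")]]
List segnet_train_cpp(List X, List Y, List weights, Rcpp::IntegerVector epochs,
                      Rcpp::NumericVector lrs, int batch, double momentum,
                      Rcpp::IntegerMatrix perms) {
  const int n = X.size();
  Net net = net_from_list(weights);
  Net vel, grad;
  for (int l = 0; l < 5; ++l) {
    vel.W.push_back(mat(size(net.W[l]), fill::zeros));
    vel.b.push_back(vec(size(net.b[l]), fill::zeros));
    grad.W.push_back(mat(size(net.W[l]), fill::zeros));
    grad.b.push_back(vec(size(net.b[l]), fill::zeros));
  }
  std::vector<cube> xs(n);
  std::vector<ivec> ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = Rcpp::as<cube>(X[i]);
    Rcpp::IntegerMatrix ym = Y[i];
    ys[i] = ivec(ym.size());
    for (int k = 0; k < ym.size(); ++k) ys[i](k) = ym[k];
  }
  std::vector<double> hist_loss, hist_acc;
  std::vector<int> hist_stage;
  int ep_global = 0;
  for (int st = 0; st < epochs.size(); ++st) {
    const double lr = lrs[st];
    for (int ep = 0; ep < epochs[st]; ++ep, ++ep_global) {
      for (int start = 0; start < n; start += batch) {
        const int stop = std::min(start + batch, n);
        for (int l = 0; l < 5; ++l) {
          grad.W[l].zeros();
          grad.b[l].zeros();
        }
        double loss = 0.0;
        long n_valid = 0, n_correct = 0;
        for (int k = start; k < stop; ++k) {
          const int i = perms(ep_global, k) - 1;
          Cache K;
          forward(net, xs[i], K);
          mat dscores;
          loss += ce_grad(K.scores, ys[i], dscores, n_valid, n_correct);
          if (n_valid > 0) backward(net, xs[i], K, dscores, grad);
        }
        if (n_valid == 0) continue;
        for (int l = 0; l < 5; ++l) {
          vel.W[l] = momentum * vel.W[l] - lr * grad.W[l] / (double)n_valid;
          vel.b[l] = momentum * vel.b[l] - lr * grad.b[l] / (double)n_valid;
          net.W[l] += vel.W[l];
          net.b[l] += vel.b[l];
        }
        hist_loss.push_back(loss / n_valid);
        hist_acc.push_back((double)n_correct / n_valid);
        hist_stage.push_back(st + 1);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(
      Rcpp::Named("weights") = net_to_list(net),
      Rcpp::Named("loss") = hist_loss, Rcpp::Named("accuracy") = hist_acc,
      Rcpp::Named("stage") = hist_stage);
}

// [[Rcpp::export(name = ".segnet_predict_cpp")]]
Rcpp::IntegerMatrix segnet_predict_cpp(arma::cube x, List weights) {
  Net net = net_from_list(weights);
  Cache K;
  forward(net, x, K);
  const int H = x.n_rows, W = x.n_cols;
  Rcpp::IntegerMatrix out(H, W);
  for (int n = 0; n < H * W; ++n) out[n] = K.scores.col(n).index_max() + 1;
  return out;
}

// [[Rcpp::export(name = ".segnet_scores_cpp")]]
arma::mat segnet_scores_cpp(arma::cube x, List weights) {
  Net net = net_from_list(weights);
  Cache K;
  forward(net, x, K);
  return K.scores;  // 4 x (H*W), column-major pixel order
}
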