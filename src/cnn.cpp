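// Compact CNN for 224x224x3 scalogram images, trained from scratch on the CPU.
// Layer stack (fixed): conv 3x3x64 same/ReLU -> maxpool 2x2/2 -> conv 5x5x128
// same/ReLU -> maxpool 2x2/2 -> flatten 401408 -> dense 256 ReLU -> dense 128
// ReLU -> dense 1 sigmoid.  Convolutions run as im2col + sgemm in single
// precision; the optimiser is Adam on the mean binary cross-entropy.
// Feature maps are stored as (H*W, C) matrices, column-major, matching the
// layout of an R array of dim c(H, W, C).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

namespace {

struct Param {
  fmat w, g, m, v;   // g/m/v are allocated lazily on first use
  void init(uword r, uword c) { w.set_size(r, c); }
  void zero_grad() {
    if (g.n_elem != w.n_elem) g.zeros(w.n_rows, w.n_cols); else g.zeros();
  }
};

// im2col for stride-1 "same" convolution. X: (H*W, C_in) -> cols: (H*W, k*k*C_in)
// with column index c*k*k + kj*k + ki holding input pixel (h+ki-p, w+kj-p, c).
void im2col(const fmat& X, int H, int W, int k, fmat& cols) {
  const int p = (k - 1) / 2;
  const int C = (int)X.n_cols;
  cols.zeros((uword)H * W, (uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        float* dst = cols.colptr((uword)c * k * k + kj * k + ki);
        const int h0 = std::max(0, p - ki);
        const int h1 = std::min(H, H + p - ki);   // exclusive
        if (h1 <= h0) continue;
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + kj - p;
          if (wi < 0 || wi >= W) continue;
          std::memcpy(dst + (size_t)wo * H + h0,
                      src + (size_t)wi * H + h0 + (ki - p),
                      sizeof(float) * (h1 - h0));
        }
      }
    }
  }
}

// Scatter-add transpose of im2col: dcols (H*W, k*k*C) -> dX (H*W, C).
void col2im(const fmat& dcols, int H, int W, int k, fmat& dX) {
  const int p = (k - 1) / 2;
  const int C = (int)dX.n_cols;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const float* src = dcols.colptr((uword)c * k * k + kj * k + ki);
        const int h0 = std::max(0, p - ki);
        const int h1 = std::min(H, H + p - ki);
        if (h1 <= h0) continue;
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + kj - p;
          if (wi < 0 || wi >= W) continue;
          float* d = dst + (size_t)wi * H + h0 + (ki - p);
          const float* s = src + (size_t)wo * H + h0;
          for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// 2x2 max pooling, stride 2 (H, W even). Records the argmax source pixel.
void maxpool(const fmat& X, int H, int W, fmat& out, Mat<u32>& idx) {
  const int C = (int)X.n_cols, H2 = H / 2, W2 = W / 2;
  out.set_size((uword)H2 * W2, C);
  idx.set_size((uword)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* o = out.colptr(c);
    u32* ix = idx.colptr(c);
    for (int wo = 0; wo < W2; ++wo) {
      for (int ho = 0; ho < H2; ++ho) {
        const int base = (2 * wo) * H + 2 * ho;
        u32 best = base; float bv = src[base];
        const int cand[3] = {base + 1, base + H, base + H + 1};
        for (int q = 0; q < 3; ++q)
          if (src[cand[q]] > bv) { bv = src[cand[q]]; best = cand[q]; }
        o[(size_t)wo * H2 + ho] = bv;
        ix[(size_t)wo * H2 + ho] = best;
      }
    }
  }
}

void unpool(const fmat& dout, const Mat<u32>& idx, fmat& dX) {
  dX.zeros();
  for (uword c = 0; c < dout.n_cols; ++c) {
    float* d = dX.colptr(c);
    const float* s = dout.colptr(c);
    const u32* ix = idx.colptr(c);
    for (uword i = 0; i < dout.n_rows; ++i) d[ix[i]] += s[i];
  }
}

inline float relu(float x) { return x > 0.f ? x : 0.f; }

class CNN {
public:
  static constexpr int H = 224, W = 224, C = 3, NPIX = H * W * C;
  static constexpr int H1 = 112, W1 = 112, C1 = 64;   // after pool1
  static constexpr int H2 = 56, W2 = 56, C2 = 128;    // after pool2
  static constexpr int NFLAT = H2 * W2 * C2;          // 401408

  Param Wc1, bc1, Wc2, bc2, Wd1, bd1, Wd2, bd2, Wd3, bd3;
  std::mt19937_64 rng;
  long adam_t = 0;

  // reusable buffers (per-image activations)
  fmat a0, cols1, z1, r1, p1, cols2, z2, r2, p2;
  Mat<u32> idx1, idx2;
  fvec xf, zd1, a1, zd2, a2;
  fmat dcols2, dX2, dr2, dz2c, dr1, dz1c, dp1;

  explicit CNN(unsigned long seed) : rng(seed) {
    Wc1.init(27, 64);      bc1.init(1, 64);
    Wc2.init(1600, 128);   bc2.init(1, 128);
    Wd1.init(256, NFLAT);  bd1.init(256, 1);
    Wd2.init(128, 256);    bd2.init(128, 1);
    Wd3.init(1, 128);      bd3.init(1, 1);
    he_init(Wc1.w, 27); he_init(Wc2.w, 1600);
    he_init(Wd1.w, NFLAT); he_init(Wd2.w, 256);
    xavier_init(Wd3.w, 128);
    bc1.w.zeros(); bc2.w.zeros(); bd1.w.zeros(); bd2.w.zeros(); bd3.w.zeros();
  }

  void he_init(fmat& w, double fan_in) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan_in));
    for (uword i = 0; i < w.n_elem; ++i) w[i] = (float)nd(rng);
  }
  void xavier_init(fmat& w, double fan_in) {
    std::normal_distribution<double> nd(0.0, std::sqrt(1.0 / fan_in));
    for (uword i = 0; i < w.n_elem; ++i) w[i] = (float)nd(rng);
  }

  void load_image(const Rcpp::RawVector& data, R_xlen_t img) {
    a0.set_size((uword)H * W, C);
    const Rbyte* src = &data[img * (R_xlen_t)NPIX];
    float* dst = a0.memptr();
    for (int i = 0; i < NPIX; ++i) dst[i] = src[i] / 255.0f;  // pixels to [0,1]
  }

  // forward for the currently loaded image; returns sigmoid output
  double forward() {
    im2col(a0, H, W, 3, cols1);
    z1 = cols1 * Wc1.w;
    z1.each_row() += bc1.w;
    r1 = z1; r1.transform(relu);
    maxpool(r1, H, W, p1, idx1);
    im2col(p1, H1, W1, 5, cols2);
    z2 = cols2 * Wc2.w;
    z2.each_row() += bc2.w;
    r2 = z2; r2.transform(relu);
    maxpool(r2, H1, W1, p2, idx2);
    xf = vectorise(p2);
    zd1 = Wd1.w * xf + bd1.w;
    a1 = zd1; a1.transform(relu);
    zd2 = Wd2.w * a1 + bd2.w;
    a2 = zd2; a2.transform(relu);
    const double z = as_scalar(Wd3.w * a2) + bd3.w(0, 0);
    return 1.0 / (1.0 + std::exp(-z));
  }

  // backward for the current image; conv gradients accumulate in-place, the
  // dense-layer weight gradients are batched outside via stored activations
  void backward(double p_hat, double y,
                fmat& Xf, fmat& A1, fmat& A2, fmat& Dz1, fmat& Dz2, fmat& Dz3,
                uword j) {
    const float dz3 = (float)(p_hat - y);
    Xf.col(j) = xf; A1.col(j) = a1; A2.col(j) = a2;
    Dz3(0, j) = dz3;
    bd3.g(0, 0) += dz3;
    fvec da2 = Wd3.w.t() * dz3;
    fvec dz2 = da2 % conv_to<fvec>::from(zd2 > 0);
    Dz2.col(j) = dz2; bd2.g += dz2;
    fvec da1 = Wd2.w.t() * dz2;
    fvec dz1 = da1 % conv_to<fvec>::from(zd1 > 0);
    Dz1.col(j) = dz1; bd1.g += dz1;
    fvec dxf = Wd1.w.t() * dz1;

    fmat dp2(dxf.memptr(), (uword)H2 * W2, C2, false, true);
    dr2.set_size((uword)H1 * W1, C2);
    unpool(dp2, idx2, dr2);
    dz2c = dr2 % conv_to<fmat>::from(z2 > 0);
    Wc2.g += cols2.t() * dz2c;
    bc2.g += sum(dz2c, 0);
    dcols2 = dz2c * Wc2.w.t();
    dp1.set_size((uword)H1 * W1, C1);
    col2im(dcols2, H1, W1, 5, dp1);
    dr1.set_size((uword)H * W, C1);
    unpool(dp1, idx1, dr1);
    dz1c = dr1 % conv_to<fmat>::from(z1 > 0);
    Wc1.g += cols1.t() * dz1c;
    bc1.g += sum(dz1c, 0);
  }

  void adam_step(Param& P, double lr, double b1, double b2, double eps,
                 double scale) {
    if (P.m.n_elem != P.w.n_elem) {
      P.m.zeros(P.w.n_rows, P.w.n_cols);
      P.v.zeros(P.w.n_rows, P.w.n_cols);
    }
    const double c1 = 1.0 - std::pow(b1, (double)adam_t);
    const double c2 = 1.0 - std::pow(b2, (double)adam_t);
    float* w = P.w.memptr(); float* g = P.g.memptr();
    float* m = P.m.memptr(); float* v = P.v.memptr();
    const uword n = P.w.n_elem;
    for (uword i = 0; i < n; ++i) {
      const float gi = (float)(g[i] * scale);
      m[i] = (float)(b1 * m[i] + (1.0 - b1) * gi);
      v[i] = (float)(b2 * v[i] + (1.0 - b2) * (double)gi * gi);
      w[i] -= (float)(lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps));
    }
  }

  void step_all(double lr, double b1, double b2, double eps, double scale) {
    ++adam_t;
    Param* ps[10] = {&Wc1, &bc1, &Wc2, &bc2, &Wd1, &bd1, &Wd2, &bd2, &Wd3, &bd3};
    for (auto* p : ps) adam_step(*p, lr, b1, b2, eps, scale);
  }

  void zero_grads() {
    Param* ps[10] = {&Wc1, &bc1, &Wc2, &bc2, &Wd1, &bd1, &Wd2, &bd2, &Wd3, &bd3};
    for (auto* p : ps) p->zero_grad();
  }

  // drop the large per-image work buffers (several hundred MB) once a
  // training or scoring pass is over; they are re-sized on demand
  void release_buffers() {
    a0.reset(); cols1.reset(); z1.reset(); r1.reset(); p1.reset();
    cols2.reset(); z2.reset(); r2.reset(); p2.reset();
    idx1.reset(); idx2.reset();
    xf.reset(); zd1.reset(); a1.reset(); zd2.reset(); a2.reset();
    dcols2.reset(); dX2.reset(); dr2.reset(); dz2c.reset(); dr1.reset();
    dz1c.reset(); dp1.reset();
    Param* ps[10] = {&Wc1, &bc1, &Wc2, &bc2, &Wd1, &bd1, &Wd2, &bd2, &Wd3, &bd3};
    for (auto* p : ps) p->g.reset();
  }
};

inline double bce(double p, double y) {
  const double q = std::min(std::max(p, 1e-7), 1.0 - 1e-7);
  return -(y * std::log(q) + (1.0 - y) * std::log(1.0 - q));
}

}  // namespace

// [[Rcpp::export(name = ".cnn_create_cpp")]]
SEXP cnn_create_cpp(double seed) {
  Rcpp::XPtr<CNN> ptr(new CNN((unsigned long)seed), true);
  return ptr;
}

// [[Rcpp::export(name = ".cnn_param_counts_cpp")]]
Rcpp::NumericVector cnn_param_counts_cpp(SEXP model) {
  Rcpp::XPtr<CNN> net(model);
  Rcpp::NumericVector out = Rcpp::NumericVector::create(
      Rcpp::Named("conv1") = (double)(net->Wc1.w.n_elem + net->bc1.w.n_elem),
      Rcpp::Named("conv2") = (double)(net->Wc2.w.n_elem + net->bc2.w.n_elem),
      Rcpp::Named("dense1") = (double)(net->Wd1.w.n_elem + net->bd1.w.n_elem),
      Rcpp::Named("dense2") = (double)(net->Wd2.w.n_elem + net->bd2.w.n_elem),
      Rcpp::Named("output") = (double)(net->Wd3.w.n_elem + net->bd3.w.n_elem));
  return out;
}

// [[Rcpp::export(name = ".cnn_feature_shapes_cpp")]]
Rcpp::List cnn_feature_shapes_cpp(SEXP model) {
  Rcpp::XPtr<CNN> net(model);
  return Rcpp::List::create(
      Rcpp::Named("input") = Rcpp::IntegerVector::create(CNN::H, CNN::W, CNN::C),
      Rcpp::Named("conv1") = Rcpp::IntegerVector::create(CNN::H, CNN::W, CNN::C1),
      Rcpp::Named("pool1") = Rcpp::IntegerVector::create(CNN::H1, CNN::W1, CNN::C1),
      Rcpp::Named("conv2") = Rcpp::IntegerVector::create(CNN::H1, CNN::W1, CNN::C2),
      Rcpp::Named("pool2") = Rcpp::IntegerVector::create(CNN::H2, CNN::W2, CNN::C2),
      Rcpp::Named("flatten") = Rcpp::IntegerVector::create(CNN::NFLAT),
      Rcpp::Named("dense1") = Rcpp::IntegerVector::create(256),
      Rcpp::Named("dense2") = Rcpp::IntegerVector::create(128),
      Rcpp::Named("output") = Rcpp::IntegerVector::create(1));
}

// [[Rcpp::export(name = ".cnn_checksum_cpp")]]
double cnn_checksum_cpp(SEXP model) {
  Rcpp::XPtr<CNN> net(model);
  long double acc = 0.0;
  Param* ps[10] = {&net->Wc1, &net->bc1, &net->Wc2, &net->bc2, &net->Wd1,
                   &net->bd1, &net->Wd2, &net->bd2, &net->Wd3, &net->bd3};
  for (auto* p : ps)
    for (uword i = 0; i < p->w.n_elem; ++i) acc += (long double)p->w[i];
  return (double)acc;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
Rcpp::NumericVector cnn_predict_cpp(SEXP model, Rcpp::RawVector images,
                                    R_xlen_t n) {
  Rcpp::XPtr<CNN> net(model);
  if (images.size() != n * (R_xlen_t)CNN::NPIX)
    Rcpp::stop("image buffer size does not match n * 224*224*3");
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    net->load_image(images, i);
    out[i] = net->forward();
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  net->release_buffers();
  return out;
}

// Trains in place; returns the per-epoch history matrix
// (train_loss, train_acc, val_loss, val_acc).
// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::NumericMatrix cnn_train_cpp(SEXP model, Rcpp::RawVector images,
                                  Rcpp::IntegerVector labels,
                                  Rcpp::IntegerVector train_idx,
                                  Rcpp::IntegerVector val_idx,
                                  int epochs, int batch_size, double lr,
                                  double beta1, double beta2, double eps,
                                  bool verbose) {
  Rcpp::XPtr<CNN> net(model);
  const R_xlen_t n = labels.size();
  if (images.size() != n * (R_xlen_t)CNN::NPIX)
    Rcpp::stop("image buffer size does not match length(labels) * 224*224*3");
  const int ntr = train_idx.size(), nva = val_idx.size();
  Rcpp::NumericMatrix history(epochs, 4);
  Rcpp::colnames(history) = Rcpp::CharacterVector::create(
      "train_loss", "train_acc", "val_loss", "val_acc");
  std::vector<int> order(train_idx.begin(), train_idx.end());
  const uword B = (uword)batch_size;
  fmat Xf(CNN::NFLAT, B), A1(256, B), A2(128, B), Dz1(256, B), Dz2(128, B),
      Dz3(1, B);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the model's own generator (seed-deterministic)
    for (int i = ntr - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(order[i], order[u(net->rng)]);
    }
    double ep_loss = 0.0; int ep_correct = 0;
    for (int b0 = 0; b0 < ntr; b0 += batch_size) {
      const int nb = std::min(batch_size, ntr - b0);
      net->zero_grads();
      for (int j = 0; j < nb; ++j) {
        const int i = order[b0 + j];
        const double y = labels[i];
        net->load_image(images, i);
        const double p = net->forward();
        ep_loss += bce(p, y);
        ep_correct += ((p >= 0.5) == (y >= 0.5));
        net->backward(p, y, Xf, A1, A2, Dz1, Dz2, Dz3, (uword)j);
      }
      // batched dense weight gradients over the batch's stored activations
      const double scale = 1.0 / nb;
      net->Wd1.g = Dz1.cols(0, nb - 1) * Xf.cols(0, nb - 1).t();
      net->Wd2.g = Dz2.cols(0, nb - 1) * A1.cols(0, nb - 1).t();
      net->Wd3.g = Dz3.cols(0, nb - 1) * A2.cols(0, nb - 1).t();
      net->step_all(lr, beta1, beta2, eps, scale);
      Rcpp::checkUserInterrupt();
    }
    history(ep, 0) = ep_loss / ntr;
    history(ep, 1) = (double)ep_correct / ntr;
    if (nva > 0) {
      double vl = 0.0; int vc = 0;
      for (int j = 0; j < nva; ++j) {
        const int i = val_idx[j];
        net->load_image(images, i);
        const double p = net->forward();
        vl += bce(p, labels[i]);
        vc += ((p >= 0.5) == (labels[i] >= 0.5));
      }
      history(ep, 2) = vl / nva;
      history(ep, 3) = (double)vc / nva;
    } else {
      history(ep, 2) = NA_REAL;
      history(ep, 3) = NA_REAL;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << "  loss " << history(ep, 0) << "  acc " << history(ep, 1)
                  << "  val_acc " << history(ep, 3) << std::endl;
  }
  net->release_buffers();
  return history;
}
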