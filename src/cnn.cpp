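// Two-convolution-layer network for swim-path image recognition.
//
// Architecture: conv(k1, n1 kernels) -> ReLU -> max-pool -> conv(k2, n2
// kernels) -> ReLU -> max-pool -> fully connected (fc nodes, ReLU, dropout)
// -> fully connected (K classes) -> softmax, trained with cross-entropy and
// Adam. All arithmetic is single precision; all randomness (weight init,
// epoch shuffling, dropout) flows from one mt19937 stream so training is
// bit-reproducible for a fixed seed on a fixed thread count.
//
// Convolutions are unpadded ("valid") and implemented as im2col + GEMM.
#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// [[Rcpp::depends(RcppArmadillo)]]

// Converged training produces subnormal single-precision values (squared
// gradients in Adam, post-softmax residuals), and x86 handles subnormals in
// microcode at a large cost. Flush them to zero for the duration of a
// train/predict call and restore the FP state afterwards; the flushed
// quantities are below any numerically meaningful scale here.
struct FlushDenormals {
#if defined(__SSE2__)
  unsigned int ftz, daz;
  FlushDenormals()
      : ftz(_MM_GET_FLUSH_ZERO_MODE()), daz(_MM_GET_DENORMALS_ZERO_MODE()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

using arma::fmat;
using arma::fvec;
using arma::umat;

namespace {

struct Dims {
  int H;             // input image side
  int k1, n1;        // conv1 kernel side, kernel count
  int k2, n2;        // conv2 kernel side, kernel count
  int fc, K;         // hidden width, class count
  int pw, ps;        // pooling window and stride
  bool pool_same;    // stride-1 "same" pooling variant
  int o1, p1, o2, p2, flat;
};

int pool_out(int o, int w, int s, bool same) {
  if (same) return o;
  return (o - w) / s + 1;
}

Dims make_dims(const Rcpp::List& cfg) {
  Dims d;
  d.H = Rcpp::as<int>(cfg["image_size"]);
  d.k1 = Rcpp::as<int>(cfg["kernel1"]);
  d.n1 = Rcpp::as<int>(cfg["n_kernels1"]);
  d.k2 = Rcpp::as<int>(cfg["kernel2"]);
  d.n2 = Rcpp::as<int>(cfg["n_kernels2"]);
  d.fc = Rcpp::as<int>(cfg["fc_width"]);
  d.K = Rcpp::as<int>(cfg["n_classes"]);
  d.pw = Rcpp::as<int>(cfg["pool_window"]);
  d.ps = Rcpp::as<int>(cfg["pool_stride"]);
  d.pool_same = Rcpp::as<bool>(cfg["pool_same"]);
  d.o1 = d.H - d.k1 + 1;
  d.p1 = pool_out(d.o1, d.pw, d.ps, d.pool_same);
  d.o2 = d.p1 - d.k2 + 1;
  d.p2 = pool_out(d.o2, d.pw, d.ps, d.pool_same);
  d.flat = d.n2 * d.p2 * d.p2;
  if (d.o1 < 1 || d.p1 < 1 || d.o2 < 1 || d.p2 < 1)
    Rcpp::stop("invalid layer geometry");
  return d;
}

// im2col for a single-channel image stored as one column (len H*H,
// column-major pixels). Output columns are o*o output pixels; rows are
// kernel offsets (kj*k + ki).
void im2col1(const fmat& X, int b, int H, int k, int o, fmat& col,
             arma::uword col0) {
  const float* x = X.colptr(b);
  for (int oj = 0; oj < o; ++oj) {
    for (int oi = 0; oi < o; ++oi) {
      float* dst = col.colptr(col0 + (arma::uword)oj * o + oi);
      for (int kj = 0; kj < k; ++kj) {
        const float* src = x + (oj + kj) * H + oi;
        for (int ki = 0; ki < k; ++ki) dst[kj * k + ki] = src[ki];
      }
    }
  }
}

// im2col for a C-channel map stored as an (C x p*p) block of columns of P
// starting at column b*p*p. Row layout: (kj*k + ki)*C + c, i.e. the C
// channels of one tap are contiguous so each tap is a memcpy.
void im2colC(const fmat& P, arma::uword pcol0, int C, int p, int k, int o,
             fmat& col, arma::uword col0) {
  for (int oj = 0; oj < o; ++oj) {
    for (int oi = 0; oi < o; ++oi) {
      float* dst = col.colptr(col0 + (arma::uword)oj * o + oi);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const float* src = P.colptr(pcol0 + (arma::uword)(oj + kj) * p + (oi + ki));
          std::memcpy(dst + (arma::uword)(kj * k + ki) * C, src,
                      sizeof(float) * C);
        }
      }
    }
  }
}

// reverse of im2colC: scatter-add gradient columns back onto the map
void col2imC(const fmat& dcol, arma::uword col0, int C, int p, int k, int o,
             fmat& dP, arma::uword pcol0) {
  for (int oj = 0; oj < o; ++oj) {
    for (int oi = 0; oi < o; ++oi) {
      const float* src = dcol.colptr(col0 + (arma::uword)oj * o + oi);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          float* dst = dP.colptr(pcol0 + (arma::uword)(oj + kj) * p + (oi + ki));
          const float* s = src + (arma::uword)(kj * k + ki) * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
}

// spatial max pooling on an (F x o*o*B) activation; records argmax columns
void pool_forward(const fmat& A, int o, int pout, int w, int s, bool same,
                  int B, fmat& P, umat& M) {
  const int F = A.n_rows;
  const float neg = -std::numeric_limits<float>::infinity();
  for (int b = 0; b < B; ++b) {
    const arma::uword a0 = (arma::uword)b * o * o;
    const arma::uword p0 = (arma::uword)b * pout * pout;
    for (int pj = 0; pj < pout; ++pj) {
      for (int pi = 0; pi < pout; ++pi) {
        const int i0 = same ? pi : pi * s;
        const int j0 = same ? pj : pj * s;
        const arma::uword pc = p0 + (arma::uword)pj * pout + pi;
        float* pd = P.colptr(pc);
        arma::uword* md = M.colptr(pc);
        for (int f = 0; f < F; ++f) pd[f] = neg;
        for (int wj = 0; wj < w; ++wj) {
          const int j = j0 + wj;
          if (j >= o) continue;  // boundary of the "same" variant
          for (int wi = 0; wi < w; ++wi) {
            const int i = i0 + wi;
            if (i >= o) continue;
            const arma::uword ac = a0 + (arma::uword)j * o + i;
            const float* ad = A.colptr(ac);
            for (int f = 0; f < F; ++f) {
              if (ad[f] > pd[f]) {
                pd[f] = ad[f];
                md[f] = ac;
              }
            }
          }
        }
      }
    }
  }
}

// zero gradient entries where the forward activation was clipped by ReLU
inline void relu_mask(fmat& dX, const fmat& X) {
  float* d = dX.memptr();
  const float* x = X.memptr();
  const arma::uword n = dX.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (x[i] <= 0.0f) d[i] = 0.0f;
}

void pool_backward(const fmat& dP, const umat& M, fmat& dA) {
  const arma::uword F = dP.n_rows, n = dP.n_cols;
  for (arma::uword c = 0; c < n; ++c) {
    const float* s = dP.colptr(c);
    const arma::uword* m = M.colptr(c);
    for (arma::uword f = 0; f < F; ++f) dA(f, m[f]) += s[f];
  }
}

template <typename T>
struct Adam {
  T m, v;
  void init(const T& like) {
    m.zeros(arma::size(like));
    v.zeros(arma::size(like));
  }
  void step(T& w, const T& g, float lr, float b1, float b2, float eps, int t) {
    // single fused pass: the hidden-layer weight matrix holds ~1.6M
    // parameters, so expression temporaries here would dominate a batch
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    float* wp = w.memptr();
    float* mp = m.memptr();
    float* vp = v.memptr();
    const float* gp = g.memptr();
    const arma::uword n = w.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      mp[i] = b1 * mp[i] + (1.0f - b1) * gp[i];
      vp[i] = b2 * vp[i] + (1.0f - b2) * gp[i] * gp[i];
      wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
    }
  }
};

struct Net {
  Dims d;
  fmat W1, W2, Wf1, Wf2;
  fvec b1, b2, bf1, bf2;

  // forward caches (batch-sized)
  fmat col1, A1, P1, col2, A2, P2, F, H1, Out;
  umat M1, M2;
  fmat drop;

  void alloc_cache(int B) {
    col1.set_size((arma::uword)d.k1 * d.k1, (arma::uword)d.o1 * d.o1 * B);
    col2.set_size((arma::uword)d.k2 * d.k2 * d.n1,
                  (arma::uword)d.o2 * d.o2 * B);
    P1.set_size(d.n1, (arma::uword)d.p1 * d.p1 * B);
    M1.set_size(d.n1, (arma::uword)d.p1 * d.p1 * B);
    P2.set_size(d.n2, (arma::uword)d.p2 * d.p2 * B);
    M2.set_size(d.n2, (arma::uword)d.p2 * d.p2 * B);
  }

  // X: (H*H x B) image batch; returns class probabilities (K x B)
  void forward(const fmat& X, bool training, float keep, std::mt19937& rng) {
    const int B = X.n_cols;
    alloc_cache(B);
    for (int b = 0; b < B; ++b)
      im2col1(X, b, d.H, d.k1, d.o1, col1, (arma::uword)b * d.o1 * d.o1);
    A1 = W1 * col1;
    A1.each_col() += b1;
    A1.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    pool_forward(A1, d.o1, d.p1, d.pw, d.ps, d.pool_same, B, P1, M1);
    for (int b = 0; b < B; ++b)
      im2colC(P1, (arma::uword)b * d.p1 * d.p1, d.n1, d.p1, d.k2, d.o2, col2,
              (arma::uword)b * d.o2 * d.o2);
    A2 = W2 * col2;
    A2.each_col() += b2;
    A2.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    pool_forward(A2, d.o2, d.p2, d.pw, d.ps, d.pool_same, B, P2, M2);
    // flatten: column b is the (n2 x p2*p2) block read column-major
    F.set_size(d.flat, B);
    for (int b = 0; b < B; ++b)
      std::memcpy(F.colptr(b), P2.colptr((arma::uword)b * d.p2 * d.p2),
                  sizeof(float) * d.flat);
    H1 = Wf1 * F;
    H1.each_col() += bf1;
    H1.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (training && keep < 1.0f) {
      drop.set_size(d.fc, B);
      std::uniform_real_distribution<float> unif(0.0f, 1.0f);
      const float scale = 1.0f / keep;
      for (arma::uword j = 0; j < drop.n_cols; ++j)
        for (arma::uword i = 0; i < drop.n_rows; ++i)
          drop(i, j) = unif(rng) < keep ? scale : 0.0f;
      H1 %= drop;
    }
    Out = Wf2 * H1;
    Out.each_col() += bf2;
    // softmax, columnwise
    for (int b = 0; b < B; ++b) {
      float mx = Out.col(b).max();
      Out.col(b) = arma::exp(Out.col(b) - mx);
      Out.col(b) /= arma::accu(Out.col(b));
    }
  }
};

fmat as_f(const Rcpp::NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) out(i, j) = (float)x(i, j);
  return out;
}

fvec as_fv(const Rcpp::NumericVector& x) {
  fvec out(x.size());
  for (int i = 0; i < x.size(); ++i) out(i) = (float)x[i];
  return out;
}

Rcpp::NumericMatrix as_d(const fmat& x) {
  Rcpp::NumericMatrix out(x.n_rows, x.n_cols);
  for (arma::uword j = 0; j < x.n_cols; ++j)
    for (arma::uword i = 0; i < x.n_rows; ++i) out(i, j) = (double)x(i, j);
  return out;
}

Rcpp::NumericVector as_dv(const fvec& x) {
  Rcpp::NumericVector out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i) out[i] = (double)x(i);
  return out;
}

fmat images_to_X(const arma::cube& images) {
  const arma::uword H = images.n_rows, N = images.n_slices;
  if (images.n_cols != H) Rcpp::stop("images must be square");
  fmat X(H * H, N);
  for (arma::uword n = 0; n < N; ++n) {
    const double* s = images.slice_colptr(n, 0);
    float* dst = X.colptr(n);
    for (arma::uword i = 0; i < H * H; ++i) dst[i] = (float)s[i];
  }
  return X;
}

void load_params(Net& net, const Rcpp::List& par) {
  net.W1 = as_f(par["W1"]);
  net.b1 = as_fv(par["b1"]);
  net.W2 = as_f(par["W2"]);
  net.b2 = as_fv(par["b2"]);
  net.Wf1 = as_f(par["Wf1"]);
  net.bf1 = as_fv(par["bf1"]);
  net.Wf2 = as_f(par["Wf2"]);
  net.bf2 = as_fv(par["bf2"]);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::cube& images, const arma::ivec& labels,
                         const Rcpp::List& cfg) {
  FlushDenormals fp_guard;
  Net net;
  net.d = make_dims(cfg);
  const Dims& d = net.d;
  const int N = images.n_slices;
  if ((int)labels.n_elem != N) Rcpp::stop("labels/images length mismatch");
  if ((int)images.n_rows != d.H) Rcpp::stop("image size mismatch with config");
  for (int i = 0; i < N; ++i)
    if (labels(i) < 0 || labels(i) >= d.K) Rcpp::stop("label out of range");

  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = std::max(1, Rcpp::as<int>(cfg["batch_size"]));
  const float lr = (float)Rcpp::as<double>(cfg["learning_rate"]);
  const float beta1 = (float)Rcpp::as<double>(cfg["beta1"]);
  const float beta2 = (float)Rcpp::as<double>(cfg["beta2"]);
  const float eps = (float)Rcpp::as<double>(cfg["adam_epsilon"]);
  const float keep = 1.0f - (float)Rcpp::as<double>(cfg["dropout"]);
  const unsigned seed = (unsigned)Rcpp::as<double>(cfg["seed"]);

  std::mt19937 rng(seed);
  std::normal_distribution<float> norm(0.0f, 1.0f);
  auto he_init = [&](fmat& w, arma::uword r, arma::uword c, double fan_in) {
    w.set_size(r, c);
    const float sd = (float)std::sqrt(2.0 / fan_in);
    for (arma::uword j = 0; j < c; ++j)
      for (arma::uword i = 0; i < r; ++i) w(i, j) = sd * norm(rng);
  };
  he_init(net.W1, d.n1, (arma::uword)d.k1 * d.k1, d.k1 * d.k1);
  he_init(net.W2, d.n2, (arma::uword)d.k2 * d.k2 * d.n1, d.k2 * d.k2 * d.n1);
  he_init(net.Wf1, d.fc, d.flat, d.flat);
  he_init(net.Wf2, d.K, d.fc, d.fc);
  net.b1.zeros(d.n1);
  net.b2.zeros(d.n2);
  net.bf1.zeros(d.fc);
  net.bf2.zeros(d.K);

  Adam<fmat> aW1, aW2, aWf1, aWf2;
  Adam<fvec> ab1, ab2, abf1, abf2;
  aW1.init(net.W1);
  ab1.init(net.b1);
  aW2.init(net.W2);
  ab2.init(net.b2);
  aWf1.init(net.Wf1);
  abf1.init(net.bf1);
  aWf2.init(net.Wf2);
  abf2.init(net.bf2);

  const fmat Xall = images_to_X(images);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  Rcpp::NumericVector loss_history(epochs);
  int t = 0;
  fmat Xb, dOut, dH1, dF, dP2, dA2, dcol2, dP1, dA1, gW, gWf;
  fvec gb;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      Xb.set_size((arma::uword)d.H * d.H, B);
      for (int b = 0; b < B; ++b) Xb.col(b) = Xall.col(idx[start + b]);
      net.forward(Xb, true, keep, rng);

      // cross-entropy loss and output gradient
      dOut = net.Out;
      for (int b = 0; b < B; ++b) {
        const int y = labels(idx[start + b]);
        ep_loss += -std::log(std::max(net.Out(y, b), 1e-12f));
        dOut(y, b) -= 1.0f;
      }
      dOut /= (float)B;

      ++t;
      // fc2
      gWf = dOut * net.H1.t();
      gb = arma::sum(dOut, 1);
      dH1 = net.Wf2.t() * dOut;
      aWf2.step(net.Wf2, gWf, lr, beta1, beta2, eps, t);
      abf2.step(net.bf2, gb, lr, beta1, beta2, eps, t);
      // fc1 (through dropout then ReLU)
      if (keep < 1.0f) dH1 %= net.drop;
      relu_mask(dH1, net.H1);
      gWf = dH1 * net.F.t();
      gb = arma::sum(dH1, 1);
      dF = net.Wf1.t() * dH1;
      aWf1.step(net.Wf1, gWf, lr, beta1, beta2, eps, t);
      abf1.step(net.bf1, gb, lr, beta1, beta2, eps, t);
      // unflatten -> pool2 backward -> conv2
      dP2.set_size(d.n2, (arma::uword)d.p2 * d.p2 * B);
      for (int b = 0; b < B; ++b)
        std::memcpy(dP2.colptr((arma::uword)b * d.p2 * d.p2), dF.colptr(b),
                    sizeof(float) * d.flat);
      dA2.zeros(d.n2, (arma::uword)d.o2 * d.o2 * B);
      pool_backward(dP2, net.M2, dA2);
      relu_mask(dA2, net.A2);
      gW = dA2 * net.col2.t();
      gb = arma::sum(dA2, 1);
      dcol2 = net.W2.t() * dA2;
      aW2.step(net.W2, gW, lr, beta1, beta2, eps, t);
      ab2.step(net.b2, gb, lr, beta1, beta2, eps, t);
      // col2im -> pool1 backward -> conv1
      dP1.zeros(d.n1, (arma::uword)d.p1 * d.p1 * B);
      for (int b = 0; b < B; ++b)
        col2imC(dcol2, (arma::uword)b * d.o2 * d.o2, d.n1, d.p1, d.k2, d.o2,
                dP1, (arma::uword)b * d.p1 * d.p1);
      dA1.zeros(d.n1, (arma::uword)d.o1 * d.o1 * B);
      pool_backward(dP1, net.M1, dA1);
      relu_mask(dA1, net.A1);
      gW = dA1 * net.col1.t();
      gb = arma::sum(dA1, 1);
      aW1.step(net.W1, gW, lr, beta1, beta2, eps, t);
      ab1.step(net.b1, gb, lr, beta1, beta2, eps, t);
    }
    loss_history[ep] = ep_loss / N;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = as_d(net.W1), Rcpp::Named("b1") = as_dv(net.b1),
      Rcpp::Named("W2") = as_d(net.W2), Rcpp::Named("b2") = as_dv(net.b2),
      Rcpp::Named("Wf1") = as_d(net.Wf1), Rcpp::Named("bf1") = as_dv(net.bf1),
      Rcpp::Named("Wf2") = as_d(net.Wf2), Rcpp::Named("bf2") = as_dv(net.bf2),
      Rcpp::Named("loss_history") = loss_history);
}

//' @noRd
// [[Rcpp::export(name = ".cnn_predict_cpp")]]
Rcpp::NumericMatrix cnn_predict_cpp(const Rcpp::List& params,
                                    const arma::cube& images,
                                    const Rcpp::List& cfg) {
  FlushDenormals fp_guard;
  Net net;
  net.d = make_dims(cfg);
  if ((int)images.n_rows != net.d.H)
    Rcpp::stop("image size mismatch with config");
  load_params(net, params);
  const int N = images.n_slices;
  const fmat Xall = images_to_X(images);
  Rcpp::NumericMatrix probs(N, net.d.K);
  std::mt19937 rng(0);
  const int batch = 128;
  for (int start = 0; start < N; start += batch) {
    const int B = std::min(batch, N - start);
    fmat Xb = Xall.cols(start, start + B - 1);
    net.forward(Xb, false, 1.0f, rng);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < net.d.K; ++k) probs(start + b, k) = net.Out(k, b);
  }
  return probs;
}
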