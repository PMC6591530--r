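// Patch-CNN compute engine: im2col convolution, batch normalisation,
// stride-1 max pooling, fully-connected and softmax layers, with the
// backward passes needed for mini-batch SGD + Nesterov momentum.
//
// Activations are batch-major: an activation matrix A has one ROW per
// sample and one column per feature, columns ordered channel-block-major,
// column-major spatially inside a channel: col = c*H*W + w*H + h. With
// this layout the im2col gather copies contiguous batch-length runs, the
// output of the convolution gemm is bit-identical to the next layer's
// activation matrix (no reorder), and each batch-norm channel block is one
// contiguous memory region.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// The training loop allocates and frees multi-megabyte activation buffers
// every mini-batch; letting glibc serve those from the heap freelist
// instead of fresh mmap/munmap cycles avoids re-faulting the pages each
// batch.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 64 * 1024 * 1024);
    done = true;
  }
#endif
}

enum LayerKind { CONV = 0, NORM = 1, POOL = 2, FULL = 3, SOFTMAX = 4 };

struct Shape {
  int c, h, w;
  int size() const { return c * h * w; }
};

struct Layer {
  int kind = CONV;
  bool has_bias = false;
  Shape in{1, 0, 0}, out{1, 0, 0};
  // parameters
  arma::mat W;                  // conv: in_c*9 x out_c; full/softmax: in x out
  arma::vec b;                  // softmax (and biased full) only
  arma::vec gamma, beta;        // norm
  arma::vec rmean, rvar;        // norm running statistics
  // velocities
  arma::mat vW;
  arma::vec vb, vgamma, vbeta;
  // caches (training forward)
  arma::mat x_in;               // input activations (m x in_features)
  arma::mat colbuf;             // im2col matrix (m*OH*OW x in_c*9)
  arma::mat pre;                // post-ReLU output used as the ReLU mask
  arma::Mat<unsigned char> poolidx;  // which of the 4 pooled inputs won
  arma::mat xhat;               // norm: normalised activations
  arma::vec mu, var_;           // norm: batch statistics
};

struct Net {
  int patch = 0;
  double eps = 1e-5;
  double bn_momentum = 0.99;
  double bn_count = 0;  // batches seen; bias-corrects the running averages
  std::vector<Layer> layers;
};

static int kind_code(const std::string& k) {
  if (k == "convolution") return CONV;
  if (k == "batch_norm") return NORM;
  if (k == "max_pool") return POOL;
  if (k == "fully_connected") return FULL;
  if (k == "softmax") return SOFTMAX;
  stop("unknown layer kind '%s'", k.c_str());
  return -1;
}

static void resolve_shapes(Net& net) {
  Shape cur{1, net.patch, net.patch};
  bool flat = false;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    Layer& L = net.layers[i];
    L.in = cur;
    switch (L.kind) {
    case CONV:
      if (flat) stop("convolution after flattening is not supported");
      if (cur.h < 3 || cur.w < 3)
        stop("layer %d: 3x3 convolution needs a map of at least 3x3, got %dx%d",
             (int)i + 1, cur.h, cur.w);
      cur = Shape{(int)L.W.n_cols, cur.h - 2, cur.w - 2};
      break;
    case POOL:
      if (cur.h < 2 || cur.w < 2)
        stop("layer %d: 2x2 pooling needs a map of at least 2x2, got %dx%d",
             (int)i + 1, cur.h, cur.w);
      cur = Shape{cur.c, cur.h - 1, cur.w - 1};
      break;
    case NORM:
      break;
    case FULL:
    case SOFTMAX:
      flat = true;
      cur = Shape{(int)L.W.n_cols, 1, 1};
      break;
    }
    L.out = cur;
  }
}

// ---- (de)serialisation between the R-side state list and Net ----

static Net net_from_list(const List& state) {
  Net net;
  net.patch = as<int>(state["patch_size"]);
  net.eps = as<double>(state["epsilon"]);
  net.bn_momentum = as<double>(state["bn_momentum"]);
  net.bn_count = as<double>(state["bn_count"]);
  List lys = state["layers"];
  for (int i = 0; i < lys.size(); ++i) {
    List l = lys[i];
    Layer L;
    L.kind = kind_code(as<std::string>(l["kind"]));
    if (L.kind == CONV || L.kind == FULL || L.kind == SOFTMAX) {
      L.W = as<arma::mat>(l["W"]);
      L.vW = as<arma::mat>(l["vW"]);
      L.has_bias = as<bool>(l["has_bias"]);
      if (L.has_bias) {
        L.b = as<arma::vec>(l["b"]);
        L.vb = as<arma::vec>(l["vb"]);
      }
    } else if (L.kind == NORM) {
      L.gamma = as<arma::vec>(l["gamma"]);
      L.beta = as<arma::vec>(l["beta"]);
      L.rmean = as<arma::vec>(l["rmean"]);
      L.rvar = as<arma::vec>(l["rvar"]);
      L.vgamma = as<arma::vec>(l["vgamma"]);
      L.vbeta = as<arma::vec>(l["vbeta"]);
    }
    net.layers.push_back(std::move(L));
  }
  resolve_shapes(net);
  return net;
}

static List net_to_list(const Net& net) {
  List lys(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Layer& L = net.layers[i];
    switch (L.kind) {
    case CONV:
      lys[i] = List::create(_["kind"] = "convolution", _["W"] = L.W,
                            _["vW"] = L.vW, _["has_bias"] = false);
      break;
    case FULL:
    case SOFTMAX: {
      List l = List::create(
          _["kind"] = (L.kind == FULL ? "fully_connected" : "softmax"),
          _["W"] = L.W, _["vW"] = L.vW, _["has_bias"] = L.has_bias);
      if (L.has_bias) {
        l["b"] = L.b;
        l["vb"] = L.vb;
      }
      lys[i] = l;
      break;
    }
    case NORM:
      lys[i] = List::create(_["kind"] = "batch_norm", _["gamma"] = L.gamma,
                            _["beta"] = L.beta, _["rmean"] = L.rmean,
                            _["rvar"] = L.rvar, _["vgamma"] = L.vgamma,
                            _["vbeta"] = L.vbeta);
      break;
    case POOL:
      lys[i] = List::create(_["kind"] = "max_pool");
      break;
    }
  }
  return List::create(_["patch_size"] = net.patch, _["epsilon"] = net.eps,
                      _["bn_momentum"] = net.bn_momentum,
                      _["bn_count"] = net.bn_count, _["layers"] = lys);
}

// ---- layer primitives (batch-major) ----

// K(smp + m*(ow*OH+oh), c*9 + kw*3 + kh) = A(smp, c*H*W + (ow+kw)*H + oh+kh)
static void im2col(const arma::mat& A, const Shape& s, arma::mat& K) {
  const int OH = s.h - 2, OW = s.w - 2;
  const size_t m = A.n_rows;
  K.set_size(m * OH * OW, (size_t)s.c * 9);
  for (int c = 0; c < s.c; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        double* kcol = K.colptr((size_t)c * 9 + kw * 3 + kh);
        for (int ow = 0; ow < OW; ++ow) {
          const double* acol =
              A.colptr((size_t)c * s.h * s.w + (size_t)(ow + kw) * s.h + kh);
          // oh runs over contiguous source columns; copy OH runs of length m
          for (int oh = 0; oh < OH; ++oh)
            std::memcpy(kcol + ((size_t)ow * OH + oh) * m,
                        acol + (size_t)oh * m, sizeof(double) * m);
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& dK, const Shape& s, arma::mat& dA) {
  const int OH = s.h - 2, OW = s.w - 2;
  const size_t m = dA.n_rows;
  for (int c = 0; c < s.c; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const double* kcol = dK.colptr((size_t)c * 9 + kw * 3 + kh);
        for (int ow = 0; ow < OW; ++ow) {
          double* acol =
              dA.colptr((size_t)c * s.h * s.w + (size_t)(ow + kw) * s.h + kh);
          for (int oh = 0; oh < OH; ++oh) {
            const double* src = kcol + ((size_t)ow * OH + oh) * m;
            double* dst = acol + (size_t)oh * m;
            for (size_t j = 0; j < m; ++j) dst[j] += src[j];
          }
        }
      }
    }
  }
}

static inline void relu_inplace(arma::mat& M) {
  double* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// zero entries of dA where the forward output was clipped
static inline void relu_mask(arma::mat& dA, const arma::mat& post) {
  double* d = dA.memptr();
  const double* p = post.memptr();
  const size_t n = dA.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] <= 0) d[i] = 0;
}

static void pool_forward(const arma::mat& A, const Shape& in, arma::mat& out,
                         arma::Mat<unsigned char>* idx) {
  const int OH = in.h - 1, OW = in.w - 1;
  const size_t m = A.n_rows;
  out.set_size(m, (size_t)in.c * OH * OW);
  if (idx) idx->set_size(m, (size_t)in.c * OH * OW);
  for (int c = 0; c < in.c; ++c) {
    const size_t coff = (size_t)c * in.h * in.w;
    const size_t ooff = (size_t)c * OH * OW;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        size_t cand[4] = {coff + (size_t)ow * in.h + oh,
                          coff + (size_t)ow * in.h + oh + 1,
                          coff + (size_t)(ow + 1) * in.h + oh,
                          coff + (size_t)(ow + 1) * in.h + oh + 1};
        const double* s0 = A.colptr(cand[0]);
        const double* s1 = A.colptr(cand[1]);
        const double* s2 = A.colptr(cand[2]);
        const double* s3 = A.colptr(cand[3]);
        double* op = out.colptr(ooff + (size_t)ow * OH + oh);
        if (idx) {
          unsigned char* ip = idx->colptr(ooff + (size_t)ow * OH + oh);
          for (size_t j = 0; j < m; ++j) {
            double v = s0[j];
            unsigned char a = 0;
            if (s1[j] > v) { v = s1[j]; a = 1; }
            if (s2[j] > v) { v = s2[j]; a = 2; }
            if (s3[j] > v) { v = s3[j]; a = 3; }
            op[j] = v;
            ip[j] = a;
          }
        } else {
          for (size_t j = 0; j < m; ++j) {
            double v = s0[j];
            if (s1[j] > v) v = s1[j];
            if (s2[j] > v) v = s2[j];
            if (s3[j] > v) v = s3[j];
            op[j] = v;
          }
        }
      }
    }
  }
}

// Forward one batch (rows of X are samples). In training mode NORM uses
// batch statistics and layer caches are stored.
static arma::mat forward(Net& net, const arma::mat& X, bool train,
                         bool update_running, std::vector<arma::mat>* trace) {
  arma::mat A = X;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    Layer& L = net.layers[i];
    switch (L.kind) {
    case CONV: {
      arma::mat K;
      im2col(A, L.in, K);
      // (m*OH*OW x in_c*9) x (in_c*9 x out_c); the result, reinterpreted
      // as m x (out_c*OH*OW), IS the next activation matrix
      arma::mat O = K * L.W;
      relu_inplace(O);
      O.reshape(A.n_rows, (size_t)L.out.size());
      if (train) { L.x_in = std::move(A); L.colbuf = std::move(K); L.pre = O; }
      A = std::move(O);
      break;
    }
    case NORM: {
      const size_t HW = (size_t)L.in.h * L.in.w;
      const int C = L.in.c;
      const size_t m = A.n_rows;
      const size_t blk = HW * m;  // contiguous per-channel block
      arma::vec mu(C), var_(C);
      if (train) {
        const double* p = A.memptr();
        for (int c = 0; c < C; ++c) {
          double s = 0, s2 = 0;
          const double* q = p + (size_t)c * blk;
          for (size_t j = 0; j < blk; ++j) { s += q[j]; s2 += q[j] * q[j]; }
          mu[c] = s / blk;
          var_[c] = s2 / blk - mu[c] * mu[c];
          if (var_[c] < 0) var_[c] = 0;
        }
        if (update_running) {
          L.rmean = net.bn_momentum * L.rmean + (1 - net.bn_momentum) * mu;
          L.rvar = net.bn_momentum * L.rvar + (1 - net.bn_momentum) * var_;
        }
      } else if (net.bn_count > 0) {
        // the exponential averages start at zero; correct the startup bias
        const double corr = 1.0 - std::pow(net.bn_momentum, net.bn_count);
        mu = L.rmean / corr;
        var_ = L.rvar / corr;
      } else {
        mu.zeros();
        var_.ones();
      }
      arma::mat xhat(A.n_rows, A.n_cols);
      arma::mat Y(A.n_rows, A.n_cols);
      for (int c = 0; c < C; ++c) {
        const double inv = 1.0 / std::sqrt(var_[c] + net.eps);
        const double g = L.gamma[c], b = L.beta[c], m0 = mu[c];
        const double* q = A.memptr() + (size_t)c * blk;
        double* xh = xhat.memptr() + (size_t)c * blk;
        double* yy = Y.memptr() + (size_t)c * blk;
        for (size_t j = 0; j < blk; ++j) {
          xh[j] = (q[j] - m0) * inv;
          yy[j] = g * xh[j] + b;
        }
      }
      if (train) { L.xhat = std::move(xhat); L.mu = mu; L.var_ = var_; }
      A = std::move(Y);
      break;
    }
    case POOL: {
      arma::mat out;
      pool_forward(A, L.in, out, train ? &L.poolidx : nullptr);
      A = std::move(out);
      break;
    }
    case FULL: {
      arma::mat O = A * L.W;  // (m x in) x (in x units)
      if (L.has_bias) O.each_row() += L.b.t();
      relu_inplace(O);
      if (train) { L.x_in = std::move(A); L.pre = O; }
      A = std::move(O);
      break;
    }
    case SOFTMAX: {
      arma::mat Z = A * L.W;
      Z.each_row() += L.b.t();
      if (train) L.x_in = std::move(A);
      Z.each_col() -= arma::max(Z, 1);
      Z = arma::exp(Z);
      arma::vec den = arma::sum(Z, 1);
      Z.each_col() /= den;
      A = std::move(Z);
      break;
    }
    }
    if (trace) trace->push_back(A);
  }
  return A;
}

// Cross-entropy on the two-way softmax output; y is 0 (normal) / 1 (DWMA).
static double batch_loss(const arma::mat& P, const arma::ivec& y) {
  double s = 0;
  for (size_t i = 0; i < y.n_elem; ++i) {
    double p = P(i, y[i]);
    s -= std::log(std::max(p, 1e-12));
  }
  return s / y.n_elem;
}

template <typename T>
static void nesterov_update(T& W, T& v, const T& g, double lr, double mom) {
  v = mom * v + g;
  W -= lr * (g + mom * v);
}

// Backward pass from softmax probabilities; updates parameters in place.
static void backward_and_update(Net& net, const arma::mat& P,
                                const arma::ivec& y, double lr, double mom) {
  const size_t m = P.n_rows;
  arma::mat dA = P;  // dL/dlogits = (p - onehot)/m
  for (size_t i = 0; i < m; ++i) dA(i, y[i]) -= 1.0;
  dA /= (double)m;
  for (int li = (int)net.layers.size() - 1; li >= 0; --li) {
    Layer& L = net.layers[li];
    switch (L.kind) {
    case SOFTMAX: {
      arma::mat dW = L.x_in.t() * dA;
      arma::vec db = arma::sum(dA, 0).t();
      arma::mat dprev = dA * L.W.t();
      nesterov_update(L.W, L.vW, dW, lr, mom);
      nesterov_update(L.b, L.vb, db, lr, mom);
      dA = std::move(dprev);
      break;
    }
    case FULL: {
      relu_mask(dA, L.pre);
      arma::mat dW = L.x_in.t() * dA;
      arma::mat dprev = dA * L.W.t();
      if (L.has_bias) {
        arma::vec db = arma::sum(dA, 0).t();
        nesterov_update(L.b, L.vb, db, lr, mom);
      }
      nesterov_update(L.W, L.vW, dW, lr, mom);
      dA = std::move(dprev);
      break;
    }
    case NORM: {
      const size_t HW = (size_t)L.in.h * L.in.w;
      const int C = L.in.c;
      const size_t blk = HW * dA.n_rows;
      arma::vec dgamma(C), dbeta(C);
      arma::mat dX(dA.n_rows, dA.n_cols);
      for (int c = 0; c < C; ++c) {
        const double* dy = dA.memptr() + (size_t)c * blk;
        const double* xh = L.xhat.memptr() + (size_t)c * blk;
        double* dx = dX.memptr() + (size_t)c * blk;
        double sg = 0, sb = 0;
        for (size_t j = 0; j < blk; ++j) {
          sg += dy[j] * xh[j];
          sb += dy[j];
        }
        dgamma[c] = sg;
        dbeta[c] = sb;
        const double inv = L.gamma[c] / std::sqrt(L.var_[c] + net.eps);
        const double mb = sb / blk, mg = sg / blk;
        for (size_t j = 0; j < blk; ++j)
          dx[j] = inv * (dy[j] - mb - xh[j] * mg);
      }
      nesterov_update(L.gamma, L.vgamma, dgamma, lr, mom);
      nesterov_update(L.beta, L.vbeta, dbeta, lr, mom);
      dA = std::move(dX);
      break;
    }
    case POOL: {
      arma::mat dX(dA.n_rows, (size_t)L.in.size(), arma::fill::zeros);
      const size_t m2 = dA.n_rows;
      const int OH = L.in.h - 1, OW = L.in.w - 1;
      for (int c = 0; c < L.in.c; ++c) {
        const size_t coff = (size_t)c * L.in.h * L.in.w;
        const size_t ooff = (size_t)c * OH * OW;
        for (int ow = 0; ow < OW; ++ow) {
          for (int oh = 0; oh < OH; ++oh) {
            const size_t ocol = ooff + (size_t)ow * OH + oh;
            const double* dp = dA.colptr(ocol);
            const unsigned char* ip = L.poolidx.colptr(ocol);
            double* dst[4] = {
                dX.colptr(coff + (size_t)ow * L.in.h + oh),
                dX.colptr(coff + (size_t)ow * L.in.h + oh + 1),
                dX.colptr(coff + (size_t)(ow + 1) * L.in.h + oh),
                dX.colptr(coff + (size_t)(ow + 1) * L.in.h + oh + 1)};
            for (size_t j = 0; j < m2; ++j) dst[ip[j]][j] += dp[j];
          }
        }
      }
      dA = std::move(dX);
      break;
    }
    case CONV: {
      relu_mask(dA, L.pre);
      // view dA as the gemm output shape (m*OH*OW x out_c)
      arma::mat dO(dA.memptr(), L.colbuf.n_rows, L.W.n_cols, false, true);
      arma::mat dW = L.colbuf.t() * dO;
      if (li == 0) {  // no gradient needed w.r.t. the input patches
        nesterov_update(L.W, L.vW, dW, lr, mom);
        break;
      }
      arma::mat dK = dO * L.W.t();
      nesterov_update(L.W, L.vW, dW, lr, mom);
      arma::mat dX(dA.n_rows, (size_t)L.in.size(), arma::fill::zeros);
      col2im_add(dK, L.in, dX);
      dA = std::move(dX);
      break;
    }
    }
  }
}

// ---- exported interface ----

// Glorot-uniform initialisation of a fresh network state. Layer
// descriptors: list(kind=, n_filters= (conv out channels / full units /
// softmax classes), has_bias=). Uses R's RNG so set.seed() governs
// reproducibility.
// [[Rcpp::export]]
List cpp_init_net(List layers, int patch_size, double epsilon,
                  double bn_momentum) {
  Net net;
  net.patch = patch_size;
  net.eps = epsilon;
  net.bn_momentum = bn_momentum;
  Shape cur{1, patch_size, patch_size};
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    Layer L;
    L.kind = kind_code(as<std::string>(l["kind"]));
    if (L.kind == CONV) {
      int out_c = as<int>(l["n_filters"]);
      int fan_in = cur.c * 9, fan_out = out_c * 9;
      double lim = std::sqrt(6.0 / (fan_in + fan_out));
      L.W.set_size((size_t)cur.c * 9, out_c);
      for (auto& v : L.W) v = R::runif(-lim, lim);
      L.vW.zeros(L.W.n_rows, L.W.n_cols);
      cur = Shape{out_c, cur.h - 2, cur.w - 2};
    } else if (L.kind == POOL) {
      cur = Shape{cur.c, cur.h - 1, cur.w - 1};
    } else if (L.kind == NORM) {
      L.gamma.ones(cur.c);
      L.beta.zeros(cur.c);
      L.rmean.zeros(cur.c);
      L.rvar.zeros(cur.c);
      L.vgamma.zeros(cur.c);
      L.vbeta.zeros(cur.c);
    } else {  // FULL or SOFTMAX
      int units = as<int>(l["n_filters"]);
      int d = cur.size();
      double lim = std::sqrt(6.0 / (d + units));
      L.W.set_size(d, units);
      for (auto& v : L.W) v = R::runif(-lim, lim);
      L.vW.zeros(d, units);
      L.has_bias = as<bool>(l["has_bias"]);
      if (L.has_bias) {
        L.b.zeros(units);
        L.vb.zeros(units);
      }
      cur = Shape{units, 1, 1};
    }
    net.layers.push_back(std::move(L));
  }
  resolve_shapes(net);
  return net_to_list(net);
}

// One epoch of mini-batch SGD with Nesterov momentum over X
// (features x N, one column per sample) in the order given (1-based
// permutation). Returns the updated state and the mean per-batch loss.
// [[Rcpp::export]]
List cpp_train_epoch(List state, const arma::mat& X, const arma::ivec& y,
                     const arma::ivec& order, int batch_size, double lr,
                     double momentum) {
  tune_allocator();
  Net net = net_from_list(state);
  const int N = X.n_cols;
  double loss_sum = 0;
  int nb = 0;
  for (int start = 0; start < N; start += batch_size) {
    int end = std::min(start + batch_size, N);
    int m = end - start;
    arma::mat Xb(m, X.n_rows);
    arma::ivec yb(m);
    for (int j = 0; j < m; ++j) {
      int src = order[start + j] - 1;
      yb[j] = y[src];
      const double* xp = X.colptr(src);
      for (size_t f = 0; f < X.n_rows; ++f) Xb(j, f) = xp[f];
    }
    arma::mat P = forward(net, Xb, true, true, nullptr);
    net.bn_count += 1;
    loss_sum += batch_loss(P, yb);
    ++nb;
    backward_and_update(net, P, yb, lr, momentum);
    if (!std::isfinite(loss_sum)) break;
  }
  return List::create(_["state"] = net_to_list(net),
                      _["loss"] = loss_sum / std::max(nb, 1));
}

// Class probabilities (2 x N) in inference mode (running BN statistics).
// X has one column per sample.
// [[Rcpp::export]]
arma::mat cpp_predict(List state, const arma::mat& X, int batch_size) {
  Net net = net_from_list(state);
  const int N = X.n_cols;
  arma::mat P(2, N);
  for (int start = 0; start < N; start += batch_size) {
    int end = std::min(start + batch_size, N);
    arma::mat Xb = X.cols(start, end - 1).t();
    arma::mat Pb = forward(net, Xb, false, false, nullptr);
    P.cols(start, end - 1) = Pb.t();
  }
  return P;
}

// Mean cross-entropy of one batch (columns of X are samples) in training
// mode, without updating anything. Used for finite-difference gradient
// checks.
// [[Rcpp::export]]
double cpp_loss(List state, const arma::mat& X, const arma::ivec& y) {
  Net net = net_from_list(state);
  arma::mat P = forward(net, X.t(), true, false, nullptr);
  return batch_loss(P, y);
}

// Per-layer activations for one batch (columns of X are samples); each
// element is a samples x features matrix in the engine's activation
// layout (feature col = c*H*W + w*H + h).
// [[Rcpp::export]]
List cpp_forward_trace(List state, const arma::mat& X, bool train_mode) {
  Net net = net_from_list(state);
  std::vector<arma::mat> tr;
  forward(net, X.t(), train_mode, false, &tr);
  List out(tr.size());
  for (size_t i = 0; i < tr.size(); ++i) out[i] = tr[i];
  return out;
}

// ---- patch extraction ----

// Axial in-plane p x p neighbourhoods centred on 1-based voxel
// coordinates, zero-padded outside the volume. Returns p*p x N with
// feature row = (dy+r)*p + (dx+r) (column-major patch pixels).
// [[Rcpp::export]]
arma::mat cpp_extract_patches(const arma::cube& vol, const arma::imat& centers,
                              int patch_size) {
  const int r = patch_size / 2;
  const int N = centers.n_rows;
  arma::mat out(patch_size * patch_size, N, arma::fill::zeros);
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  for (int i = 0; i < N; ++i) {
    int cx = centers(i, 0) - 1, cy = centers(i, 1) - 1, cz = centers(i, 2) - 1;
    if (cz < 0 || cz >= nz) stop("patch centre slice out of volume");
    double* op = out.colptr(i);
    for (int dy = -r; dy <= r; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= nx) continue;
        op[(size_t)(dy + r) * patch_size + (dx + r)] = vol(xx, yy, cz);
      }
    }
  }
  return out;
}

// ---- connected components (26-connectivity) ----

// Labels foreground voxels of a logical volume; returns an integer volume
// of component ids (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int z = v / ((size_t)nx * ny);
      int rem = v % ((size_t)nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            size_t w = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
            if (mask[w] && labels[w] == 0) {
              labels[w] = cur;
              stack.push_back(w);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
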