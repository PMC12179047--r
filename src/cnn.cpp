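// Single-precision CNN engine for the U-Net-encoder slice classifier.
//
// The network is a contracting path of encoder blocks (two 3x3 "same"
// convolutions + ReLU, then 2x2 max-pooling) followed by fully connected
// layers and one sigmoid output unit.  Training is plain minibatch Adam on
// binary cross-entropy.  Everything runs in float32; convolutions are
// im2col + BLAS sgemm.  All randomness (He init, epoch shuffling) comes from
// explicit integer seeds so runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct NetShape {
  int input_size;
  std::vector<int> filters;       // channels per encoder block
  std::vector<int> dense;         // hidden dense widths (final 1-unit added)
  std::vector<int> conv_cin, conv_cout;  // per conv layer (2 per block)
  std::vector<int> conv_hw;       // spatial side at each conv layer
  std::vector<int> dense_in, dense_out;
  int flat_dim;
};

NetShape make_shape(int input_size, const std::vector<int>& filters,
                    const std::vector<int>& dense) {
  NetShape s;
  s.input_size = input_size;
  s.filters = filters;
  s.dense = dense;
  int hw = input_size, cin = 1;
  for (size_t b = 0; b < filters.size(); ++b) {
    int f = filters[b];
    s.conv_cin.push_back(cin);  s.conv_cout.push_back(f); s.conv_hw.push_back(hw);
    s.conv_cin.push_back(f);    s.conv_cout.push_back(f); s.conv_hw.push_back(hw);
    hw /= 2;
    cin = f;
  }
  s.flat_dim = cin * hw * hw;
  int din = s.flat_dim;
  for (size_t j = 0; j < dense.size(); ++j) {
    s.dense_in.push_back(din); s.dense_out.push_back(dense[j]);
    din = dense[j];
  }
  s.dense_in.push_back(din); s.dense_out.push_back(1);
  return s;
}

NetShape shape_from_cfg(const List& cfg) {
  std::vector<int> filters = as<std::vector<int>>(cfg["filters"]);
  std::vector<int> dense = as<std::vector<int>>(cfg["dense"]);
  return make_shape(as<int>(cfg["input_size"]), filters, dense);
}

struct Params {
  std::vector<fmat> Wc; std::vector<fvec> bc;  // conv: (cout x 9*cin)
  std::vector<fmat> Wd; std::vector<fvec> bd;  // dense: (out x in)
};

Params params_from_list(const List& w, const NetShape& s) {
  Params p;
  for (size_t l = 0; l < s.conv_cin.size(); ++l) {
    p.Wc.push_back(arma::conv_to<fmat>::from(
        as<arma::mat>(w["conv" + std::to_string(l + 1) + "_W"])));
    p.bc.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>(w["conv" + std::to_string(l + 1) + "_b"])));
  }
  for (size_t l = 0; l < s.dense_in.size(); ++l) {
    p.Wd.push_back(arma::conv_to<fmat>::from(
        as<arma::mat>(w["dense" + std::to_string(l + 1) + "_W"])));
    p.bd.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>(w["dense" + std::to_string(l + 1) + "_b"])));
  }
  return p;
}

List params_to_list(const Params& p) {
  List out;
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    out["conv" + std::to_string(l + 1) + "_W"] =
        wrap(arma::conv_to<arma::mat>::from(p.Wc[l]));
    out["conv" + std::to_string(l + 1) + "_b"] =
        wrap(arma::conv_to<arma::vec>::from(p.bc[l]));
  }
  for (size_t l = 0; l < p.Wd.size(); ++l) {
    out["dense" + std::to_string(l + 1) + "_W"] =
        wrap(arma::conv_to<arma::mat>::from(p.Wd[l]));
    out["dense" + std::to_string(l + 1) + "_b"] =
        wrap(arma::conv_to<arma::vec>::from(p.bd[l]));
  }
  return out;
}

// Activations for a batch of B images live in an fmat A of size
// (C, B*H*W); column index = b*H*W + x*H + y (column-major within image).
// im2col rows are ordered offset-major (r = k*C + c) so that each of the 9
// kernel offsets contributes one contiguous C-float block per column; the
// weight matrices use the matching column order throughout.

// im2col for 3x3 "same" (zero-padded) convolution over the whole batch.
void im2col3(const fmat& A, int C, int B, int H, fmat& X) {
  const int HW = H * H;
  X.set_size(9 * C, (size_t)B * HW);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * HW;
    for (int x = 0; x < H; ++x) {
      for (int y = 0; y < H; ++y) {
        float* dst = X.colptr(base + (size_t)x * H + y);
        for (int k = 0; k < 9; ++k) {
          const int dy = k % 3 - 1, dx = k / 3 - 1;
          const int xs = x + dx, ys = y + dy;
          if (xs < 0 || xs >= H || ys < 0 || ys >= H) {
            std::fill(dst + (size_t)k * C, dst + (size_t)(k + 1) * C, 0.0f);
          } else {
            const float* src = A.colptr(base + (size_t)xs * H + ys);
            std::copy(src, src + C, dst + (size_t)k * C);
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col3
void col2im3(const fmat& Xg, int C, int B, int H, fmat& dA) {
  const int HW = H * H;
  dA.zeros(C, (size_t)B * HW);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * HW;
    for (int x = 0; x < H; ++x) {
      for (int y = 0; y < H; ++y) {
        const float* src = Xg.colptr(base + (size_t)x * H + y);
        for (int k = 0; k < 9; ++k) {
          const int dy = k % 3 - 1, dx = k / 3 - 1;
          const int xs = x + dx, ys = y + dy;
          if (xs < 0 || xs >= H || ys < 0 || ys >= H) continue;
          float* dst = dA.colptr(base + (size_t)xs * H + ys);
          const float* s = src + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
}

// 2x2 max-pool, stride 2.  A: (C, B*H*H) -> P: (C, B*h*h), h = H/2.
// argmax stores the source column index (per channel row) for backward.
void maxpool2(const fmat& A, int C, int B, int H, fmat& P, arma::umat& argmax) {
  const int h = H / 2, HW = H * H, hw = h * h;
  P.set_size(C, (size_t)B * hw);
  argmax.set_size(C, (size_t)B * hw);
  for (int b = 0; b < B; ++b) {
    const size_t ibase = (size_t)b * HW, obase = (size_t)b * hw;
    for (int ox = 0; ox < h; ++ox) {
      for (int oy = 0; oy < h; ++oy) {
        const size_t ocol = obase + (size_t)ox * h + oy;
        const size_t c00 = ibase + (size_t)(2 * ox) * H + 2 * oy;
        const size_t cands[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        const float* s0 = A.colptr(cands[0]);
        const float* s1 = A.colptr(cands[1]);
        const float* s2 = A.colptr(cands[2]);
        const float* s3 = A.colptr(cands[3]);
        float* dst = P.colptr(ocol);
        arma::uword* am = argmax.colptr(ocol);
        for (int c = 0; c < C; ++c) {
          float best = s0[c]; size_t bi = cands[0];
          if (s1[c] > best) { best = s1[c]; bi = cands[1]; }
          if (s2[c] > best) { best = s2[c]; bi = cands[2]; }
          if (s3[c] > best) { best = s3[c]; bi = cands[3]; }
          dst[c] = best; am[c] = bi;
        }
      }
    }
  }
}

// Persistent buffers reused across minibatches: each holds one layer's
// im2col matrix, activation or gradient, so no large allocation happens
// after the first batch of an epoch.
struct Workspace {
  std::vector<fmat> conv_in_cols;   // im2col input of each conv layer
  std::vector<fmat> conv_out;       // post-ReLU conv activations
  std::vector<fmat> pool_out;
  std::vector<arma::umat> pool_arg;
  std::vector<fmat> dense_in;       // input to each dense layer
  fvec prob;
  // backward scratch
  std::vector<fmat> dconv;          // per-block gradient buffers
  std::vector<fmat> dcols;          // per-conv-layer col gradients

  explicit Workspace(const NetShape& s) {
    conv_in_cols.resize(s.conv_cin.size());
    conv_out.resize(s.conv_cin.size());
    pool_out.resize(s.filters.size());
    pool_arg.resize(s.filters.size());
    dense_in.resize(s.dense_in.size());
    dconv.resize(s.filters.size());
    dcols.resize(s.conv_cin.size());
  }
};

// forward pass for image batch (already laid out as (1, B*H*W))
void forward(const Params& p, const NetShape& s, const fmat& input, int B,
             Workspace& ws, fvec& prob) {
  const int nb = (int)s.filters.size();
  const fmat* A = &input;
  int lc = 0;
  for (int b = 0; b < nb; ++b) {
    for (int j = 0; j < 2; ++j, ++lc) {
      fmat& X = ws.conv_in_cols[lc];
      im2col3(*A, s.conv_cin[lc], B, s.conv_hw[lc], X);
      fmat& Y = ws.conv_out[lc];
      Y = p.Wc[lc] * X;
      Y.each_col() += p.bc[lc];
      Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      A = &Y;
    }
    maxpool2(*A, s.filters[b], B, s.conv_hw[lc - 1], ws.pool_out[b],
             ws.pool_arg[b]);
    A = &ws.pool_out[b];
  }
  // flatten: feature f = sp*C + c (contiguous channel blocks)
  const int C = s.filters[nb - 1], hw = s.flat_dim / C;
  fmat& D0 = ws.dense_in[0];
  D0.set_size(s.flat_dim, B);
  for (int b = 0; b < B; ++b) {
    float* dst = D0.colptr(b);
    const float* src = A->colptr((size_t)b * hw);
    std::copy(src, src + (size_t)hw * C, dst);
  }
  const int nd = (int)s.dense_in.size();
  for (int l = 0; l < nd; ++l) {
    fmat Z = p.Wd[l] * ws.dense_in[l];
    Z.each_col() += p.bd[l];
    if (l < nd - 1) {
      Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      ws.dense_in[l + 1] = std::move(Z);
    } else {
      prob = 1.0f / (1.0f + arma::exp(-Z.row(0).t()));
    }
  }
  ws.prob = prob;
}

double bce_loss(const fvec& prob, const fvec& y) {
  const float eps = 1e-7f;
  double s = 0.0;
  for (arma::uword i = 0; i < prob.n_elem; ++i) {
    float pcl = std::min(std::max(prob[i], eps), 1.0f - eps);
    s += -(y[i] * std::log(pcl) + (1.0f - y[i]) * std::log(1.0f - pcl));
  }
  return s / prob.n_elem;
}

void backward(const Params& p, const NetShape& s, Workspace& ws,
              const fvec& y, int B, Params& grad) {
  const int nd = (int)s.dense_in.size();
  const int nb = (int)s.filters.size();
  // output layer: d(BCE)/dz = (p - y)/B with sigmoid z
  fmat dZ(1, B);
  for (int b = 0; b < B; ++b) dZ(0, b) = (ws.prob[b] - y[b]) / B;
  fmat dD;
  for (int l = nd - 1; l >= 0; --l) {
    grad.Wd[l] = dZ * ws.dense_in[l].t();
    grad.bd[l] = arma::sum(dZ, 1);
    dD = p.Wd[l].t() * dZ;
    if (l > 0) {
      // ReLU mask of that layer's input (post-activation of previous layer)
      dZ = dD;
      const fmat& act = ws.dense_in[l];
      float* g = dZ.memptr();
      const float* a = act.memptr();
      for (arma::uword i = 0; i < dZ.n_elem; ++i)
        if (a[i] <= 0.0f) g[i] = 0.0f;
    }
  }
  // unflatten (feature f = sp*C + c)
  const int C = s.filters[nb - 1], hw = s.flat_dim / C;
  fmat dA(C, (size_t)B * hw);
  for (int b = 0; b < B; ++b) {
    const float* src = dD.colptr(b);
    float* dst = dA.colptr((size_t)b * hw);
    std::copy(src, src + (size_t)hw * C, dst);
  }
  for (int b = nb - 1; b >= 0; --b) {
    // unpool
    const int lc = 2 * b + 1;                  // last conv layer of block b
    const int H = s.conv_hw[lc];
    fmat& dConv = ws.dconv[b];
    dConv.zeros(s.conv_cout[lc], (size_t)B * H * H);
    const arma::umat& am = ws.pool_arg[b];
    const fmat& src = (b == nb - 1) ? dA : ws.dconv[b + 1];
    for (arma::uword j = 0; j < am.n_cols; ++j)
      for (arma::uword c = 0; c < am.n_rows; ++c)
        dConv(c, am(c, j)) += src(c, j);
    // two conv layers, reverse order
    for (int j = 1; j >= 0; --j) {
      const int l = 2 * b + j;
      {
        float* g = dConv.memptr();
        const float* a = ws.conv_out[l].memptr();
        for (arma::uword i = 0; i < dConv.n_elem; ++i)
          if (a[i] <= 0.0f) g[i] = 0.0f;
      }
      grad.Wc[l] = dConv * ws.conv_in_cols[l].t();
      grad.bc[l] = arma::sum(dConv, 1);
      if (l > 0) {
        ws.dcols[l] = p.Wc[l].t() * dConv;
        col2im3(ws.dcols[l], s.conv_cin[l], B, s.conv_hw[l], dConv);
      }
    }
  }
}

void adam_update(fmat& W, fmat& m, fmat& v, const fmat& g, double lr,
                 double b1, double b2, double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  W -= arma::conv_to<fmat>::from(
      (lr / c1) * m / (arma::sqrt(v / c2) + eps));
}

fmat batch_input(const arma::fcube& data, const std::vector<int>& idx,
                 size_t lo, size_t hi) {
  const int H = data.n_rows;
  const size_t HW = (size_t)H * H, B = hi - lo;
  fmat A(1, B * HW);
  for (size_t b = 0; b < B; ++b)
    std::copy(data.slice_memptr(idx[lo + b]),
              data.slice_memptr(idx[lo + b]) + HW, A.colptr(b * HW));
  return A;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_make_dataset(NumericVector arr) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) stop("expected a 3-d array (H, W, N)");
  arma::fcube* d = new arma::fcube(dim[0], dim[1], dim[2]);
  std::copy(arr.begin(), arr.end(), d->memptr());
  XPtr<arma::fcube> ptr(d, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_dataset_size(SEXP xptr) {
  XPtr<arma::fcube> d(xptr);
  return d->n_slices;
}

// [[Rcpp::export]]
List cpp_init_weights(List cfg, int seed) {
  NetShape s = shape_from_cfg(cfg);
  std::mt19937 rng((unsigned)seed);
  Params p;
  for (size_t l = 0; l < s.conv_cin.size(); ++l) {
    const int fan_in = 9 * s.conv_cin[l];
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
    fmat W(s.conv_cout[l], fan_in);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = nd(rng);
    p.Wc.push_back(W);
    p.bc.push_back(fvec(s.conv_cout[l], arma::fill::zeros));
  }
  for (size_t l = 0; l < s.dense_in.size(); ++l) {
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / s.dense_in[l]));
    fmat W(s.dense_out[l], s.dense_in[l]);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = nd(rng);
    p.Wd.push_back(W);
    p.bd.push_back(fvec(s.dense_out[l], arma::fill::zeros));
  }
  return params_to_list(p);
}

// One full epoch of shuffled minibatch Adam.  Returns updated weights,
// Adam moments, step counter and the mean training loss over minibatches.
// [[Rcpp::export]]
List cpp_train_epoch(List weights, List adam_m, List adam_v, SEXP xptr,
                     NumericVector y, List cfg, double lr, double beta1,
                     double beta2, double adam_eps, int batch_size,
                     int shuffle_seed, int t0) {
  NetShape s = shape_from_cfg(cfg);
  Params p = params_from_list(weights, s);
  XPtr<arma::fcube> data(xptr);
  const int N = data->n_slices;
  if (y.size() != N) stop("label length does not match dataset");

  Params m, v;
  bool fresh = adam_m.size() == 0;
  if (fresh) {
    for (auto& W : p.Wc) { m.Wc.push_back(fmat(arma::size(W), arma::fill::zeros));
                           v.Wc.push_back(fmat(arma::size(W), arma::fill::zeros)); }
    for (auto& b : p.bc) { m.bc.push_back(fvec(arma::size(b), arma::fill::zeros));
                           v.bc.push_back(fvec(arma::size(b), arma::fill::zeros)); }
    for (auto& W : p.Wd) { m.Wd.push_back(fmat(arma::size(W), arma::fill::zeros));
                           v.Wd.push_back(fmat(arma::size(W), arma::fill::zeros)); }
    for (auto& b : p.bd) { m.bd.push_back(fvec(arma::size(b), arma::fill::zeros));
                           v.bd.push_back(fvec(arma::size(b), arma::fill::zeros)); }
  } else {
    m = params_from_list(adam_m, s);
    v = params_from_list(adam_v, s);
  }

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::mt19937 rng((unsigned)shuffle_seed);
  std::shuffle(idx.begin(), idx.end(), rng);

  int t = t0;
  double loss_sum = 0.0; int n_batches = 0;
  Workspace ws(s);
  for (int lo = 0; lo < N; lo += batch_size) {
    const int hi = std::min(N, lo + batch_size);
    const int B = hi - lo;
    fmat input = batch_input(*data, idx, lo, hi);
    fvec yb(B);
    for (int b = 0; b < B; ++b) yb[b] = (float)y[idx[lo + b]];
    fvec prob;
    forward(p, s, input, B, ws, prob);
    loss_sum += bce_loss(prob, yb); ++n_batches;
    Params g;
    g.Wc.resize(p.Wc.size()); g.bc.resize(p.bc.size());
    g.Wd.resize(p.Wd.size()); g.bd.resize(p.bd.size());
    backward(p, s, ws, yb, B, g);
    ++t;
    for (size_t l = 0; l < p.Wc.size(); ++l) {
      adam_update(p.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], lr, beta1, beta2, adam_eps, t);
      fmat bm(m.bc[l]), bv(v.bc[l]), bw(p.bc[l]), bg(g.bc[l]);
      adam_update(bw, bm, bv, bg, lr, beta1, beta2, adam_eps, t);
      p.bc[l] = bw.col(0); m.bc[l] = bm.col(0); v.bc[l] = bv.col(0);
    }
    for (size_t l = 0; l < p.Wd.size(); ++l) {
      adam_update(p.Wd[l], m.Wd[l], v.Wd[l], g.Wd[l], lr, beta1, beta2, adam_eps, t);
      fmat bm(m.bd[l]), bv(v.bd[l]), bw(p.bd[l]), bg(g.bd[l]);
      adam_update(bw, bm, bv, bg, lr, beta1, beta2, adam_eps, t);
      p.bd[l] = bw.col(0); m.bd[l] = bm.col(0); v.bd[l] = bv.col(0);
    }
  }

  return List::create(_["weights"] = params_to_list(p),
                      _["adam_m"] = params_to_list(m),
                      _["adam_v"] = params_to_list(v),
                      _["t"] = t,
                      _["train_loss"] = loss_sum / std::max(1, n_batches));
}

// [[Rcpp::export]]
NumericVector cpp_predict_scores(List weights, SEXP xptr, List cfg,
                                 int batch_size) {
  NetShape s = shape_from_cfg(cfg);
  Params p = params_from_list(weights, s);
  XPtr<arma::fcube> data(xptr);
  const int N = data->n_slices;
  NumericVector out(N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  Workspace ws(s);
  for (int lo = 0; lo < N; lo += batch_size) {
    const int hi = std::min(N, lo + batch_size);
    fmat input = batch_input(*data, idx, lo, hi);
    fvec prob;
    forward(p, s, input, hi - lo, ws, prob);
    for (int b = lo; b < hi; ++b) out[b] = prob[b - lo];
  }
  return out;
}

// round doubles through IEEE single precision (float32 storage contract)
// [[Rcpp::export]]
NumericVector cpp_round_float32(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  out.attr("dim") = x.attr("dim");
  return out;
}
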