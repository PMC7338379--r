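// Minimal CNN engine: valid 3x3 convolutions + ReLU + 2x2 max-pool blocks,
// a ReLU dense layer with inverted dropout, and a softmax head, trained by
// mini-batch Adam on categorical cross-entropy. Layout conventions:
//  - images are column-major (height fastest), one channel cube per image
//  - conv weights: (c_out x kh*kw*c_in), row index c*kh*kw + kj*kw + ki
//  - flatten follows arma::vectorise of the (h, w, c) cube
// The R side owns shape inference and parameter accounting; both sides must
// agree or cnn_check_weights() aborts.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Arch {
  int in_h, in_w, in_c;
  arma::ivec filters;   // conv filter counts, in order
  int kernel;           // square, 3 by default
  int pool;             // square, 2 by default
  int dense_units;
  int n_classes;
};

Arch read_arch(const List& arch) {
  Arch a;
  IntegerVector input = arch["input"];
  a.in_h = input[0];
  a.in_w = input[1];
  a.in_c = input[2];
  a.filters = as<arma::ivec>(arch["conv_filters"]);
  a.kernel = as<int>(arch["kernel"]);
  a.pool = as<int>(arch["pool"]);
  a.dense_units = as<int>(arch["dense_units"]);
  a.n_classes = as<int>(arch["n_classes"]);
  if (a.kernel < 1 || a.pool < 1) stop("kernel and pool sizes must be positive");
  return a;
}

// conv output: in - k + 1 (valid); pool output: floor(in / pool)
void conv_stack_shapes(const Arch& a, std::vector<int>& hs, std::vector<int>& ws,
                       std::vector<int>& cs) {
  int h = a.in_h, w = a.in_w, c = a.in_c;
  hs.push_back(h); ws.push_back(w); cs.push_back(c);
  for (arma::uword l = 0; l < a.filters.n_elem; ++l) {
    h = h - a.kernel + 1;
    w = w - a.kernel + 1;
    if (h < 1 || w < 1) stop("network too deep for input: conv output collapsed");
    c = a.filters[l];
    h = h / a.pool;
    w = w / a.pool;
    if (h < 1 || w < 1) stop("network too deep for input: pool output collapsed");
    hs.push_back(h); ws.push_back(w); cs.push_back(c);
  }
}

struct Weights {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  arma::mat Wd1, Wd2;
  arma::vec bd1, bd2;
};

Weights read_weights(const List& wl, const Arch& a) {
  Weights w;
  int nconv = a.filters.n_elem;
  if (wl.size() != 2 * (nconv + 2))
    stop("weight list has %d elements, expected %d", wl.size(), 2 * (nconv + 2));
  for (int l = 0; l < nconv; ++l) {
    w.Wc.push_back(as<arma::mat>(wl[2 * l]));
    w.bc.push_back(as<arma::vec>(wl[2 * l + 1]));
  }
  w.Wd1 = as<arma::mat>(wl[2 * nconv]);
  w.bd1 = as<arma::vec>(wl[2 * nconv + 1]);
  w.Wd2 = as<arma::mat>(wl[2 * nconv + 2]);
  w.bd2 = as<arma::vec>(wl[2 * nconv + 3]);
  return w;
}

List write_weights(const Weights& w) {
  int nconv = w.Wc.size();
  List out(2 * (nconv + 2));
  for (int l = 0; l < nconv; ++l) {
    out[2 * l] = w.Wc[l];
    out[2 * l + 1] = w.bc[l];
  }
  out[2 * nconv] = w.Wd1;
  out[2 * nconv + 1] = w.bd1;
  out[2 * nconv + 2] = w.Wd2;
  out[2 * nconv + 3] = w.bd2;
  return out;
}

void check_weights(const Weights& w, const Arch& a) {
  std::vector<int> hs, ws, cs;
  conv_stack_shapes(a, hs, ws, cs);
  int k2 = a.kernel * a.kernel;
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    int cin = cs[l], cout = a.filters[l];
    if ((int)w.Wc[l].n_rows != cout || (int)w.Wc[l].n_cols != k2 * cin)
      stop("conv weight %d has wrong shape", (int)l + 1);
    if ((int)w.bc[l].n_elem != cout) stop("conv bias %d has wrong length", (int)l + 1);
  }
  int flat = hs.back() * ws.back() * cs.back();
  if ((int)w.Wd1.n_cols != flat || (int)w.Wd1.n_rows != a.dense_units)
    stop("dense weight 1 has wrong shape (expected %d x %d)", a.dense_units, flat);
  if ((int)w.Wd2.n_cols != a.dense_units || (int)w.Wd2.n_rows != a.n_classes)
    stop("dense weight 2 has wrong shape");
}

// im2col for valid k x k convolution: (k*k*cin) x (oh*ow), column = j*oh + i
arma::mat im2col(const arma::cube& A, int k) {
  int oh = A.n_rows - k + 1, ow = A.n_cols - k + 1, cin = A.n_slices;
  arma::mat P(k * k * cin, oh * ow);
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int row = c * k * k + kj * k + ki;
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i)
            P(row, (arma::uword)j * oh + i) = A(i + ki, j + kj, c);
      }
  return P;
}

void col2im_add(arma::cube& dA, const arma::mat& dP, int k) {
  int oh = dA.n_rows - k + 1, ow = dA.n_cols - k + 1, cin = dA.n_slices;
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int row = c * k * k + kj * k + ki;
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i)
            dA(i + ki, j + kj, c) += dP(row, (arma::uword)j * oh + i);
      }
}

// 2x2 (or p x p) max pooling with argmax bookkeeping for the backward pass
arma::cube maxpool(const arma::cube& A, int p, arma::ucube& argmax) {
  int ph = A.n_rows / p, pw = A.n_cols / p, c = A.n_slices;
  arma::cube out(ph, pw, c);
  argmax.set_size(ph, pw, c);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < pw; ++j)
      for (int i = 0; i < ph; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < p; ++dj)
          for (int di = 0; di < p; ++di) {
            double v = A(i * p + di, j * p + dj, s);
            if (v > best) {
              best = v;
              bi = (arma::uword)(j * p + dj) * A.n_rows + (i * p + di);
            }
          }
        out(i, j, s) = best;
        argmax(i, j, s) = bi;
      }
  return out;
}

struct ForwardCache {
  std::vector<arma::mat> P;       // im2col patches per conv layer
  std::vector<arma::cube> conv;   // post-ReLU conv activations
  std::vector<arma::cube> pooled; // post-pool activations
  std::vector<arma::ucube> argmax;
  arma::vec flat, pre1, h1, drop_mask;
  arma::vec probs;
};

arma::vec softmax(arma::vec z) {
  z -= z.max();
  arma::vec e = arma::exp(z);
  return e / arma::accu(e);
}

// Forward pass for one image; `train` enables dropout (inverted scaling).
void forward_one(const arma::cube& img, const Weights& w, const Arch& a,
                 double dropout_rate, bool train, std::mt19937* rng,
                 ForwardCache& fc) {
  int nconv = w.Wc.size();
  arma::cube A = img;
  fc.P.clear(); fc.conv.clear(); fc.pooled.clear(); fc.argmax.clear();
  for (int l = 0; l < nconv; ++l) {
    arma::mat P = im2col(A, a.kernel);
    arma::mat Z = w.Wc[l] * P;
    Z.each_col() += w.bc[l];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    int oh = A.n_rows - a.kernel + 1, ow = A.n_cols - a.kernel + 1;
    arma::cube C(oh, ow, w.Wc[l].n_rows);
    for (arma::uword c = 0; c < C.n_slices; ++c)
      C.slice(c) = arma::reshape(Z.row(c).t(), oh, ow);
    arma::ucube am;
    arma::cube Pd = maxpool(C, a.pool, am);
    fc.P.push_back(std::move(P));
    fc.conv.push_back(std::move(C));
    fc.argmax.push_back(std::move(am));
    fc.pooled.push_back(Pd);
    A = std::move(Pd);
  }
  fc.flat = arma::vectorise(A);
  fc.pre1 = w.Wd1 * fc.flat + w.bd1;
  fc.h1 = arma::clamp(fc.pre1, 0.0, arma::datum::inf);
  if (train && dropout_rate > 0.0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    fc.drop_mask.set_size(fc.h1.n_elem);
    for (arma::uword i = 0; i < fc.h1.n_elem; ++i)
      fc.drop_mask[i] = unif(*rng) >= dropout_rate ? 1.0 / (1.0 - dropout_rate) : 0.0;
    fc.h1 %= fc.drop_mask;
  } else {
    fc.drop_mask.ones(fc.h1.n_elem);
  }
  fc.probs = softmax(w.Wd2 * fc.h1 + w.bd2);
}

struct Grads {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  arma::mat Wd1, Wd2;
  arma::vec bd1, bd2;
  void zero_like(const Weights& w) {
    Wc.clear(); bc.clear();
    for (auto& m : w.Wc) Wc.push_back(arma::zeros<arma::mat>(m.n_rows, m.n_cols));
    for (auto& v : w.bc) bc.push_back(arma::zeros<arma::vec>(v.n_elem));
    Wd1.zeros(w.Wd1.n_rows, w.Wd1.n_cols);
    Wd2.zeros(w.Wd2.n_rows, w.Wd2.n_cols);
    bd1.zeros(w.bd1.n_elem);
    bd2.zeros(w.bd2.n_elem);
  }
};

void backward_one(const arma::cube& img, int label, const Weights& w,
                  const Arch& a, const ForwardCache& fc, Grads& g) {
  int nconv = w.Wc.size();
  arma::vec dlogit = fc.probs;
  dlogit[label] -= 1.0;
  g.Wd2 += dlogit * fc.h1.t();
  g.bd2 += dlogit;
  arma::vec dh1 = w.Wd2.t() * dlogit;
  dh1 %= fc.drop_mask;                       // dropout (already holds 1/(1-p))
  dh1.elem(arma::find(fc.pre1 <= 0.0)).zeros();
  g.Wd1 += dh1 * fc.flat.t();
  g.bd1 += dh1;
  arma::vec dflat = w.Wd1.t() * dh1;

  const arma::cube& last = fc.pooled[nconv - 1];
  arma::cube dA(last.n_rows, last.n_cols, last.n_slices);
  std::memcpy(dA.memptr(), dflat.memptr(), sizeof(double) * dflat.n_elem);

  for (int l = nconv - 1; l >= 0; --l) {
    const arma::cube& C = fc.conv[l];
    arma::cube dC(C.n_rows, C.n_cols, C.n_slices, arma::fill::zeros);
    const arma::ucube& am = fc.argmax[l];
    for (arma::uword s = 0; s < dA.n_slices; ++s)
      for (arma::uword j = 0; j < dA.n_cols; ++j)
        for (arma::uword i = 0; i < dA.n_rows; ++i)
          dC.slice(s)[am(i, j, s)] += dA(i, j, s);
    // ReLU mask (post-activation > 0)
    dC.elem(arma::find(C <= 0.0)).zeros();
    int oh = C.n_rows, ow = C.n_cols;
    arma::mat dZ(C.n_slices, (arma::uword)oh * ow);
    for (arma::uword c = 0; c < C.n_slices; ++c)
      dZ.row(c) = arma::vectorise(dC.slice(c)).t();
    g.Wc[l] += dZ * fc.P[l].t();
    g.bc[l] += arma::sum(dZ, 1);
    if (l > 0) {
      const arma::cube& prev = fc.pooled[l - 1];
      arma::mat dP = w.Wc[l].t() * dZ;
      arma::cube dprev(prev.n_rows, prev.n_cols, prev.n_slices, arma::fill::zeros);
      col2im_add(dprev, dP, a.kernel);
      dA = std::move(dprev);
    }
  }
}

arma::cube image_slice(const arma::cube& X, int idx, int h, int w, int c) {
  // X stores images as (h, w*c, n)? No: X is (h, w, n*c) flattened by caller.
  // Caller passes a 4-d array collapsed to (h, w, c * n); channel-major per image.
  arma::cube img(h, w, c);
  for (int s = 0; s < c; ++s) img.slice(s) = X.slice(idx * c + s);
  return img;
}

void adam_update(arma::mat& W, arma::mat& m, arma::mat& v, const arma::mat& g,
                 double lr, double b1, double b2, double eps, int t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * arma::square(g);
  arma::mat mh = m / (1 - std::pow(b1, t));
  arma::mat vh = v / (1 - std::pow(b2, t));
  W -= lr * mh / (arma::sqrt(vh) + eps);
}

void adam_update(arma::vec& W, arma::vec& m, arma::vec& v, const arma::vec& g,
                 double lr, double b1, double b2, double eps, int t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * arma::square(g);
  arma::vec mh = m / (1 - std::pow(b1, t));
  arma::vec vh = v / (1 - std::pow(b2, t));
  W -= lr * mh / (arma::sqrt(vh) + eps);
}

} // namespace

// [[Rcpp::export]]
arma::mat cnn_predict_proba_cpp(List weights, List arch, arma::cube X) {
  Arch a = read_arch(arch);
  Weights w = read_weights(weights, a);
  check_weights(w, a);
  if ((int)X.n_rows != a.in_h || (int)X.n_cols != a.in_w)
    stop("image raster is %dx%d but the model expects %dx%d",
         (int)X.n_rows, (int)X.n_cols, a.in_h, a.in_w);
  if (X.n_slices % a.in_c != 0) stop("slice count not a multiple of channels");
  int n = X.n_slices / a.in_c;
  arma::mat out(n, a.n_classes);
  ForwardCache fc;
  for (int i = 0; i < n; ++i) {
    arma::cube img = image_slice(X, i, a.in_h, a.in_w, a.in_c);
    forward_one(img, w, a, 0.0, false, nullptr, fc);
    out.row(i) = fc.probs.t();
  }
  return out;
}

// One epoch of shuffled mini-batch Adam. Returns updated weights, Adam state,
// step counter, mean cross-entropy loss and (dropout-active) training accuracy.
// [[Rcpp::export]]
List cnn_train_epoch_cpp(List weights, List m_state, List v_state, int t0,
                         List arch, arma::cube X, IntegerVector y,
                         double lr, double beta1, double beta2, double eps,
                         double dropout_rate, int batch_size, int seed) {
  Arch a = read_arch(arch);
  Weights w = read_weights(weights, a);
  check_weights(w, a);
  Weights m = read_weights(m_state, a);
  Weights v = read_weights(v_state, a);
  int n = X.n_slices / a.in_c;
  if (n != y.size()) stop("label count does not match image count");
  if (n == 0) stop("empty training set");
  if (batch_size < 1) stop("batch_size must be >= 1");

  std::mt19937 rng(seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);

  Grads g;
  ForwardCache fc;
  double loss = 0.0;
  int correct = 0, t = t0;
  for (int start = 0; start < n; start += batch_size) {
    int stop_ = std::min(start + batch_size, n);
    int bn = stop_ - start;
    g.zero_like(w);
    for (int b = start; b < stop_; ++b) {
      int idx = order[b];
      arma::cube img = image_slice(X, idx, a.in_h, a.in_w, a.in_c);
      forward_one(img, w, a, dropout_rate, true, &rng, fc);
      int lab = y[idx];
      if (lab < 0 || lab >= a.n_classes) stop("label out of range");
      loss += -std::log(std::max(fc.probs[lab], 1e-12));
      if ((int)fc.probs.index_max() == lab) ++correct;
      backward_one(img, lab, w, a, fc, g);
    }
    double inv = 1.0 / bn;
    for (auto& gm : g.Wc) gm *= inv;
    for (auto& gv : g.bc) gv *= inv;
    g.Wd1 *= inv; g.bd1 *= inv; g.Wd2 *= inv; g.bd2 *= inv;
    ++t;
    for (size_t l = 0; l < w.Wc.size(); ++l) {
      adam_update(w.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], lr, beta1, beta2, eps, t);
      adam_update(w.bc[l], m.bc[l], v.bc[l], g.bc[l], lr, beta1, beta2, eps, t);
    }
    adam_update(w.Wd1, m.Wd1, v.Wd1, g.Wd1, lr, beta1, beta2, eps, t);
    adam_update(w.bd1, m.bd1, v.bd1, g.bd1, lr, beta1, beta2, eps, t);
    adam_update(w.Wd2, m.Wd2, v.Wd2, g.Wd2, lr, beta1, beta2, eps, t);
    adam_update(w.bd2, m.bd2, v.bd2, g.bd2, lr, beta1, beta2, eps, t);
  }
  return List::create(
      _["weights"] = write_weights(w), _["m"] = write_weights(m),
      _["v"] = write_weights(v), _["t"] = t,
      _["loss"] = loss / n, _["train_acc"] = (double)correct / n);
}
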