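// Fully-convolutional recognizer core: im2col convolutions over
// (time x mel) maps with batch normalization and ReLU, a 1-D convolutional
// head emitting 6 class logits + 1 age channel per 240 ms step, and the
// corresponding backward pass. Activations are stored as C x (N*T*M)
// matrices with column index ((n*T + t)*M + m); output sizes follow the
// floor rule T_out = floor(T / stride), so the temporal downsampling chain
// composes to exactly floor(T / 24).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Dims { int T, M, N; };

static inline int out_len(int T, int s) { return T / s; }

// Gather 3x3 neighborhoods (zero-padded, centers at t*st, m*sm) into a
// (9*Cin) x (N*To*Mo) matrix.
static mat im2col(const mat& A, const Dims& d, int st, int sm,
                  int To, int Mo) {
  const int Cin = A.n_rows;
  mat out(9 * Cin, (size_t)d.N * To * Mo, arma::fill::zeros);
  for (int n = 0; n < d.N; ++n) {
    for (int t = 0; t < To; ++t) {
      const int tc = t * st;
      for (int m = 0; m < Mo; ++m) {
        const int mc = m * sm;
        const size_t col = ((size_t)n * To + t) * Mo + m;
        for (int dt = -1; dt <= 1; ++dt) {
          const int ti = tc + dt;
          if (ti < 0 || ti >= d.T) continue;
          for (int dm = -1; dm <= 1; ++dm) {
            const int mi = mc + dm;
            if (mi < 0 || mi >= d.M) continue;
            const size_t src = ((size_t)n * d.T + ti) * d.M + mi;
            const int k = (dt + 1) * 3 + (dm + 1);
            std::memcpy(out.colptr(col) + (size_t)k * Cin,
                        A.colptr(src), sizeof(double) * Cin);
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the transpose of im2col: accumulate column gradients back
// onto the input map.
static mat col2im(const mat& cols, int Cin, const Dims& d, int st, int sm,
                  int To, int Mo) {
  mat out(Cin, (size_t)d.N * d.T * d.M, arma::fill::zeros);
  for (int n = 0; n < d.N; ++n) {
    for (int t = 0; t < To; ++t) {
      const int tc = t * st;
      for (int m = 0; m < Mo; ++m) {
        const int mc = m * sm;
        const size_t col = ((size_t)n * To + t) * Mo + m;
        for (int dt = -1; dt <= 1; ++dt) {
          const int ti = tc + dt;
          if (ti < 0 || ti >= d.T) continue;
          for (int dm = -1; dm <= 1; ++dm) {
            const int mi = mc + dm;
            if (mi < 0 || mi >= d.M) continue;
            const size_t dst = ((size_t)n * d.T + ti) * d.M + mi;
            const int k = (dt + 1) * 3 + (dm + 1);
            double* po = out.colptr(dst);
            const double* pc = cols.colptr(col) + (size_t)k * Cin;
            for (int c = 0; c < Cin; ++c) po[c] += pc[c];
          }
        }
      }
    }
  }
  return out;
}

struct LayerCache {
  mat xcol, xhat, relu_out;
  vec sigma, mu;
  Dims din, dout;
  int st, sm;
};

static const double BN_EPS = 1e-5;

// Forward through one conv+BN+ReLU layer. In training mode batch statistics
// are used and (mu, sigma) cached; in inference mode the running statistics
// stored with the layer are used.
static mat layer_forward(const List& L, const mat& A, const Dims& din,
                         bool training, LayerCache* cache) {
  const mat W = L["W"];
  const vec b = L["b"], gamma = L["gamma"], beta = L["beta"];
  const int st = as<int>(L["stride_t"]), sm = as<int>(L["stride_m"]);
  const int To = out_len(din.T, st), Mo = out_len(din.M, sm);
  const int Cin = A.n_rows;
  mat xcol = im2col(A, din, st, sm, To, Mo);
  mat Z = W * xcol;
  Z.each_col() += b;
  vec mu, var;
  if (training) {
    mu = arma::mean(Z, 1);
    var = arma::var(Z, 1 /* population */, 1);
  } else {
    mu = as<vec>(L["rmean"]);
    var = as<vec>(L["rvar"]);
  }
  vec sigma = arma::sqrt(var + BN_EPS);
  mat xhat = Z;
  xhat.each_col() -= mu;
  xhat.each_col() /= sigma;
  mat out = xhat;
  out.each_col() %= gamma;
  out.each_col() += beta;
  out = arma::clamp(out, 0.0, arma::datum::inf);
  if (cache) {
    cache->xcol = std::move(xcol);
    cache->xhat = std::move(xhat);
    cache->relu_out = out;
    cache->sigma = sigma;
    cache->mu = mu;
    cache->din = din;
    cache->dout = {To, Mo, din.N};
    cache->st = st; cache->sm = sm;
    (void)Cin;
  }
  return out;
}

// 1-D head: kernel-3 convolution over time (mel already reduced to 1).
static mat head_forward(const List& L, const mat& A, const Dims& din,
                        mat* xcol_cache) {
  const mat W = L["W"];
  const vec b = L["b"];
  Dims d1 = {din.T, 1, din.N};
  mat xcol = im2col(A, d1, 1, 1, din.T, 1);
  // drop mel-offset rows that are always zero-padding: keep dm == 0 rows
  const int Cin = A.n_rows;
  uvec keep(3 * (size_t)Cin);
  for (int dt = 0; dt < 3; ++dt)
    for (int c = 0; c < Cin; ++c)
      keep[(size_t)dt * Cin + c] = (size_t)(dt * 3 + 1) * Cin + c;
  mat xc = xcol.rows(keep);
  mat Z = W * xc;
  Z.each_col() += b;
  if (xcol_cache) *xcol_cache = std::move(xc);
  return Z;
}

static mat softmax_cols(const mat& Z) {
  mat P = Z;
  arma::rowvec mx = arma::max(Z, 0);
  P.each_row() -= mx;
  P = arma::exp(P);
  arma::rowvec s = arma::sum(P, 0);
  P.each_row() /= s;
  return P;
}

// [[Rcpp::export]]
List cpp_net_infer(List layers, List head, const arma::mat& x,
                   int n_frames, int n_mels, int n_samples) {
  Dims d = {n_frames, n_mels, n_samples};
  mat A = x;
  for (int i = 0; i < layers.size(); ++i) {
    List L = layers[i];
    Dims dn;
    A = layer_forward(L, A, d, false, nullptr);
    dn.T = out_len(d.T, as<int>(L["stride_t"]));
    dn.M = out_len(d.M, as<int>(L["stride_m"]));
    dn.N = d.N;
    d = dn;
    if (d.T < 1) return List::create(_["scores"] = mat(0, 6),
                                     _["age"] = vec());
  }
  mat Z = head_forward(head, A, d, nullptr);
  mat P = softmax_cols(Z.rows(0, 5));
  vec age = arma::log1p(arma::exp(-arma::abs(Z.row(6).t()))) +
    arma::clamp(Z.row(6).t(), 0.0, arma::datum::inf);  // softplus, stable
  return List::create(_["scores"] = P.t(), _["age"] = age,
                      _["t_out"] = d.T);
}

// Training step on a batch of equal-length examples.
// x: C=1 map, dims (T x M x N) flattened as described above.
// labels: 0-based class index per (n, t_out) as an (t_out x N) matrix.
// Returns loss components, parameter gradients, and batch BN statistics
// (for the running-average update done on the R side).
// [[Rcpp::export]]
List cpp_train_step(List layers, List head, const arma::mat& x,
                    int n_frames, int n_mels, int n_samples,
                    const arma::imat& labels, const arma::vec& ages,
                    const arma::vec& class_w, double age_w) {
  const int nl = layers.size();
  std::vector<LayerCache> caches(nl);
  Dims d = {n_frames, n_mels, n_samples};
  mat A = x;
  std::vector<Dims> dims_in(nl);
  for (int i = 0; i < nl; ++i) {
    dims_in[i] = d;
    List L = layers[i];
    A = layer_forward(L, A, d, true, &caches[i]);
    d = caches[i].dout;
  }
  mat head_xcol;
  mat Z = head_forward(head, A, d, &head_xcol);
  const int To = d.T, N = d.N;
  mat P = softmax_cols(Z.rows(0, 5));

  // ---- loss ----
  double wsum = 0.0, loss_cls = 0.0, loss_age = 0.0;
  mat dZ(7, Z.n_cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < To; ++t) {
      const size_t j = (size_t)n * To + t;
      const int y = labels(t, n);
      const double w = class_w[y];
      wsum += w;
      loss_cls += -w * std::log(std::max(P(y, j), 1e-12));
      for (int c = 0; c < 6; ++c)
        dZ(c, j) = w * (P(c, j) - (c == y ? 1.0 : 0.0));
      // softplus age head, L1 loss in days
      const double z = Z(6, j);
      const double sp = (z > 0 ? z : 0) + std::log1p(std::exp(-std::abs(z)));
      const double diff = sp - ages[n];
      loss_age += std::abs(diff);
      const double sig = 1.0 / (1.0 + std::exp(-z));
      dZ(6, j) = age_w * (diff > 0 ? 1.0 : -1.0) * sig / (double)Z.n_cols;
    }
  }
  loss_cls /= wsum;
  loss_age /= (double)Z.n_cols;
  dZ.rows(0, 5) /= wsum;

  // ---- backward: head ----
  List Lh = head;
  const mat Wh = Lh["W"];
  mat dWh = dZ * head_xcol.t();
  vec dbh = arma::sum(dZ, 1);
  mat dxc = Wh.t() * dZ;               // (3*C) x cols
  const int Ch = A.n_rows;
  mat dxcol_full(9 * Ch, dxc.n_cols, arma::fill::zeros);
  for (int dt = 0; dt < 3; ++dt)
    dxcol_full.rows((dt * 3 + 1) * Ch, (dt * 3 + 2) * Ch - 1) =
      dxc.rows(dt * Ch, (dt + 1) * Ch - 1);
  Dims dh = {d.T, 1, d.N};
  mat dA = col2im(dxcol_full, Ch, dh, 1, 1, d.T, 1);

  // ---- backward: conv stack ----
  List grads(nl);
  List bn_stats(nl);
  for (int i = nl - 1; i >= 0; --i) {
    List L = layers[i];
    LayerCache& cc = caches[i];
    const mat W = L["W"];
    const vec gamma = L["gamma"];
    // ReLU
    mat dOut = dA % (cc.relu_out > 0);
    // BN backward (batch statistics over columns)
    vec dgamma = arma::sum(dOut % cc.xhat, 1);
    vec dbeta = arma::sum(dOut, 1);
    mat dxhat = dOut;
    dxhat.each_col() %= gamma;
    vec m1 = arma::mean(dxhat, 1);
    vec m2 = arma::mean(dxhat % cc.xhat, 1);
    mat dZl = dxhat;
    dZl.each_col() -= m1;
    dZl -= cc.xhat.each_col() % m2;
    dZl.each_col() /= cc.sigma;
    // conv backward
    mat dW = dZl * cc.xcol.t();
    vec db = arma::sum(dZl, 1);
    mat dxcol = W.t() * dZl;
    const int Cin = (i == 0) ? 1 : as<mat>(as<List>(layers[i - 1])["W"]).n_rows;
    dA = col2im(dxcol, Cin, cc.din, cc.st, cc.sm, cc.dout.T, cc.dout.M);
    grads[i] = List::create(_["W"] = dW, _["b"] = db,
                            _["gamma"] = dgamma, _["beta"] = dbeta);
    bn_stats[i] = List::create(_["mean"] = cc.mu,
                               _["var"] = arma::square(cc.sigma) - BN_EPS);
  }
  return List::create(
    _["loss_class"] = loss_cls, _["loss_age"] = loss_age,
    _["grads"] = grads,
    _["head_grads"] = List::create(_["W"] = dWh, _["b"] = dbh),
    _["bn_stats"] = bn_stats);
}
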