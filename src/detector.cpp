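// Convolutional detector: 10 conv stages (3x3, same padding, stride 1,
// batch-norm + rectifier), global average pooling, single logistic unit.
// Forward/backward, binary cross-entropy and Adam are implemented here in
// single precision; GEMMs (im2col convolution) go through BLAS. All large
// buffers live in a Work struct reused across batches, so the hot loop is
// free of large allocations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

namespace {

const float BN_EPS = 1e-5f;

struct Net {
  int L, Cf, H, W, P;
  std::vector<fmat> Wc;                 // conv weights (Cout x 9*Cin)
  std::vector<fvec> bc, gamma, beta;    // conv bias, BN scale/shift
  std::vector<fvec> rmean, rvar;        // BN running stats
  fvec head_w; float head_b;
};

Net unpack(const List& params) {
  Net net;
  net.L = as<int>(params["n_layers"]);
  net.Cf = as<int>(params["n_features"]);
  net.H = as<int>(params["img_side"]);
  net.W = net.H;
  net.P = net.H * net.W;
  List cW = params["conv_W"], cb = params["conv_b"];
  List g = params["bn_gamma"], be = params["bn_beta"];
  List rm = params["bn_mean"], rv = params["bn_var"];
  for (int l = 0; l < net.L; ++l) {
    net.Wc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(cW[l])));
    net.bc.push_back(arma::conv_to<fvec>::from(as<arma::vec>(cb[l])));
    net.gamma.push_back(arma::conv_to<fvec>::from(as<arma::vec>(g[l])));
    net.beta.push_back(arma::conv_to<fvec>::from(as<arma::vec>(be[l])));
    net.rmean.push_back(arma::conv_to<fvec>::from(as<arma::vec>(rm[l])));
    net.rvar.push_back(arma::conv_to<fvec>::from(as<arma::vec>(rv[l])));
  }
  net.head_w = arma::conv_to<fvec>::from(as<arma::vec>(params["head_w"]));
  net.head_b = as<double>(params["head_b"]);
  return net;
}

void repack(const Net& net, List& params) {
  List cW = params["conv_W"], cb = params["conv_b"];
  List g = params["bn_gamma"], be = params["bn_beta"];
  List rm = params["bn_mean"], rv = params["bn_var"];
  for (int l = 0; l < net.L; ++l) {
    cW[l] = wrap(arma::conv_to<arma::mat>::from(net.Wc[l]));
    cb[l] = wrap(arma::conv_to<arma::vec>::from(net.bc[l]));
    g[l] = wrap(arma::conv_to<arma::vec>::from(net.gamma[l]));
    be[l] = wrap(arma::conv_to<arma::vec>::from(net.beta[l]));
    rm[l] = wrap(arma::conv_to<arma::vec>::from(net.rmean[l]));
    rv[l] = wrap(arma::conv_to<arma::vec>::from(net.rvar[l]));
  }
  params["conv_W"] = cW; params["conv_b"] = cb;
  params["bn_gamma"] = g; params["bn_beta"] = be;
  params["bn_mean"] = rm; params["bn_var"] = rv;
  params["head_w"] = wrap(arma::conv_to<arma::vec>::from(net.head_w));
  params["head_b"] = (double)net.head_b;
}

// source-pixel maps for the 9 offsets of a 3x3 same-padding convolution
std::vector<std::vector<int>> shift_maps(int H, int W) {
  std::vector<std::vector<int>> maps;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      std::vector<int> m(H * W);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          int rr = r + dr, cc = c + dc;
          m[r + H * c] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? rr + H * cc : -1;
        }
      maps.push_back(m);
    }
  return maps;
}

void im2col(const fmat& X, int P, int B, int Cin,
            const std::vector<std::vector<int>>& maps, fmat& Xcol) {
  Xcol.set_size(9 * Cin, P * B);
  const size_t bytes = Cin * sizeof(float);
  for (int k = 0; k < 9; ++k) {
    const std::vector<int>& mp = maps[k];
    for (int b = 0; b < B; ++b) {
      const int off = P * b;
      for (int p = 0; p < P; ++p) {
        int sp = mp[p];
        float* dst = Xcol.colptr(off + p) + k * Cin;
        if (sp < 0) std::memset(dst, 0, bytes);
        else std::memcpy(dst, X.colptr(off + sp), bytes);
      }
    }
  }
}

void col2im_add(const fmat& dXcol, int P, int B, int Cin,
                const std::vector<std::vector<int>>& maps, fmat& dX) {
  dX.zeros();
  for (int k = 0; k < 9; ++k) {
    const std::vector<int>& mp = maps[k];
    for (int b = 0; b < B; ++b) {
      const int off = P * b;
      for (int p = 0; p < P; ++p) {
        int sp = mp[p];
        if (sp < 0) continue;
        const float* src = dXcol.colptr(off + p) + k * Cin;
        float* dst = dX.colptr(off + sp);
        for (int c = 0; c < Cin; ++c) dst[c] += src[c];
      }
    }
  }
}

// column-sweep mean/variance per row (cache-friendly for wide matrices)
void row_stats(const fmat& Z, fvec& mu, fvec& var) {
  const int C = Z.n_rows, N = Z.n_cols;
  mu.zeros(C); var.zeros(C);
  for (int j = 0; j < N; ++j) {
    const float* z = Z.colptr(j);
    for (int c = 0; c < C; ++c) mu[c] += z[c];
  }
  mu /= (float)N;
  for (int j = 0; j < N; ++j) {
    const float* z = Z.colptr(j);
    for (int c = 0; c < C; ++c) { float d = z[c] - mu[c]; var[c] += d * d; }
  }
  var /= (float)N;
}

// reusable large buffers
struct Work {
  std::vector<fmat> A;      // L+1 activations, A[0] = network input
  std::vector<fmat> Xcol;   // L im2col matrices
  std::vector<fmat> xhat;   // L BN-normalised pre-activations
  std::vector<fvec> istd;   // L BN inverse std
  fmat Z, dZ, dXcol, dA, G;
  frowvec prob;
  Work(int L) : A(L + 1), Xcol(L), xhat(L), istd(L) {}
};

// forward pass over the batch held in w.A[0]; train = true uses batch
// statistics (updating running stats), train = false uses running stats
void forward(Net& net, int B, bool train, float bn_mom,
             const std::vector<std::vector<int>>& maps, Work& w) {
  const int P = net.P;
  for (int l = 0; l < net.L; ++l) {
    const fmat& Ain = w.A[l];
    const int Cin = Ain.n_rows, N = P * B;
    im2col(Ain, P, B, Cin, maps, w.Xcol[l]);
    w.Z = net.Wc[l] * w.Xcol[l];
    w.Z.each_col() += net.bc[l];
    fmat& Aout = w.A[l + 1];
    Aout.set_size(net.Cf, N);
    if (train) {
      fvec mu, var;
      row_stats(w.Z, mu, var);
      net.rmean[l] = (1.0f - bn_mom) * net.rmean[l] + bn_mom * mu;
      net.rvar[l] = (1.0f - bn_mom) * net.rvar[l] +
        bn_mom * var * ((float)N / std::max(1, N - 1));
      fvec istd = 1.0f / arma::sqrt(var + BN_EPS);
      fmat& xh = w.xhat[l];
      xh.set_size(net.Cf, N);
      for (int j = 0; j < N; ++j) {
        const float* z = w.Z.colptr(j);
        float* xo = xh.colptr(j);
        float* ao = Aout.colptr(j);
        for (int c = 0; c < net.Cf; ++c) {
          float v = (z[c] - mu[c]) * istd[c];
          xo[c] = v;
          float a = net.gamma[l][c] * v + net.beta[l][c];
          ao[c] = a > 0.0f ? a : 0.0f;
        }
      }
      w.istd[l] = istd;
    } else {
      fvec istd = 1.0f / arma::sqrt(net.rvar[l] + BN_EPS);
      for (int j = 0; j < N; ++j) {
        const float* z = w.Z.colptr(j);
        float* ao = Aout.colptr(j);
        for (int c = 0; c < net.Cf; ++c) {
          float a = net.gamma[l][c] * (z[c] - net.rmean[l][c]) * istd[c] +
            net.beta[l][c];
          ao[c] = a > 0.0f ? a : 0.0f;
        }
      }
    }
  }
  // head: global-average-pooled logistic unit (head_w of length Cf) or a
  // dense logistic unit over all Cf x P trunk activations
  const fmat& A = w.A[net.L];
  const bool dense = (int)net.head_w.n_elem == net.Cf * P;
  if (dense) {
    w.G.set_size(net.Cf * P, B);
    for (int b = 0; b < B; ++b)
      w.G.col(b) = arma::vectorise(A.cols(P * b, P * (b + 1) - 1));
  } else {
    w.G.set_size(net.Cf, B);
    for (int b = 0; b < B; ++b)
      w.G.col(b) = arma::mean(A.cols(P * b, P * (b + 1) - 1), 1);
  }
  frowvec z = net.head_w.t() * w.G + net.head_b;
  w.prob = 1.0f / (1.0f + arma::exp(-z));
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db, dgamma, dbeta;
  fvec dhead_w; float dhead_b;
};

float backward(Net& net, const fvec& y, int B,
               const std::vector<std::vector<int>>& maps, Work& w, Grads& gr) {
  const int P = net.P;
  float loss = 0.0f;
  frowvec dz(B);
  for (int b = 0; b < B; ++b) {
    float p = std::min(std::max(w.prob[b], 1e-7f), 1.0f - 1e-7f);
    loss += -(y[b] * std::log(p) + (1.0f - y[b]) * std::log(1.0f - p));
    dz[b] = (w.prob[b] - y[b]) / B;
  }
  loss /= B;
  gr.dhead_w = w.G * dz.t();
  gr.dhead_b = arma::accu(dz);
  const bool dense = (int)net.head_w.n_elem == net.Cf * P;
  fmat dG = net.head_w * dz;           // (Cf or Cf*P) x B
  w.dA.set_size(net.Cf, P * B);
  if (dense) {
    for (int b = 0; b < B; ++b)
      w.dA.cols(P * b, P * (b + 1) - 1) =
        arma::reshape(dG.col(b), net.Cf, P);
  } else {
    for (int b = 0; b < B; ++b)
      w.dA.cols(P * b, P * (b + 1) - 1) = arma::repmat(dG.col(b) / P, 1, P);
  }

  gr.dW.assign(net.L, fmat());
  gr.db.assign(net.L, fvec());
  gr.dgamma.assign(net.L, fvec());
  gr.dbeta.assign(net.L, fvec());

  for (int l = net.L - 1; l >= 0; --l) {
    const fmat& Aout = w.A[l + 1];
    const fmat& xh = w.xhat[l];
    const fvec& istd = w.istd[l];
    const int N = P * B;
    const int C = net.Cf;
    // fused ReLU + batch-norm backward
    fvec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    fvec dg(C, arma::fill::zeros), db2(C, arma::fill::zeros);
    for (int j = 0; j < N; ++j) {
      float* d = w.dA.colptr(j);
      const float* ao = Aout.colptr(j);
      const float* xo = xh.colptr(j);
      for (int c = 0; c < C; ++c) {
        float v = ao[c] > 0.0f ? d[c] : 0.0f;
        d[c] = v;                        // dA now holds d(loss)/d(BN out)
        dg[c] += v * xo[c];
        db2[c] += v;
        float wv = v * net.gamma[l][c];  // dxhat
        s1[c] += wv;
        s2[c] += wv * xo[c];
      }
    }
    gr.dgamma[l] = dg;
    gr.dbeta[l] = db2;
    w.dZ.set_size(C, N);
    for (int j = 0; j < N; ++j) {
      const float* d = w.dA.colptr(j);
      const float* xo = xh.colptr(j);
      float* z = w.dZ.colptr(j);
      for (int c = 0; c < C; ++c) {
        float wv = d[c] * net.gamma[l][c] * (float)N;
        z[c] = (wv - s1[c] - xo[c] * s2[c]) * istd[c] / (float)N;
      }
    }
    gr.dW[l] = w.dZ * w.Xcol[l].t();
    gr.db[l] = arma::sum(w.dZ, 1);
    if (l > 0) {
      const int Cin = w.A[l].n_rows;
      w.dXcol = net.Wc[l].t() * w.dZ;
      w.dA.set_size(Cin, N);
      col2im_add(w.dXcol, P, B, Cin, maps, w.dA);
    }
  }
  return loss;
}

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb, mg, vg, mbeta2, vbeta2;
  fvec mhw, vhw; float mhb, vhb;
  int t;
};

AdamState unpack_adam(const List& st, const Net& net) {
  AdamState a;
  a.t = as<int>(st["t"]);
  List mW = st["mW"], vW = st["vW"], mb = st["mb"], vb = st["vb"];
  List mg = st["mg"], vg = st["vg"], mbe = st["mbeta"], vbe = st["vbeta"];
  for (int l = 0; l < net.L; ++l) {
    a.mW.push_back(arma::conv_to<fmat>::from(as<arma::mat>(mW[l])));
    a.vW.push_back(arma::conv_to<fmat>::from(as<arma::mat>(vW[l])));
    a.mb.push_back(arma::conv_to<fvec>::from(as<arma::vec>(mb[l])));
    a.vb.push_back(arma::conv_to<fvec>::from(as<arma::vec>(vb[l])));
    a.mg.push_back(arma::conv_to<fvec>::from(as<arma::vec>(mg[l])));
    a.vg.push_back(arma::conv_to<fvec>::from(as<arma::vec>(vg[l])));
    a.mbeta2.push_back(arma::conv_to<fvec>::from(as<arma::vec>(mbe[l])));
    a.vbeta2.push_back(arma::conv_to<fvec>::from(as<arma::vec>(vbe[l])));
  }
  a.mhw = arma::conv_to<fvec>::from(as<arma::vec>(st["mhw"]));
  a.vhw = arma::conv_to<fvec>::from(as<arma::vec>(st["vhw"]));
  a.mhb = as<double>(st["mhb"]); a.vhb = as<double>(st["vhb"]);
  return a;
}

void repack_adam(const AdamState& a, List& st, const Net& net) {
  List mW = st["mW"], vW = st["vW"], mb = st["mb"], vb = st["vb"];
  List mg = st["mg"], vg = st["vg"], mbe = st["mbeta"], vbe = st["vbeta"];
  for (int l = 0; l < net.L; ++l) {
    mW[l] = wrap(arma::conv_to<arma::mat>::from(a.mW[l]));
    vW[l] = wrap(arma::conv_to<arma::mat>::from(a.vW[l]));
    mb[l] = wrap(arma::conv_to<arma::vec>::from(a.mb[l]));
    vb[l] = wrap(arma::conv_to<arma::vec>::from(a.vb[l]));
    mg[l] = wrap(arma::conv_to<arma::vec>::from(a.mg[l]));
    vg[l] = wrap(arma::conv_to<arma::vec>::from(a.vg[l]));
    mbe[l] = wrap(arma::conv_to<arma::vec>::from(a.mbeta2[l]));
    vbe[l] = wrap(arma::conv_to<arma::vec>::from(a.vbeta2[l]));
  }
  st["mW"] = mW; st["vW"] = vW; st["mb"] = mb; st["vb"] = vb;
  st["mg"] = mg; st["vg"] = vg; st["mbeta"] = mbe; st["vbeta"] = vbe;
  st["mhw"] = wrap(arma::conv_to<arma::vec>::from(a.mhw));
  st["vhw"] = wrap(arma::conv_to<arma::vec>::from(a.vhw));
  st["mhb"] = (double)a.mhb; st["vhb"] = (double)a.vhb;
  st["t"] = a.t;
}

template <class T>
void adam_step(T& w, T& m, T& v, const T& g, float lr, float b1, float b2,
               float eps, float bc1, float bc2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

void load_batch(const arma::cube& X, const IntegerVector& idx, int P, fmat& X0) {
  const int B = idx.size(), Cin = X.n_rows;
  X0.set_size(Cin, P * B);
  for (int b = 0; b < B; ++b) {
    const double* src = X.slice_memptr(idx[b] - 1);
    float* dst = X0.colptr(P * b);
    for (int i = 0; i < Cin * P; ++i) dst[i] = (float)src[i];
  }
}

} // namespace

// [[Rcpp::export]]
List cnn_train_epoch(List params, List adam, const arma::cube& X,
                     const arma::vec& y, const List& batches, double lr,
                     double beta1, double beta2, double adam_eps,
                     double bn_momentum) {
  Net net = unpack(params);
  AdamState ad = unpack_adam(adam, net);
  auto maps = shift_maps(net.H, net.W);
  double total_loss = 0.0; int n_seen = 0;
  Work w(net.L); Grads gr;
  for (int bi = 0; bi < batches.size(); ++bi) {
    IntegerVector idx = batches[bi];
    const int B = idx.size();
    load_batch(X, idx, net.P, w.A[0]);
    fvec yb(B);
    for (int b = 0; b < B; ++b) yb[b] = (float)y[idx[b] - 1];
    forward(net, B, true, (float)bn_momentum, maps, w);
    float loss = backward(net, yb, B, maps, w, gr);
    total_loss += loss * B; n_seen += B;
    ad.t += 1;
    float bc1 = 1.0f - std::pow((float)beta1, (float)ad.t);
    float bc2 = 1.0f - std::pow((float)beta2, (float)ad.t);
    for (int l = 0; l < net.L; ++l) {
      adam_step(net.Wc[l], ad.mW[l], ad.vW[l], gr.dW[l], (float)lr,
                (float)beta1, (float)beta2, (float)adam_eps, bc1, bc2);
      adam_step(net.bc[l], ad.mb[l], ad.vb[l], gr.db[l], (float)lr,
                (float)beta1, (float)beta2, (float)adam_eps, bc1, bc2);
      adam_step(net.gamma[l], ad.mg[l], ad.vg[l], gr.dgamma[l], (float)lr,
                (float)beta1, (float)beta2, (float)adam_eps, bc1, bc2);
      adam_step(net.beta[l], ad.mbeta2[l], ad.vbeta2[l], gr.dbeta[l], (float)lr,
                (float)beta1, (float)beta2, (float)adam_eps, bc1, bc2);
    }
    adam_step(net.head_w, ad.mhw, ad.vhw, gr.dhead_w, (float)lr,
              (float)beta1, (float)beta2, (float)adam_eps, bc1, bc2);
    ad.mhb = (float)beta1 * ad.mhb + (1.0f - (float)beta1) * gr.dhead_b;
    ad.vhb = (float)beta2 * ad.vhb + (1.0f - (float)beta2) * gr.dhead_b * gr.dhead_b;
    net.head_b -= (float)lr * (ad.mhb / bc1) /
      (std::sqrt(ad.vhb / bc2) + (float)adam_eps);
  }
  repack(net, params);
  repack_adam(ad, adam, net);
  return List::create(_["params"] = params, _["adam"] = adam,
                      _["train_loss"] = total_loss / std::max(1, n_seen));
}

// [[Rcpp::export]]
NumericVector cnn_predict(List params, const arma::cube& X, int batch_size = 64) {
  Net net = unpack(params);
  auto maps = shift_maps(net.H, net.W);
  const int n = X.n_slices;
  NumericVector out(n);
  Work w(net.L);
  for (int start = 0; start < n; start += batch_size) {
    int B = std::min(batch_size, n - start);
    IntegerVector idx(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b + 1;
    load_batch(X, idx, net.P, w.A[0]);
    forward(net, B, false, 0.0f, maps, w);
    for (int b = 0; b < B; ++b) out[start + b] = w.prob[b];
  }
  return out;
}

// [[Rcpp::export]]
double cnn_loss(List params, const arma::cube& X, const arma::vec& y,
                int batch_size = 64) {
  NumericVector p = cnn_predict(params, X, batch_size);
  double loss = 0.0;
  for (int i = 0; i < p.size(); ++i) {
    double pi = std::min(std::max(p[i], 1e-7), 1.0 - 1e-7);
    loss += -(y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi));
  }
  return loss / p.size();
}
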