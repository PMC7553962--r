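// Feedforward neural-network classifier used for gene-set screening:
// input layer sized to the gene set, three ReLU hidden layers
// (512/256/128 by default), softmax output over region classes.
// Trained with mini-batch Adam on the cross-entropy loss, in single
// precision.  Deterministic given the seed (own RNG stream; He init).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

namespace {

struct Layer {
  fmat W;      // in x out
  frowvec b;
  fmat mW, vW; // Adam moments
  frowvec mb, vb;
};

void init_layer(Layer &L, int nin, int nout, std::mt19937 &rng) {
  std::normal_distribution<float> g(0.0f, std::sqrt(2.0f / nin));
  L.W.set_size(nin, nout);
  for (auto &w : L.W) w = g(rng);
  L.b.zeros(nout);
  L.mW.zeros(nin, nout); L.vW.zeros(nin, nout);
  L.mb.zeros(nout); L.vb.zeros(nout);
}

inline void adam_step(fmat &p, fmat &m, fmat &v, const fmat &g,
                      float lr, float b1, float b2, float eps, float t) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  fmat mh = m / (1.0f - std::pow(b1, t));
  fmat vh = v / (1.0f - std::pow(b2, t));
  p -= lr * mh / (arma::sqrt(vh) + eps);
}

inline void adam_step_row(frowvec &p, frowvec &m, frowvec &v, const frowvec &g,
                          float lr, float b1, float b2, float eps, float t) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  frowvec mh = m / (1.0f - std::pow(b1, t));
  frowvec vh = v / (1.0f - std::pow(b2, t));
  p -= lr * mh / (arma::sqrt(vh) + eps);
}

} // namespace

// Train on (X, y) and return predicted class indices (0-based) for Xtest.
// X rows are samples, columns features (already standardised by the caller).
// [[Rcpp::export(name = ".mlp_fit_predict_cpp")]]
IntegerVector mlp_fit_predict_cpp(NumericMatrix Xr, IntegerVector y, NumericMatrix Xtr,
                                  int n_classes, IntegerVector hidden,
                                  int epochs, int batch_size, double lr_in, int seed) {
  const int n = Xr.nrow(), d = Xr.ncol();
  const float lr = (float)lr_in, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  fmat X(n, d);
  for (int i = 0; i < n; ++i) for (int j = 0; j < d; ++j) X(i, j) = (float)Xr(i, j);
  const int nt = Xtr.nrow();
  fmat Xt(nt, d);
  for (int i = 0; i < nt; ++i) for (int j = 0; j < d; ++j) Xt(i, j) = (float)Xtr(i, j);

  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(n_classes);
  const int L = sizes.size() - 1;

  std::seed_seq ss{seed, 7919};
  std::mt19937 rng(ss);
  std::vector<Layer> lay(L);
  for (int l = 0; l < L; ++l) init_layer(lay[l], sizes[l], sizes[l + 1], rng);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<fmat> act(L + 1), delta(L);
  float t_adam = 0.0f;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n);
      const int bs = end - start;
      arma::uvec rows(bs);
      for (int i = 0; i < bs; ++i) rows[i] = idx[start + i];
      act[0] = X.rows(rows);
      for (int l = 0; l < L; ++l) {
        act[l + 1] = act[l] * lay[l].W;
        act[l + 1].each_row() += lay[l].b;
        if (l < L - 1) act[l + 1].transform([](float v) { return v > 0.0f ? v : 0.0f; });
      }
      // softmax + cross-entropy gradient
      fmat &z = act[L];
      arma::fvec zmax = arma::max(z, 1);
      z.each_col() -= zmax;
      z = arma::exp(z);
      arma::fvec zsum = arma::sum(z, 1);
      z.each_col() /= zsum;
      for (int i = 0; i < bs; ++i) z(i, y[rows[i]]) -= 1.0f;
      z /= (float)bs;

      t_adam += 1.0f;
      fmat grad = z;
      for (int l = L - 1; l >= 0; --l) {
        fmat gW = act[l].t() * grad;
        frowvec gb = arma::sum(grad, 0);
        if (l > 0) {
          grad = grad * lay[l].W.t();
          // ReLU mask from the forward activations
          const fmat &a = act[l];
          for (arma::uword k = 0; k < grad.n_elem; ++k)
            if (a[k] <= 0.0f) grad[k] = 0.0f;
        }
        adam_step(lay[l].W, lay[l].mW, lay[l].vW, gW, lr, b1, b2, eps, t_adam);
        adam_step_row(lay[l].b, lay[l].mb, lay[l].vb, gb, lr, b1, b2, eps, t_adam);
      }
    }
  }

  // predict
  fmat a = Xt;
  for (int l = 0; l < L; ++l) {
    a = a * lay[l].W;
    a.each_row() += lay[l].b;
    if (l < L - 1) a.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  }
  IntegerVector pred(nt);
  for (int i = 0; i < nt; ++i) {
    int bj = 0; float best = a(i, 0);
    for (int j = 1; j < n_classes; ++j) if (a(i, j) > best) { best = a(i, j); bj = j; }
    pred[i] = bj;
  }
  return pred;
}
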