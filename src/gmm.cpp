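// Per-gene-pair sample clustering with 2-D Gaussian mixture models.
//
// Every unordered gene pair is clustered in the 2-D space of its paired
// expression values (samples with a missing or negative value in either
// gene are excluded).  The component count is chosen by BIC over
// 1..max_components; each retained component with >= min_cluster members
// becomes a candidate condition-specific edge whose Spearman correlation
// is computed over its member samples only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Gauss2 {
  double mx, my;        // mean
  double sxx, sxy, syy; // covariance
  double w;             // mixing weight
};

// log density of a 2-D Gaussian, covariance regularised by the caller
inline double log_dnorm2(double x, double y, const Gauss2 &g) {
  const double det = g.sxx * g.syy - g.sxy * g.sxy;
  const double dx = x - g.mx, dy = y - g.my;
  const double quad = (g.syy * dx * dx - 2.0 * g.sxy * dx * dy + g.sxx * dy * dy) / det;
  return -std::log(2.0 * M_PI) - 0.5 * std::log(det) - 0.5 * quad;
}

inline double logsumexp2(const std::vector<double> &v) {
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// k-means++ seeding followed by a few Lloyd iterations; returns hard labels
void kmeans_init(const arma::vec &x, const arma::vec &y, int k,
                 std::mt19937 &rng, arma::ivec &lab) {
  const int n = x.n_elem;
  std::vector<double> cx(k), cy(k);
  std::uniform_int_distribution<int> unif(0, n - 1);
  int first = unif(rng);
  cx[0] = x[first]; cy[0] = y[first];
  std::vector<double> d2(n);
  for (int c = 1; c < k; ++c) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::max();
      for (int j = 0; j < c; ++j) {
        double dx = x[i] - cx[j], dy = y[i] - cy[j];
        best = std::min(best, dx * dx + dy * dy);
      }
      d2[i] = best; tot += best;
    }
    double r = std::uniform_real_distribution<double>(0.0, tot)(rng);
    int pick = n - 1; double acc = 0.0;
    for (int i = 0; i < n; ++i) { acc += d2[i]; if (acc >= r) { pick = i; break; } }
    cx[c] = x[pick]; cy[c] = y[pick];
  }
  for (int it = 0; it < 5; ++it) {
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::max(); int bj = 0;
      for (int j = 0; j < k; ++j) {
        double dx = x[i] - cx[j], dy = y[i] - cy[j];
        double d = dx * dx + dy * dy;
        if (d < best) { best = d; bj = j; }
      }
      lab[i] = bj;
    }
    for (int j = 0; j < k; ++j) {
      double sx = 0, sy = 0; int m = 0;
      for (int i = 0; i < n; ++i) if (lab[i] == j) { sx += x[i]; sy += y[i]; ++m; }
      if (m > 0) { cx[j] = sx / m; cy[j] = sy / m; }
    }
  }
}

// EM for a k-component full-covariance 2-D mixture; returns log-likelihood,
// fills hard assignments.  reg keeps covariances positive definite.
double fit_em(const arma::vec &x, const arma::vec &y, int k,
              std::mt19937 &rng, int max_iter, double tol,
              arma::ivec &lab_out) {
  const int n = x.n_elem;
  const double reg = 1e-6;
  arma::ivec lab(n, arma::fill::zeros);
  if (k > 1) kmeans_init(x, y, k, rng, lab);

  std::vector<Gauss2> comp(k);
  arma::mat resp(n, k);
  // init from hard labels
  for (int j = 0; j < k; ++j) {
    double sx = 0, sy = 0; int m = 0;
    for (int i = 0; i < n; ++i) if (lab[i] == j) { sx += x[i]; sy += y[i]; ++m; }
    if (m < 2) { // degenerate seed: global init with jitter
      comp[j].mx = arma::mean(x) + 1e-3 * j; comp[j].my = arma::mean(y);
      comp[j].sxx = arma::var(x) + reg; comp[j].syy = arma::var(y) + reg;
      comp[j].sxy = 0.0; comp[j].w = 1.0 / k;
      continue;
    }
    comp[j].mx = sx / m; comp[j].my = sy / m;
    double sxx = 0, sxy = 0, syy = 0;
    for (int i = 0; i < n; ++i) if (lab[i] == j) {
      double dx = x[i] - comp[j].mx, dy = y[i] - comp[j].my;
      sxx += dx * dx; sxy += dx * dy; syy += dy * dy;
    }
    comp[j].sxx = sxx / m + reg; comp[j].sxy = sxy / m; comp[j].syy = syy / m + reg;
    comp[j].w = (double)m / n;
  }

  double ll_old = -std::numeric_limits<double>::max(), ll = ll_old;
  std::vector<double> lp(k);
  for (int it = 0; it < max_iter; ++it) {
    // E step
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j)
        lp[j] = std::log(std::max(comp[j].w, 1e-300)) + log_dnorm2(x[i], y[i], comp[j]);
      double lse = logsumexp2(lp);
      ll += lse;
      for (int j = 0; j < k; ++j) resp(i, j) = std::exp(lp[j] - lse);
    }
    if (ll - ll_old < tol * std::abs(ll) && it > 0) break;
    ll_old = ll;
    // M step
    for (int j = 0; j < k; ++j) {
      double nj = arma::accu(resp.col(j));
      if (nj < 1e-8) { comp[j].w = 1e-8; continue; }
      double mx = arma::dot(resp.col(j), x) / nj;
      double my = arma::dot(resp.col(j), y) / nj;
      double sxx = 0, sxy = 0, syy = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x[i] - mx, dy = y[i] - my, r = resp(i, j);
        sxx += r * dx * dx; sxy += r * dx * dy; syy += r * dy * dy;
      }
      comp[j].mx = mx; comp[j].my = my;
      comp[j].sxx = sxx / nj + reg; comp[j].sxy = sxy / nj; comp[j].syy = syy / nj + reg;
      comp[j].w = nj / n;
    }
  }
  for (int i = 0; i < n; ++i) {
    int bj = 0; double best = resp(i, 0);
    for (int j = 1; j < k; ++j) if (resp(i, j) > best) { best = resp(i, j); bj = j; }
    lab_out[i] = bj;
  }
  return ll;
}

// average ranks (ties -> mean rank)
arma::vec avg_rank(const arma::vec &v) {
  const int n = v.n_elem;
  arma::uvec ord = arma::sort_index(v);
  arma::vec rk(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int t = i; t <= j; ++t) rk[ord[t]] = r;
    i = j + 1;
  }
  return rk;
}

// Spearman rho = Pearson on average ranks; NaN if either rank vector constant
double spearman(const arma::vec &x, const arma::vec &y) {
  arma::vec rx = avg_rank(x), ry = avg_rank(y);
  double sx = arma::stddev(rx), sy = arma::stddev(ry);
  if (sx == 0.0 || sy == 0.0) return NA_REAL;
  return arma::as_scalar(arma::cor(rx, ry));
}

// deterministic per-pair RNG stream
inline std::mt19937 pair_rng(int seed, int i, int j) {
  std::seed_seq ss{seed, i, j};
  return std::mt19937(ss);
}

struct PairResult {
  std::vector<int> cluster_index;
  std::vector<int> cluster_size;
  std::vector<double> rho;
  std::vector<std::string> mask;
  int n_clusters = 0;
};

// full per-pair pipeline: usable-sample filter, BIC model selection, masks,
// per-cluster Spearman for clusters >= min_cluster
PairResult cluster_pair(const arma::vec &xi, const arma::vec &yi,
                        int min_cluster, int max_components,
                        int restarts, int max_iter, double tol,
                        std::mt19937 &rng, bool keep_small) {
  const int n = xi.n_elem;
  PairResult out;
  std::vector<int> use;
  use.reserve(n);
  for (int s = 0; s < n; ++s) {
    double a = xi[s], b = yi[s];
    if (std::isfinite(a) && std::isfinite(b) && a >= 0.0 && b >= 0.0) use.push_back(s);
  }
  const int m = use.size();
  if (m < min_cluster) return out;

  arma::vec x(m), y(m);
  for (int t = 0; t < m; ++t) { x[t] = xi[use[t]]; y[t] = yi[use[t]]; }

  // BIC model selection over component counts; larger counts are skipped
  // once BIC has failed to improve twice in a row
  int best_k = 1;
  double best_bic = -std::numeric_limits<double>::max();
  arma::ivec best_lab(m, arma::fill::zeros);
  arma::ivec lab(m), lab_try(m);
  int stale = 0;
  for (int k = 1; k <= max_components; ++k) {
    if (m < 3 * k) break; // too few points to support k components
    double ll_best = -std::numeric_limits<double>::max();
    int nrep = (k == 1) ? 1 : restarts;
    for (int r = 0; r < nrep; ++r) {
      double ll = fit_em(x, y, k, rng, max_iter, tol, lab_try);
      if (ll > ll_best) { ll_best = ll; lab = lab_try; }
    }
    const int p = (k - 1) + 2 * k + 3 * k; // weights + means + covariances
    const double bic = 2.0 * ll_best - p * std::log((double)m);
    if (bic > best_bic) {
      best_bic = bic; best_k = k; best_lab = lab; stale = 0;
    } else if (++stale >= 2) {
      break;
    }
  }

  out.n_clusters = best_k;
  for (int j = 0; j < best_k; ++j) {
    std::vector<int> mem;
    for (int t = 0; t < m; ++t) if (best_lab[t] == j) mem.push_back(t);
    const int sz = mem.size();
    if (sz < min_cluster && !keep_small) continue;
    std::string msk(n, '9');
    for (int s = 0; s < n; ++s) {
      double a = xi[s], b = yi[s];
      if (std::isfinite(a) && std::isfinite(b) && a >= 0.0 && b >= 0.0) msk[s] = '0';
    }
    for (int t : mem) msk[use[t]] = '1';
    double rho = NA_REAL;
    if (sz >= min_cluster) {
      arma::vec cx(sz), cy(sz);
      for (int t = 0; t < sz; ++t) { cx[t] = x[mem[t]]; cy[t] = y[mem[t]]; }
      rho = spearman(cx, cy);
    }
    out.cluster_index.push_back(j);
    out.cluster_size.push_back(sz);
    out.rho.push_back(rho);
    out.mask.push_back(msk);
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".pair_clusters_cpp")]]
List pair_clusters_cpp(NumericVector x, NumericVector y,
                       int min_cluster, int max_components,
                       int restarts, int max_iter, double tol,
                       int seed, bool keep_small) {
  arma::vec xv(x.begin(), x.size(), false), yv(y.begin(), y.size(), false);
  std::mt19937 rng = pair_rng(seed, 0, 1);
  PairResult r = cluster_pair(xv, yv, min_cluster, max_components,
                              restarts, max_iter, tol, rng, keep_small);
  return List::create(
    _["cluster_index"] = wrap(r.cluster_index),
    _["n_clusters"] = r.n_clusters,
    _["cluster_size"] = wrap(r.cluster_size),
    _["rho"] = wrap(r.rho),
    _["sample_mask"] = wrap(r.mask));
}

// [[Rcpp::export(name = ".similarity_scan_cpp")]]
List similarity_scan_cpp(NumericMatrix gem, IntegerVector pair_i, IntegerVector pair_j,
                         IntegerVector pair_seed,
                         int min_cluster, int max_components,
                         int restarts, int max_iter, double tol,
                         bool keep_small) {
  const int n_samples = gem.ncol();
  const int n_pairs = pair_i.size();
  std::vector<int> oi, oj, ocl, onc, osz;
  std::vector<double> orho;
  std::vector<std::string> omask;

  arma::vec x(n_samples), y(n_samples);
  for (int p = 0; p < n_pairs; ++p) {
    if (p % 2048 == 0) Rcpp::checkUserInterrupt();
    const int gi = pair_i[p] - 1, gj = pair_j[p] - 1;
    for (int s = 0; s < n_samples; ++s) { x[s] = gem(gi, s); y[s] = gem(gj, s); }
    std::mt19937 rng = pair_rng(pair_seed[p], 0, 1);
    PairResult r = cluster_pair(x, y, min_cluster, max_components,
                                restarts, max_iter, tol, rng, keep_small);
    for (size_t c = 0; c < r.cluster_index.size(); ++c) {
      oi.push_back(gi + 1); oj.push_back(gj + 1);
      ocl.push_back(r.cluster_index[c]); onc.push_back(r.n_clusters);
      osz.push_back(r.cluster_size[c]); orho.push_back(r.rho[c]);
      omask.push_back(r.mask[c]);
    }
  }
  return List::create(
    _["i"] = wrap(oi), _["j"] = wrap(oj),
    _["cluster_index"] = wrap(ocl), _["n_clusters"] = wrap(onc),
    _["cluster_size"] = wrap(osz), _["rho"] = wrap(orho),
    _["sample_mask"] = wrap(omask));
}

// [[Rcpp::export(name = ".spearman_cpp")]]
double spearman_cpp(NumericVector x, NumericVector y) {
  arma::vec xv(x.begin(), x.size(), false), yv(y.begin(), y.size(), false);
  return spearman(xv, yv);
}
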