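// Regression CART forest tuned for the many tiny fits demanded by
// LOOCV-wrapped sequential forward selection (n ~ 60-90, p <= ~30).
// Deterministic across platforms: own splitmix64 RNG, split ties broken
// by lowest feature index then lowest threshold. Features are pre-sorted
// once per fit and kept sorted through stable partitions, so no sorting
// happens inside the recursion; trees are stored in flat arrays with
// per-tree offsets to keep per-fit allocation minimal.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1) from the top 53 bits; stdlib distributions are not
  // reproducible across implementations, so bounded draws go through this
  double unif() { return (double)(next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

uint64_t mix_seed(uint64_t seed, uint64_t tree) {
  return seed * 0x9E3779B97F4A7C15ULL + (tree + 1) * 0xBF58476D1CE4E5B9ULL;
}

struct ForestBuilder {
  const double* X;  // column-major n x p
  const double* y;
  int n, p, min_node, mtry;
  // flat tree storage shared across trees
  std::vector<int> var, left, right;
  std::vector<double> thr, pred;
  std::vector<int> tree_start;
  std::vector<double> importance;
  // workspaces
  std::vector<int> ord;   // p x n: rows sorted by each feature (once per fit)
  std::vector<int> srt;   // p x n: per-tree working copy, kept sorted
  std::vector<int> tmp;   // n
  std::vector<int> cnt;   // n: bootstrap multiplicities
  std::vector<int> feats;
  Rng* rng;

  ForestBuilder(const double* X_, const double* y_, int n_, int p_,
                int min_node_, int mtry_)
      : X(X_), y(y_), n(n_), p(p_), min_node(min_node_), mtry(mtry_),
        importance(p_, 0.0), ord((size_t)p_ * n_), srt((size_t)p_ * n_),
        tmp(n_), cnt(n_), feats(p_), rng(nullptr) {
    std::vector<std::pair<double, int>> key(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) key[i] = std::make_pair(xv(i, j), i);
      std::sort(key.begin(), key.end());
      for (int i = 0; i < n; ++i) ord[(size_t)j * n + i] = key[i].second;
    }
  }

  double xv(int i, int j) const { return X[i + (size_t)j * n]; }

  // build one node over srt[j][lo, hi); returns node id
  int build_node(int lo, int hi) {
    int node = (int)var.size();
    var.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    int m = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int t = lo; t < hi; ++t) {
      double v = y[srt[t]];  // feature 0's segment holds the node's multiset
      sum += v;
      sumsq += v * v;
    }
    pred.push_back(sum / m);
    double ss = sumsq - sum * sum / m;
    if (m < 2 || m < 2 * min_node || ss <= 1e-12) return node;

    int ncand = p;
    if (mtry < p) {
      for (int j = 0; j < p; ++j) feats[j] = j;
      for (int j = 0; j < mtry; ++j) {
        int k = j + rng->below(p - j);
        std::swap(feats[j], feats[k]);
      }
      std::sort(feats.begin(), feats.begin() + mtry);
      ncand = mtry;
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_var = -1;
    for (int c = 0; c < ncand; ++c) {
      int j = (mtry < p) ? feats[c] : c;
      const int* s = &srt[(size_t)j * n];
      double sumL = 0.0;
      for (int k = 1; k < m; ++k) {
        double x_prev = xv(s[lo + k - 1], j);
        sumL += y[s[lo + k - 1]];
        if (x_prev >= xv(s[lo + k], j)) continue;  // cannot separate ties
        int nL = k, nR = m - k;
        if (nL < min_node || nR < min_node) continue;
        double sumR = sum - sumL;
        double gain = sumL * sumL / nL + sumR * sumR / nR - sum * sum / m;
        // strict > keeps the first maximiser: lowest feature index, then
        // lowest threshold (features ascend, thresholds ascend within one)
        if (gain > best_gain) {
          best_gain = gain;
          best_var = j;
          best_thr = 0.5 * (x_prev + xv(s[lo + k], j));
        }
      }
    }
    if (best_var < 0 || best_gain <= 1e-12) return node;

    importance[best_var] += best_gain;
    // stable partition of every feature's segment: left block then right
    // block, preserving within-block sort order
    int nl = 0;
    for (int j = 0; j < p; ++j) {
      int* s = &srt[(size_t)j * n];
      int a = 0, b = 0;
      for (int t = lo; t < hi; ++t) {
        if (xv(s[t], best_var) <= best_thr)
          s[lo + a++] = s[t];
        else
          tmp[b++] = s[t];
      }
      for (int t = 0; t < b; ++t) s[lo + a + t] = tmp[t];
      nl = a;
    }

    var[node] = best_var;
    thr[node] = best_thr;
    int L = build_node(lo, lo + nl);
    left[node] = L;
    int R = build_node(lo + nl, hi);
    right[node] = R;
    return node;
  }

  void build_forest(int ntree, bool bootstrap, uint64_t seed) {
    var.reserve(4 * n);
    for (int t = 0; t < ntree; ++t) {
      Rng r(mix_seed(seed, (uint64_t)t));
      rng = &r;
      std::fill(cnt.begin(), cnt.end(), 0);
      if (bootstrap)
        for (int i = 0; i < n; ++i) ++cnt[r.below(n)];
      else
        std::fill(cnt.begin(), cnt.end(), 1);
      for (int j = 0; j < p; ++j) {
        int* s = &srt[(size_t)j * n];
        const int* o = &ord[(size_t)j * n];
        int k = 0;
        for (int i = 0; i < n; ++i)
          for (int c = 0; c < cnt[o[i]]; ++c) s[k++] = o[i];
      }
      tree_start.push_back((int)var.size());
      build_node(0, n);
    }
    tree_start.push_back((int)var.size());
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int min_node, bool bootstrap, double seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("forest fit needs at least 2 rows");
  if ((int)y.size() != n) stop("length(y) must match nrow(X)");
  if (ntree < 1) stop("need at least 1 tree");
  if (mtry < 1 || mtry > p) mtry = p;
  ForestBuilder fb(X.begin(), y.begin(), n, p, min_node, mtry);
  fb.build_forest(ntree, bootstrap, (uint64_t)seed);
  double s = 0.0;
  for (double v : fb.importance) s += v;
  if (s > 0)
    for (double& v : fb.importance) v /= s;  // normalized impurity importance
  return List::create(
      _["var"] = IntegerVector(fb.var.begin(), fb.var.end()),
      _["thr"] = NumericVector(fb.thr.begin(), fb.thr.end()),
      _["left"] = IntegerVector(fb.left.begin(), fb.left.end()),
      _["right"] = IntegerVector(fb.right.begin(), fb.right.end()),
      _["pred"] = NumericVector(fb.pred.begin(), fb.pred.end()),
      _["tree_start"] = IntegerVector(fb.tree_start.begin(),
                                      fb.tree_start.end()),
      _["importance"] = NumericVector(fb.importance.begin(),
                                      fb.importance.end()),
      _["ntree"] = ntree, _["mtry"] = mtry, _["min_node"] = min_node,
      _["bootstrap"] = bootstrap, _["seed"] = seed);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix Xnew) {
  IntegerVector var = forest["var"];
  NumericVector thr = forest["thr"];
  IntegerVector left = forest["left"];
  IntegerVector right = forest["right"];
  NumericVector pred = forest["pred"];
  IntegerVector tree_start = forest["tree_start"];
  int ntree = tree_start.size() - 1;
  int n = Xnew.nrow();
  const double* Xp = Xnew.begin();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    int root = tree_start[t];
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (var[node] >= 0)
        node = Xp[i + (size_t)var[node] * n] <= thr[node] ? left[node]
                                                          : right[node];
      out[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export]]
List cpp_ols(const arma::mat& X, const arma::vec& y) {
  arma::mat X1 = arma::join_horiz(arma::ones<arma::vec>(X.n_rows), X);
  if (X1.n_rows < X1.n_cols || arma::rank(X1) < X1.n_cols)
    stop("singular design matrix");
  arma::vec coef = arma::solve(X1, y);
  arma::vec fitted = X1 * coef;
  return List::create(_["coefficients"] = NumericVector(coef.begin(), coef.end()),
                      _["fitted"] = NumericVector(fitted.begin(), fitted.end()));
}

// LOOCV inner loop in C++: for each held-out row, refit the requested
// components on the remaining rows (reusing the spec seed every fold so
// candidate scores are comparable) and predict the held-out row.
// kind: 0 = linear, 1 = forest, 2 = ensemble.
// [[Rcpp::export]]
NumericVector cpp_loocv(NumericMatrix X, NumericVector y, int kind,
                        int ntree, int mtry, int min_node, bool bootstrap,
                        double seed, double w_linear, double w_forest) {
  int n = X.nrow(), p = X.ncol();
  if (n < 3) stop("need at least 3 rows for LOOCV");
  if (mtry < 1 || mtry > p) mtry = p;
  NumericVector out(n);
  std::vector<double> Xtr((size_t)(n - 1) * p), ytr(n - 1), xte(p);
  arma::mat X1(n - 1, p + 1);
  arma::vec yv(n - 1);
  for (int hold = 0; hold < n; ++hold) {
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < p; ++j)
        Xtr[r + (size_t)j * (n - 1)] = X(i, j);
      ytr[r] = y[i];
      ++r;
    }
    for (int j = 0; j < p; ++j) xte[j] = X(hold, j);
    double pred_lin = 0.0, pred_for = 0.0;
    if (kind == 0 || kind == 2) {
      for (int i = 0; i < n - 1; ++i) {
        X1(i, 0) = 1.0;
        for (int j = 0; j < p; ++j) X1(i, j + 1) = Xtr[i + (size_t)j * (n - 1)];
        yv(i) = ytr[i];
      }
      if (arma::rank(X1) < (arma::uword)(p + 1))
        stop("singular design matrix");
      arma::vec coef = arma::solve(X1, yv);
      pred_lin = coef(0);
      for (int j = 0; j < p; ++j) pred_lin += coef(j + 1) * xte[j];
    }
    if (kind == 1 || kind == 2) {
      ForestBuilder fb(Xtr.data(), ytr.data(), n - 1, p, min_node, mtry);
      fb.build_forest(ntree, bootstrap, (uint64_t)seed);
      double acc = 0.0;
      for (int t = 0; t < ntree; ++t) {
        int node = fb.tree_start[t];
        while (fb.var[node] >= 0)
          node = xte[fb.var[node]] <= fb.thr[node] ? fb.left[node]
                                                   : fb.right[node];
        acc += fb.pred[node];
      }
      pred_for = acc / ntree;
    }
    out[hold] = kind == 0 ? pred_lin
              : kind == 1 ? pred_for
                          : w_linear * pred_lin + w_forest * pred_for;
  }
  return out;
}
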