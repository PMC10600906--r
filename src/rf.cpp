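#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Self-contained RNG (splitmix64 / xoshiro256**) so that forests are
// bit-reproducible across platforms and independent of R's global RNG state.
namespace {

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x[feature] <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaf: fraction of positives
};

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry;
  int min_node;
  Rng &rng;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
          int min_node_, Rng &rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
        feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int make_leaf(int npos, int n) {
    int id = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back((double)npos / (double)n);
    return id;
  }

  // Grow on sample index vector idx (with multiplicity from the bootstrap).
  int grow(std::vector<int> &idx) {
    int n = (int)idx.size();
    int npos = 0;
    for (int i : idx) npos += y[i];
    if (npos == 0 || npos == n || n < min_node) return make_leaf(npos, n);

    // sample mtry candidate features by partial Fisher-Yates
    int p = (int)feat_pool.size();
    for (int j = 0; j < mtry; ++j) {
      int k = j + rng.below(p - j);
      std::swap(feat_pool[j], feat_pool[k]);
    }

    double parent_gini = 1.0 - ((double)npos / n) * ((double)npos / n) -
                         ((double)(n - npos) / n) * ((double)(n - npos) / n);
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry; ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue; // constant
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        int rpos = npos - lpos;
        double gl = 1.0 - ((double)lpos / nl) * ((double)lpos / nl) -
                    ((double)(nl - lpos) / nl) * ((double)(nl - lpos) / nl);
        double gr = 1.0 - ((double)rpos / nr) * ((double)rpos / nr) -
                    ((double)(nr - rpos) / nr) * ((double)(nr - rpos) / nr);
        double gain = parent_gini - ((double)nl / n) * gl - ((double)nr / n) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }
    if (best_feat < 0) return make_leaf(npos, n);

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return make_leaf(npos, n);

    int id = (int)tree.feature.size();
    tree.feature.push_back(best_feat);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(NA_REAL);
    std::vector<int>().swap(idx); // free before recursing
    int l = grow(lidx);
    int r = grow(ridx);
    tree.left[id] = l;
    tree.right[id] = r;
    return id;
  }
};

double tree_vote(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = X(row, t.feature[node]) <= t.threshold[node] ? t.left[node]
                                                        : t.right[node];
  }
  double frac = t.value[node];
  if (frac > 0.5) return 1.0;
  if (frac < 0.5) return 0.0;
  return 0.5; // tied impure leaf
}

Tree unpack_tree(const List &tl) {
  Tree t;
  t.feature = as<std::vector<int>>(tl["feature"]);
  t.threshold = as<std::vector<double>>(tl["threshold"]);
  t.left = as<std::vector<int>>(tl["left"]);
  t.right = as<std::vector<int>>(tl["right"]);
  t.value = as<std::vector<double>>(tl["value"]);
  return t;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node, double seed) {
  int n = X.nrow();
  uint64_t master = (uint64_t)seed;
  List forest(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    uint64_t s = master;
    uint64_t tree_seed = Rng::splitmix64(s) + (uint64_t)b * 0x9E3779B97F4A7C15ULL;
    Rng rng(tree_seed);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n); // bootstrap
    Builder builder(X, y, mtry, min_node, rng);
    builder.grow(idx);
    forest[b] = List::create(
        _["feature"] = wrap(builder.tree.feature),
        _["threshold"] = wrap(builder.tree.threshold),
        _["left"] = wrap(builder.tree.left),
        _["right"] = wrap(builder.tree.right),
        _["value"] = wrap(builder.tree.value));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow();
  int n_trees = forest.size();
  std::vector<Tree> trees;
  trees.reserve(n_trees);
  for (int b = 0; b < n_trees; ++b) trees.push_back(unpack_tree(forest[b]));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int b = 0; b < n_trees; ++b) acc += tree_vote(trees[b], X, i);
    out[i] = acc / n_trees;
  }
  return out;
}
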