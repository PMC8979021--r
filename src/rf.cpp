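// Random forest for binary classification.
//
// Classic Breiman forest: bootstrap sample per tree, CART splits by Gini
// impurity over `mtry` features drawn uniformly at each node, trees grown
// to purity (subject to a depth cap), prediction = fraction of trees whose
// leaf majority votes positive. Written against a private mt19937 stream
// so a given (data, seed) pair always yields the same forest.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; leaf iff feat == -1, then thr holds the vote (0/1)
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left;
  std::vector<int> right;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_), feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int leaf(Tree& t, int n1, int n) {
    t.feat.push_back(-1);
    // majority vote; exact tie breaks to the negative class
    t.thr.push_back(2 * n1 > n ? 1.0 : 0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    return (int)t.feat.size() - 1;
  }

  // build node over samples[lo, hi); returns node index
  int build(Tree& t, std::vector<int>& samples, int lo, int hi, int depth) {
    int n = hi - lo, n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[samples[i]];
    if (n1 == 0 || n1 == n || n < 2 * min_node || depth >= max_depth)
      return leaf(t, n1, n);

    // draw mtry distinct features (partial Fisher-Yates)
    int p = X.ncol();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> d(k, p - 1);
      std::swap(feat_pool[k], feat_pool[d(rng)]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    double parent = (double)n1 * (n - n1);  // n^2/2 * gini, monotone proxy

    std::vector<std::pair<double, int> > vals(n);
    std::vector<std::pair<double, int> > best_order;
    for (int k = 0; k < m; ++k) {
      int j = feat_pool[k];
      for (int i = 0; i < n; ++i) {
        int s = samples[lo + i];
        vals[i] = std::make_pair(X(s, j), y[s]);
      }
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        int r1 = n1 - l1;
        // weighted Gini decrease (up to constants): parent/n - sum child
        double child = (double)l1 * (nl - l1) / nl +
                       (double)r1 * (nr - r1) / nr;
        double gain = parent / n - child;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return leaf(t, n1, n);

    // partition samples in place
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(samples[i], best_feat) <= best_thr) {
        std::swap(samples[i], samples[mid]);
        ++mid;
      }
    }
    if (mid == lo || mid == hi) return leaf(t, n1, n);

    int node = (int)t.feat.size();
    t.feat.push_back(best_feat);
    t.thr.push_back(best_thr);
    t.left.push_back(-1);
    t.right.push_back(-1);
    int l = build(t, samples, lo, mid, depth + 1);
    int r = build(t, samples, mid, hi, depth + 1);
    t.left[node] = l;
    t.right[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, int max_depth, int seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y disagree on the number of rows");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  std::vector<int> samples(n);
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) samples[i] = boot(rng);
    Tree t;
    Builder builder(X, y, mtry, min_node, max_depth, rng);
    builder.build(t, samples, 0, n, 0);
    trees[b] = List::create(_["feat"] = wrap(t.feat),
                            _["thr"] = wrap(t.thr),
                            _["left"] = wrap(t.left),
                            _["right"] = wrap(t.right));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int b = 0; b < ntree; ++b) {
    List t = trees[b];
    IntegerVector feat = t["feat"];
    NumericVector thr = t["thr"];
    IntegerVector left = t["left"], right = t["right"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = X(i, feat[node]) <= thr[node] ? left[node] : right[node];
      out[i] += thr[node];
    }
  }
  return out / (double)ntree;
}
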