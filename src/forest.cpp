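// Bagged CART forest with per-node mtry feature sampling (Gini criterion).
// Kept in-package so that bootstrap membership and per-split impurity
// decreases are recoverable exactly; all randomness comes from R's RNG so
// fits are bit-reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeBuild {
  std::vector<int> var;      // split feature (0-based), -1 for leaf
  std::vector<double> split; // threshold, left if x <= split
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf class (0-based), -1 for internal
  std::vector<double> dec;   // fraction-of-samples weighted Gini decrease

  int newNode() {
    var.push_back(-1); split.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    pred.push_back(-1); dec.push_back(0.0);
    return (int)var.size() - 1;
  }
};

inline double giniFromCounts(const std::vector<int>& cnt, int n) {
  double s = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = (double)cnt[c] / n;
    s += p * p;
  }
  return 1.0 - s;
}

inline int majorityClass(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c; // ties -> smallest class index
  return best;
}

// Sample `m` distinct values from 0..(d-1) by partial Fisher-Yates, R RNG.
inline void sampleFeatures(std::vector<int>& pool, int d, int m,
                           std::vector<int>& out) {
  for (int i = 0; i < d; ++i) pool[i] = i;
  out.resize(m);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (d - i));
    if (j >= d) j = d - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct Frame { int node, begin, end; };

void growTree(const NumericMatrix& X, const IntegerVector& y, int nClass,
              const std::vector<int>& bootstrap, int mtry, int nodesize,
              TreeBuild& T) {
  const int d = X.ncol();
  const int nTotal = (int)bootstrap.size(); // = n, bootstrap size
  std::vector<int> idx(bootstrap);

  std::vector<int> pool(d), cand;
  std::vector<std::pair<double,int> > buf; // (value, class)
  std::vector<int> cntAll(nClass), cntL(nClass), cntR(nClass);

  std::vector<Frame> stack;
  int root = T.newNode();
  stack.push_back(Frame{root, 0, nTotal});

  while (!stack.empty()) {
    Frame f = stack.back(); stack.pop_back();
    const int nNode = f.end - f.begin;

    std::fill(cntAll.begin(), cntAll.end(), 0);
    for (int i = f.begin; i < f.end; ++i) cntAll[y[idx[i]]]++;
    const int maj = majorityClass(cntAll);
    const bool pure = (cntAll[maj] == nNode);

    if (pure || nNode < std::max(2, nodesize)) {
      T.pred[f.node] = maj;
      continue;
    }

    const double gP = giniFromCounts(cntAll, nNode);
    sampleFeatures(pool, d, mtry, cand);

    int bestVar = -1; double bestThr = 0.0, bestDec = 0.0;
    for (int k = 0; k < mtry; ++k) {
      const int j = cand[k];
      buf.clear();
      for (int i = f.begin; i < f.end; ++i)
        buf.push_back(std::make_pair(X(idx[i], j), y[idx[i]]));
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue; // constant in node

      // incremental sum-of-squares Gini: gini = 1 - ssq / nside^2
      std::fill(cntL.begin(), cntL.end(), 0);
      for (int c = 0; c < nClass; ++c) cntR[c] = cntAll[c];
      double ssqL = 0.0, ssqR = 0.0;
      for (int c = 0; c < nClass; ++c)
        ssqR += (double)cntAll[c] * cntAll[c];
      for (int i = 0; i < nNode - 1; ++i) {
        const int cls = buf[i].second;
        ssqL += 2.0 * cntL[cls] + 1.0;
        ssqR -= 2.0 * cntR[cls] - 1.0;
        cntL[cls]++; cntR[cls]--;
        if (buf[i].first == buf[i + 1].first) continue;
        const double nL = i + 1, nR = nNode - nL;
        const double decNode = gP
          - (nL / nNode) * (1.0 - ssqL / (nL * nL))
          - (nR / nNode) * (1.0 - ssqR / (nR * nR));
        if (decNode > bestDec + 1e-12) {
          bestDec = decNode;
          bestVar = j;
          bestThr = (buf[i].first + buf[i + 1].first) / 2.0;
        }
      }
    }

    if (bestVar < 0 || bestDec <= 1e-12) { // no admissible split among mtry
      T.pred[f.node] = maj;
      continue;
    }

    // partition idx[begin,end) by x <= thr, preserving relative order
    std::vector<int> lo, hi;
    for (int i = f.begin; i < f.end; ++i) {
      if (X(idx[i], bestVar) <= bestThr) lo.push_back(idx[i]);
      else hi.push_back(idx[i]);
    }
    for (size_t i = 0; i < lo.size(); ++i) idx[f.begin + i] = lo[i];
    for (size_t i = 0; i < hi.size(); ++i) idx[f.begin + lo.size() + i] = hi[i];

    T.var[f.node] = bestVar;
    T.split[f.node] = bestThr;
    T.dec[f.node] = bestDec * (double)nNode / nTotal;
    const int lid = T.newNode(), rid = T.newNode();
    T.left[f.node] = lid; T.right[f.node] = rid;
    const int mid = f.begin + (int)lo.size();
    stack.push_back(Frame{rid, mid, f.end});
    stack.push_back(Frame{lid, f.begin, mid});
  }
}

struct TreeView {
  IntegerVector var, left, right, pred;
  NumericVector split;
  explicit TreeView(const List& t)
    : var(t["var"]), left(t["left"]), right(t["right"]), pred(t["pred"]),
      split(t["split"]) {}

  int predictRow(const NumericMatrix& X, int i) const {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
    return pred[node];
  }
  // predict with feature j's value overridden by `value`
  int predictRowSwap(const NumericMatrix& X, int i, int j, double value) const {
    int node = 0;
    while (var[node] >= 0) {
      const double x = (var[node] == j) ? value : X(i, var[node]);
      node = (x <= split[node]) ? left[node] : right[node];
    }
    return pred[node];
  }
};

} // namespace

// [[Rcpp::export]]
List rf_fit(NumericMatrix X, IntegerVector y, int nClass, int ntree,
            int mtry, int nodesize) {
  const int n = X.nrow();
  RNGScope scope;
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);

  std::vector<int> bootstrap(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      bootstrap[i] = k;
      inbag(k, t)++;
    }
    TreeBuild T;
    growTree(X, y, nClass, bootstrap, mtry, nodesize, T);
    trees[t] = List::create(
      _["var"] = wrap(T.var), _["split"] = wrap(T.split),
      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
      _["pred"] = wrap(T.pred), _["dec"] = wrap(T.dec));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// Out-of-bag vote matrix: votes[i, c] = number of trees for which sample i
// is out of bag and which predict class c for it.
// [[Rcpp::export]]
IntegerMatrix rf_oob_votes(List trees, NumericMatrix X, IntegerMatrix inbag,
                           int nClass) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nClass);
  for (int t = 0; t < ntree; ++t) {
    TreeView T(trees[t]);
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) votes(i, T.predictRow(X, i))++;
  }
  return votes;
}

// Per-tree out-of-bag permutation importance (mean decrease in accuracy).
// For each tree and each feature used by that tree, the feature's values are
// permuted among the tree's OOB samples only; features unused by a tree
// contribute exactly 0 for that tree and consume no randomness. Trees with an
// empty OOB set are skipped and the mean is taken over the remaining trees.
// [[Rcpp::export]]
NumericVector rf_mda(List trees, NumericMatrix X, IntegerVector y,
                     IntegerMatrix inbag) {
  const int n = X.nrow(), d = X.ncol(), ntree = trees.size();
  RNGScope scope;
  NumericVector vi(d);
  std::vector<int> oob;
  std::vector<int> baseline;
  std::vector<double> permuted;
  std::vector<bool> used(d);

  int validTrees = 0;
  for (int t = 0; t < ntree; ++t) {
    TreeView T(trees[t]);
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m == 0) continue;
    validTrees++;

    baseline.resize(m);
    int base = 0;
    for (int k = 0; k < m; ++k) {
      baseline[k] = T.predictRow(X, oob[k]);
      if (baseline[k] == y[oob[k]]) base++;
    }

    std::fill(used.begin(), used.end(), false);
    for (int node = 0; node < T.var.size(); ++node)
      if (T.var[node] >= 0) used[T.var[node]] = true;

    for (int j = 0; j < d; ++j) {
      if (!used[j]) continue;
      permuted.resize(m);
      for (int k = 0; k < m; ++k) permuted[k] = X(oob[k], j);
      for (int k = m - 1; k > 0; --k) { // Fisher-Yates, R RNG
        int r = (int)(unif_rand() * (k + 1));
        if (r > k) r = k;
        std::swap(permuted[k], permuted[r]);
      }
      int after = 0;
      for (int k = 0; k < m; ++k)
        if (T.predictRowSwap(X, oob[k], j, permuted[k]) == y[oob[k]]) after++;
      vi[j] += (double)(base - after) / m;
    }
  }
  if (validTrees > 0)
    for (int j = 0; j < d; ++j) vi[j] /= validTrees;
  return vi;
}

// [[Rcpp::export]]
IntegerVector rf_predict(List trees, NumericMatrix X, int nClass) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nClass);
  for (int t = 0; t < ntree; ++t) {
    TreeView T(trees[t]);
    for (int i = 0; i < n; ++i) votes(i, T.predictRow(X, i))++;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int c = 1; c < nClass; ++c)
      if (votes(i, c) > votes(i, best)) best = c;
    out[i] = best;
  }
  return out;
}
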