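// Random-forest regression engine for the genotype prediction harness.
//
// Deliberately specialised to the harness contract: binary 0/1 features,
// bootstrap of the training rows per tree, mtry candidate features per
// split (best sum-of-squares split among them; a node with no valid split
// or fewer observations than the minimum node size is terminal, predicting
// its mean). All randomness flows through R's RNG so results are fully
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int randInt(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct Tree {
  std::vector<int> feat;  // split feature, -1 for terminal
  std::vector<int> kid0, kid1;
  std::vector<double> pred;
};

static void buildNode(const IntegerMatrix& X, const double* y,
                      std::vector<int>& idx, int lo, int hi,
                      int mtry, int nodesize, Tree& tr, int node,
                      std::vector<int>& featBuf) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    const double v = y[idx[i]];
    sum += v; sum2 += v * v;
  }
  tr.pred[node] = sum / n;
  if (n <= nodesize || sum2 - sum * (sum / n) < 1e-12) {
    tr.feat[node] = -1;
    return;
  }
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) featBuf[j] = j;
  for (int j = 0; j < mtry; ++j) {
    const int r = j + randInt(p - j);
    std::swap(featBuf[j], featBuf[r]);
  }
  int bestF = -1;
  double bestCrit = 1e-12;
  for (int j = 0; j < mtry; ++j) {
    const int f = featBuf[j];
    double s1 = 0.0; int n1 = 0;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], f) == 1) { s1 += y[idx[i]]; ++n1; }
    if (n1 == 0 || n1 == n) continue;
    const double s0 = sum - s1;
    const int n0 = n - n1;
    const double crit = s0 * s0 / n0 + s1 * s1 / n1 - sum * sum / n;
    if (crit > bestCrit) { bestCrit = crit; bestF = f; }
  }
  if (bestF < 0) { tr.feat[node] = -1; return; }
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], bestF) == 0) std::swap(idx[i], idx[mid++]);
  tr.feat[node] = bestF;
  const int c0 = (int)tr.feat.size();
  tr.feat.push_back(0); tr.feat.push_back(0);
  tr.kid0.push_back(-1); tr.kid0.push_back(-1);
  tr.kid1.push_back(-1); tr.kid1.push_back(-1);
  tr.pred.push_back(0.0); tr.pred.push_back(0.0);
  tr.kid0[node] = c0;
  tr.kid1[node] = c0 + 1;
  buildNode(X, y, idx, lo, mid, mtry, nodesize, tr, c0, featBuf);
  buildNode(X, y, idx, mid, hi, mtry, nodesize, tr, c0 + 1, featBuf);
}

static void fitForest(const IntegerMatrix& X, const double* y,
                      const std::vector<int>& train, int ntree, int mtry,
                      int nodesize, std::vector<Tree>& forest) {
  const int n = (int)train.size();
  std::vector<int> idx(n);
  std::vector<int> featBuf(X.ncol());
  forest.assign(ntree, Tree());
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = train[randInt(n)];  // bootstrap
    Tree& tr = forest[t];
    tr.feat.assign(1, 0);
    tr.kid0.assign(1, -1);
    tr.kid1.assign(1, -1);
    tr.pred.assign(1, 0.0);
    buildNode(X, y, idx, 0, n, mtry, nodesize, tr, 0, featBuf);
  }
}

static inline double predictRow(const IntegerMatrix& X, int row,
                                const Tree& tr) {
  int node = 0;
  while (tr.feat[node] >= 0)
    node = X(row, tr.feat[node]) == 0 ? tr.kid0[node] : tr.kid1[node];
  return tr.pred[node];
}

// one fold assignment: squared errors pooled over the k held-out folds
static double cvRmseOnce(const IntegerMatrix& X, const double* y, int k,
                         int ntree, int mtry, int nodesize,
                         std::vector<int>& perm) {
  const int n = (int)perm.size();
  for (int i = n - 1; i > 0; --i) {
    const int j = randInt(i + 1);
    std::swap(perm[i], perm[j]);
  }
  double sse = 0.0;
  std::vector<Tree> forest;
  std::vector<int> train;
  train.reserve(n);
  for (int f = 0; f < k; ++f) {
    const int lo = (int)((long long)n * f / k);
    const int hi = (int)((long long)n * (f + 1) / k);
    train.clear();
    for (int i = 0; i < n; ++i)
      if (i < lo || i >= hi) train.push_back(perm[i]);
    fitForest(X, y, train, ntree, mtry, nodesize, forest);
    for (int i = lo; i < hi; ++i) {
      double pr = 0.0;
      for (int t = 0; t < ntree; ++t) pr += predictRow(X, perm[i], forest[t]);
      pr /= ntree;
      const double e = y[perm[i]] - pr;
      sse += e * e;
    }
  }
  return std::sqrt(sse / n);
}

// [[Rcpp::export(name = ".forestCvRmse")]]
NumericVector forest_cv_rmse(IntegerMatrix X, NumericVector y, int k,
                             int nresample, int ntree, int mtry,
                             int nodesize) {
  const int n = y.size();
  if (X.nrow() != n) stop("feature rows and outcome length disagree");
  if (k < 2 || k > n) stop("invalid number of folds");
  NumericVector out(nresample);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int r = 0; r < nresample; ++r)
    out[r] = cvRmseOnce(X, REAL(y), k, ntree, mtry, nodesize, perm);
  return out;
}

// [[Rcpp::export(name = ".forestPermNull")]]
NumericVector forest_perm_null(IntegerMatrix X, NumericVector y, int B,
                               int k, int nresample, int ntree, int mtry,
                               int nodesize) {
  const int n = y.size();
  if (X.nrow() != n) stop("feature rows and outcome length disagree");
  NumericVector out(B);
  NumericVector yp = clone(y);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) {
      const int j = randInt(i + 1);
      std::swap(yp[i], yp[j]);
    }
    double acc = 0.0;
    for (int r = 0; r < nresample; ++r)
      acc += cvRmseOnce(X, REAL(yp), k, ntree, mtry, nodesize, perm);
    out[b] = acc / nresample;
  }
  return out;
}

// [[Rcpp::export(name = ".forestFitPredict")]]
NumericVector forest_fit_predict(IntegerMatrix Xtrain, NumericVector y,
                                 IntegerMatrix Xtest, int ntree, int mtry,
                                 int nodesize) {
  const int n = y.size();
  if (Xtrain.nrow() != n) stop("feature rows and outcome length disagree");
  if (Xtest.ncol() != Xtrain.ncol()) stop("feature count mismatch");
  std::vector<int> train(n);
  for (int i = 0; i < n; ++i) train[i] = i;
  std::vector<Tree> forest;
  fitForest(Xtrain, REAL(y), train, ntree, mtry, nodesize, forest);
  NumericVector out(Xtest.nrow());
  for (int i = 0; i < Xtest.nrow(); ++i) {
    double pr = 0.0;
    for (int t = 0; t < ntree; ++t) pr += predictRow(Xtest, i, forest[t]);
    out[i] = pr / ntree;
  }
  return out;
}
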