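#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Random-forest internals specialised for genotype dosage matrices.
// Dosage features take values in {0, 1, 2}, so the only informative split
// thresholds are 0.5 and 1.5.  Fractional (mean-imputed) dosages at
// prediction time route through the same comparisons.  All randomness is
// drawn from R's RNG stream so set.seed() makes training reproducible.

namespace {

struct Job {
  int start, end, depth, node;
};

// weighted gini impurity contribution of a node of size n with n1 positives
inline double wgini(double n, double n1) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * n * p * (1.0 - p);
}

inline int runif_int(int n) {
  int j = (int)std::floor(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

} // namespace

// Grow `ntree` classification trees on bootstrap resamples of the rows of
// X (samples x markers, dosages) against 0/1 labels y.  Each tree is a
// numeric matrix with one row per node and columns
// (feature, threshold, left, right, pred); feature == -1 marks a leaf.
// Indices are 0-based and only dereferenced in C++.
// [[Rcpp::export]]
List forest_grow(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                 int min_node, int max_depth) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List forest(ntree);
  std::vector<int> pool(p);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n);

    std::vector<double> nfeat(1, -1.0), nthr(1, 0.0), npred(1, 0.0);
    std::vector<int> nleft(1, -1), nright(1, -1);
    std::vector<Job> stack;
    stack.push_back(Job{0, n, 0, 0});

    while (!stack.empty()) {
      Job jb = stack.back();
      stack.pop_back();
      const int nn = jb.end - jb.start;
      int n1 = 0;
      for (int i = jb.start; i < jb.end; ++i) n1 += y[idx[i]];
      npred[jb.node] = nn > 0 ? (double)n1 / nn : 0.0;

      bool leaf = nn < min_node || n1 == 0 || n1 == nn ||
                  jb.depth >= max_depth;
      int best_f = -1;
      double best_thr = 0.0, best_score = R_PosInf;

      if (!leaf) {
        for (int i = 0; i < p; ++i) pool[i] = i;
        for (int i = 0; i < mtry; ++i) {
          int j = i + runif_int(p - i);
          std::swap(pool[i], pool[j]);
          const int f = pool[i];
          // one pass: counts left of both candidate thresholds
          int nA = 0, nA1 = 0, nB = 0, nB1 = 0;
          for (int k = jb.start; k < jb.end; ++k) {
            const double x = X(idx[k], f);
            const int yy = y[idx[k]];
            if (x <= 0.5) { ++nA; nA1 += yy; }
            if (x <= 1.5) { ++nB; nB1 += yy; }
          }
          if (nA > 0 && nA < nn) {
            double s = wgini(nA, nA1) + wgini(nn - nA, n1 - nA1);
            if (s < best_score) { best_score = s; best_f = f; best_thr = 0.5; }
          }
          if (nB > 0 && nB < nn) {
            double s = wgini(nB, nB1) + wgini(nn - nB, n1 - nB1);
            if (s < best_score) { best_score = s; best_f = f; best_thr = 1.5; }
          }
        }
      }

      if (best_f < 0) continue; // stays a leaf

      // partition idx[start, end) by x <= thr
      int mid = jb.start;
      for (int k = jb.start; k < jb.end; ++k) {
        if (X(idx[k], best_f) <= best_thr) {
          std::swap(idx[k], idx[mid]);
          ++mid;
        }
      }

      const int lid = (int)nfeat.size(), rid = lid + 1;
      nfeat[jb.node] = best_f;
      nthr[jb.node] = best_thr;
      nleft[jb.node] = lid;
      nright[jb.node] = rid;
      for (int c = 0; c < 2; ++c) {
        nfeat.push_back(-1.0);
        nthr.push_back(0.0);
        npred.push_back(0.0);
        nleft.push_back(-1);
        nright.push_back(-1);
      }
      stack.push_back(Job{jb.start, mid, jb.depth + 1, lid});
      stack.push_back(Job{mid, jb.end, jb.depth + 1, rid});
    }

    const int nnode = (int)nfeat.size();
    NumericMatrix tr(nnode, 5);
    for (int i = 0; i < nnode; ++i) {
      tr(i, 0) = nfeat[i];
      tr(i, 1) = nthr[i];
      tr(i, 2) = nleft[i];
      tr(i, 3) = nright[i];
      tr(i, 4) = npred[i];
    }
    forest[t] = tr;
  }
  return forest;
}

// Fraction of trees whose leaf majority votes class 1, per row of X.
// A leaf with class-1 proportion >= 0.5 votes 1.
// [[Rcpp::export]]
NumericVector forest_vote_fraction(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr(node, 0) >= 0) {
        const int f = (int)tr(node, 0);
        node = (X(i, f) <= tr(node, 1)) ? (int)tr(node, 2)
                                        : (int)tr(node, 3);
      }
      if (tr(node, 4) >= 0.5) out[i] += 1.0;
    }
  }
  if (T > 0) for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
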