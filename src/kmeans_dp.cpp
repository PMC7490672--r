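#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact univariate weighted k-means by dynamic programming.
// Points must be sorted ascending; optimal clusters are contiguous runs,
// so D[k][j] = min_{s} D[k-1][s-1] + SSE(s..j). The inner minimisation is
// filled by divide-and-conquer using the monotonicity of the argmin,
// giving O(k n log n) instead of O(k n^2).

typedef long double ld;

namespace {

struct Prefix {
  std::vector<ld> w, wx, wxx;
  void init(const NumericVector& x, const NumericVector& wt) {
    int n = x.size();
    w.assign(n + 1, 0.0L);
    wx.assign(n + 1, 0.0L);
    wxx.assign(n + 1, 0.0L);
    for (int i = 0; i < n; ++i) {
      w[i + 1] = w[i] + (ld)wt[i];
      wx[i + 1] = wx[i] + (ld)wt[i] * (ld)x[i];
      wxx[i + 1] = wxx[i] + (ld)wt[i] * (ld)x[i] * (ld)x[i];
    }
  }
  // within-cluster sum of squares of points i..j (0-based, inclusive)
  double sse(int i, int j) const {
    ld W = w[j + 1] - w[i];
    if (W <= 0) return 0.0;
    ld Sx = wx[j + 1] - wx[i];
    ld Sxx = wxx[j + 1] - wxx[i];
    ld c = Sxx - Sx * Sx / W;
    return c > 0 ? (double)c : 0.0;
  }
};

void fill_row(const Prefix& pre, const std::vector<double>& prev,
              std::vector<double>& cur, std::vector<int>& back,
              int row_k, int jlo, int jhi, int slo, int shi) {
  if (jlo > jhi) return;
  int jm = jlo + (jhi - jlo) / 2;
  double best = R_PosInf;
  int args = slo;
  int sup = std::min(jm, shi);
  for (int s = slo; s <= sup; ++s) {
    if (s < row_k - 1) continue;  // need k-1 points before the last cluster
    double v = prev[s - 1] + pre.sse(s, jm);
    if (v < best) { best = v; args = s; }
  }
  cur[jm] = best;
  back[jm] = args;
  fill_row(pre, prev, cur, back, row_k, jlo, jm - 1, slo, args);
  fill_row(pre, prev, cur, back, row_k, jm + 1, jhi, args, shi);
}

}  // namespace

// [[Rcpp::export]]
List kmeans_dp_cpp(NumericVector x, NumericVector w, int k) {
  int n = x.size();
  if (k < 1 || k > n) stop("k must be between 1 and the number of points");
  for (int i = 1; i < n; ++i) {
    if (x[i] < x[i - 1]) stop("x must be sorted ascending");
  }
  Prefix pre;
  pre.init(x, w);

  std::vector<double> prev(n), cur(n);
  std::vector<std::vector<int> > back(k + 1, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) prev[j] = pre.sse(0, j);
  for (int kk = 2; kk <= k; ++kk) {
    fill_row(pre, prev, cur, back[kk], kk, kk - 1, n - 1, 1, n - 1);
    for (int j = 0; j < kk - 1; ++j) cur[j] = R_PosInf;
    prev = cur;
  }
  double total = (k == 1) ? pre.sse(0, n - 1) : prev[n - 1];

  // backtrack cluster start indices
  IntegerVector cluster(n);
  NumericVector centers(k), withinss(k);
  int hi = n - 1;
  for (int kk = k; kk >= 1; --kk) {
    int lo = (kk == 1) ? 0 : back[kk][hi];
    ld W = pre.w[hi + 1] - pre.w[lo];
    ld Sx = pre.wx[hi + 1] - pre.wx[lo];
    centers[kk - 1] = (W > 0) ? (double)(Sx / W) : x[lo];
    withinss[kk - 1] = pre.sse(lo, hi);
    for (int j = lo; j <= hi; ++j) cluster[j] = kk;
    hi = lo - 1;
  }
  return List::create(_["cluster"] = cluster, _["centers"] = centers,
                      _["withinss"] = withinss, _["tot_withinss"] = total);
}
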