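#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pearson correlation; returns NA when either side is constant.
static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  const size_t n = a.size();
  double ma = 0.0, mb = 0.0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0.0, saa = 0.0, sbb = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Cross-map skill over a schedule of contiguous-prefix library sizes.
//
// embed: n_anchors x E delay embedding of the EFFECT series (rows are
//        anchors in time order). x: value of the CAUSE series at each
//        anchor. For each library size L the neighbor library is the first
//        L anchors; predictions are made for every anchor (leave-one-out
//        when the target anchor sits inside the library); each anchor's k
//        nearest library neighbors get exponential weights
//        w_i = exp(-d_i / d_1) (uniform over exact-zero-distance neighbors
//        when d_1 == 0), and the skill is Pearson(x, x_hat) over all
//        anchors. Keeping the prediction set fixed while the library grows
//        is what makes the convergence delta a clean diagnostic: for
//        unrelated series rho stays near 0 at every library size.
// [[Rcpp::export(name = ".ccm_skill")]]
NumericVector ccm_skill(NumericMatrix embed, NumericVector x,
                        IntegerVector lib_sizes, int k) {
  const int n = embed.nrow(), E = embed.ncol();
  if (x.size() != n) stop("embed/x length mismatch");
  NumericVector rho(lib_sizes.size());

  std::vector<double> d(n);
  std::vector<int> idx(n);
  for (int li = 0; li < lib_sizes.size(); ++li) {
    const int L = lib_sizes[li];
    if (L < k + 1 || L > n) { rho[li] = NA_REAL; continue; }
    std::vector<double> xhat(n), xobs(n);
    for (int t = 0; t < n; ++t) {
      int m = 0;
      for (int j = 0; j < L; ++j) {
        if (j == t) continue;
        double s = 0.0;
        for (int e = 0; e < E; ++e) {
          const double diff = embed(t, e) - embed(j, e);
          s += diff * diff;
        }
        d[m] = std::sqrt(s);
        idx[m] = j;
        ++m;
      }
      const int kk = std::min(k, m);
      // partial sort of neighbor indices by distance, ties by time order
      std::vector<int> ord(m);
      for (int j = 0; j < m; ++j) ord[j] = j;
      std::partial_sort(ord.begin(), ord.begin() + kk, ord.end(),
                        [&](int a, int b) {
                          if (d[a] != d[b]) return d[a] < d[b];
                          return idx[a] < idx[b];
                        });
      const double d1 = d[ord[0]];
      double wsum = 0.0, est = 0.0;
      if (d1 <= 0.0) {
        // all weight uniformly on the zero-distance neighbors
        for (int q = 0; q < kk; ++q) {
          if (d[ord[q]] > 0.0) break;
          est += x[idx[ord[q]]];
          wsum += 1.0;
        }
      } else {
        for (int q = 0; q < kk; ++q) {
          const double w = std::exp(-d[ord[q]] / d1);
          est += w * x[idx[ord[q]]];
          wsum += w;
        }
      }
      xhat[t] = est / wsum;
      xobs[t] = x[t];
    }
    rho[li] = pearson(xobs, xhat);
  }
  return rho;
}
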