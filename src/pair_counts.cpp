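#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs stable-REO mining over the reference (epithelial) samples.
//
// xe: samples x genes (transposed so each gene's values are contiguous).
// For every unordered gene pair {i, j} count the samples with strictly
// x_i > x_j and strictly x_i < x_j (ties support neither direction). A pair
// is emitted, oriented so gene_a carries the majority direction, when the
// concordant fraction n_gt / n_samples >= threshold.
//
// Memory is O(1) counters per pair plus the emitted stable pairs; a pair is
// abandoned as soon as both directions have exceeded the discordant budget
// floor(n * (1 - threshold)), which makes mining on weakly ordered
// backgrounds close to linear in the number of pairs.
//
// [[Rcpp::export(name = ".stable_pair_mine")]]
DataFrame stable_pair_mine(NumericMatrix xe, double threshold) {
  const int n = xe.nrow();   // samples
  const int g = xe.ncol();   // genes
  if (n < 1) stop("no samples");
  // budget: discordant-or-tied samples tolerated while still reaching
  // ceil-free fraction >= threshold: n_gt >= threshold * n
  const double need = threshold * (double)n;
  const int budget = n - (int)std::ceil(need - 1e-9);

  std::vector<int> out_a, out_b, out_gt, out_lt;
  const double* base = REAL(xe);

  for (int i = 0; i < g - 1; ++i) {
    const double* xi = base + (size_t)i * n;
    for (int j = i + 1; j < g; ++j) {
      const double* xj = base + (size_t)j * n;
      int gt = 0, lt = 0;
      bool alive = true;
      for (int s = 0; s < n; ++s) {
        const double a = xi[s], b = xj[s];
        if (a > b) ++gt; else if (a < b) ++lt;
        // both orientations dead once each has > budget non-supporting samples
        const int s1 = s + 1;
        if (s1 - gt > budget && s1 - lt > budget) { alive = false; break; }
      }
      if (!alive) continue;
      if (gt >= need - 1e-9) {
        out_a.push_back(i + 1); out_b.push_back(j + 1);
        out_gt.push_back(gt);  out_lt.push_back(lt);
      } else if (lt >= need - 1e-9) {
        out_a.push_back(j + 1); out_b.push_back(i + 1);
        out_gt.push_back(lt);  out_lt.push_back(gt);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["ia"] = out_a, _["ib"] = out_b,
                           _["n_gt"] = out_gt, _["n_lt"] = out_lt);
}

// Per-pair strict ordering counts for given (oriented) pairs over a sample
// block: returns counts of x_a > x_b and x_a < x_b per pair.
// x: samples x genes; ia, ib: 1-based gene indices.
// [[Rcpp::export(name = ".pair_order_counts")]]
DataFrame pair_order_counts(NumericMatrix x, IntegerVector ia,
                            IntegerVector ib) {
  const int n = x.nrow();
  const int g = x.ncol();
  const int p = ia.size();
  if (ib.size() != p) stop("ia and ib differ in length");
  IntegerVector gt(p), lt(p);
  const double* base = REAL(x);
  for (int k = 0; k < p; ++k) {
    const int i = ia[k] - 1, j = ib[k] - 1;
    if (i < 0 || i >= g || j < 0 || j >= g) stop("gene index out of range");
    const double* xi = base + (size_t)i * n;
    const double* xj = base + (size_t)j * n;
    int cgt = 0, clt = 0;
    for (int s = 0; s < n; ++s) {
      if (xi[s] > xj[s]) ++cgt; else if (xi[s] < xj[s]) ++clt;
    }
    gt[k] = cgt; lt[k] = clt;
  }
  return DataFrame::create(_["n_gt"] = gt, _["n_lt"] = lt);
}
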