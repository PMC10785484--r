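#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Integrated EHH around core sites. Mirrors the R-level
// ehh_curve()/ihh() pair exactly: EHH is the fraction of haplotype pairs
// identical over the spanned alleles (core included), the curve truncates at
// the first value below the cutoff (or the chromosome end), and the final
// segment is linearly interpolated to the cutoff crossing when requested.

static double span_hh(const std::vector<int> &g, int n) {
  // g holds group ids in 1..n
  std::vector<int> tab(n + 1, 0);
  for (int i = 0; i < n; ++i) tab[g[i]]++;
  double s = 0.0;
  for (int i = 1; i <= n; ++i) s += (double)tab[i] * (tab[i] - 1);
  return s / ((double)n * (n - 1));
}

static void refine(std::vector<int> &g, const IntegerMatrix &haps, int site,
                   int n) {
  // new group id = dense id of (old id, allele); allele in {0,1}
  std::vector<int> map(2 * (n + 1), 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * g[i] + haps(i, site);
    if (map[key] == 0) map[key] = ++next;
    g[i] = map[key];
  }
}

static double one_side(const IntegerMatrix &haps, int core, int step,
                       const NumericVector &pos, double cutoff,
                       bool interpolate, int n, int M) {
  std::vector<int> g(n, 1);
  double prev_d = 0.0, prev_e = 1.0, integral = 0.0;
  int m = core;
  bool first = true;
  while (true) {
    int m2;
    if (first) { m2 = core; first = false; }
    else {
      m2 = m + step;
      if (m2 < 0 || m2 >= M) break;
      m = m2;
    }
    refine(g, haps, m2, n);
    double e = span_hh(g, n);
    double d = std::abs(pos[m2] - pos[core]);
    if (e < cutoff) {
      if (interpolate && prev_e > cutoff) {
        double frac = (prev_e - cutoff) / (prev_e - e);
        double dc = prev_d + frac * (d - prev_d);
        integral += (dc - prev_d) * (prev_e + cutoff) / 2.0;
      } else if (!interpolate) {
        // truncate at the last point at or above the cutoff: nothing to add
      } else {
        // prev_e == cutoff exactly: crossing is at prev_d
      }
      return integral;
    }
    integral += (d - prev_d) * (prev_e + e) / 2.0;
    prev_d = d; prev_e = e;
  }
  return integral;
}

// [[Rcpp::export(name = ".ihh_scan_cpp")]]
NumericVector ihh_scan_cpp(IntegerMatrix haps, NumericVector positions,
                           IntegerVector cores, double ehh_cutoff,
                           bool interpolate) {
  const int n = haps.nrow(), M = haps.ncol();
  if (n < 2) stop("EHH needs at least 2 haplotypes");
  NumericVector out(cores.size());
  for (int c = 0; c < cores.size(); ++c) {
    int core = cores[c]; // 0-based
    out[c] = one_side(haps, core, -1, positions, ehh_cutoff, interpolate, n, M) +
             one_side(haps, core, +1, positions, ehh_cutoff, interpolate, n, M);
  }
  return out;
}
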