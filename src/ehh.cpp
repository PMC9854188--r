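#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haplotype homozygosity of a grouping: sum_h C(n_h,2) / C(n,2).
static double homozygosity(const std::vector<int>& group, int n_groups,
                           int n) {
  std::vector<int> cnt(n_groups, 0);
  for (int g : group) cnt[g]++;
  double num = 0.0;
  for (int c : cnt) num += 0.5 * c * (c - 1.0);
  return num / (0.5 * n * (n - 1.0));
}

// Refine groups by the alleles of marker j; returns new group count.
// H is haplotype x marker, 0/1.
static int refine(const IntegerMatrix& H, int j, std::vector<int>& group,
                  int n_groups) {
  int n = group.size();
  std::vector<int> remap(2 * n_groups, -1);
  int next = 0;
  for (int i = 0; i < n; i++) {
    int key = 2 * group[i] + H(i, j);
    if (remap[key] < 0) remap[key] = next++;
    group[i] = remap[key];
  }
  return next;
}

// Extend EHH from `core` in direction `dir` (+1/-1) within marker index
// range [lo, hi] (inclusive, same chromosome). Appends (distance, ehh)
// pairs; starts from groups defined by the core allele so the extended
// haplotype spans core..j. Stops past a recorded value below `floor`,
// at an inter-marker gap > max_gap, or at the range end.
static void extend_side(const IntegerMatrix& H, const NumericVector& pos,
                        int core, int dir, int lo, int hi, double floor_,
                        double max_gap, std::vector<double>& dist,
                        std::vector<double>& ehh) {
  int n = H.nrow();
  std::vector<int> group(n);
  for (int i = 0; i < n; i++) group[i] = H(i, core);
  int n_groups = 2;
  double prev_pos = pos[core];
  for (int j = core + dir; j >= lo && j <= hi; j += dir) {
    if (std::abs(pos[j] - prev_pos) > max_gap) break;
    n_groups = refine(H, j, group, n_groups);
    double e = homozygosity(group, n_groups, n);
    dist.push_back(pos[j] - pos[core]);
    ehh.push_back(e);
    if (e < floor_) break;
    prev_pos = pos[j];
  }
}

// Trapezoidal integral of an EHH decay over |distance|, starting at
// (0, 1); points with ehh < floor are excluded (truncation).
static double trapz_side(const std::vector<double>& dist,
                         const std::vector<double>& ehh, double floor_) {
  double area = 0.0, d_prev = 0.0, e_prev = 1.0;
  for (size_t k = 0; k < dist.size(); k++) {
    if (ehh[k] < floor_) break;
    double d = std::abs(dist[k]);
    area += (d - d_prev) * 0.5 * (e_prev + ehh[k]);
    d_prev = d;
    e_prev = ehh[k];
  }
  return area;
}

// [[Rcpp::export]]
List cpp_ehh_profile(IntegerMatrix H, NumericVector pos, int core0,
                     int lo0, int hi0, double truncation, double max_gap) {
  std::vector<double> dl, el, dr, er;
  extend_side(H, pos, core0, -1, lo0, hi0, truncation, max_gap, dl, el);
  extend_side(H, pos, core0, +1, lo0, hi0, truncation, max_gap, dr, er);
  int nl = dl.size(), nr = dr.size();
  NumericVector dist(nl + 1 + nr), ehh(nl + 1 + nr);
  for (int k = 0; k < nl; k++) {           // left side, farthest first
    dist[nl - 1 - k] = dl[k];
    ehh[nl - 1 - k] = el[k];
  }
  dist[nl] = 0.0;
  ehh[nl] = 1.0;
  for (int k = 0; k < nr; k++) {
    dist[nl + 1 + k] = dr[k];
    ehh[nl + 1 + k] = er[k];
  }
  return List::create(_["distance"] = dist, _["ehh"] = ehh,
                      _["core_offset"] = nl + 1);
}

// iHH at every marker: both-sided truncated trapezoid, chromosome bounds
// given per marker by lo/hi (0-based, inclusive).
// [[Rcpp::export]]
NumericVector cpp_ihh_all(IntegerMatrix H, NumericVector pos,
                          IntegerVector lo, IntegerVector hi,
                          double truncation, double max_gap) {
  int m = H.ncol();
  NumericVector out(m);
  std::vector<double> d, e;
  for (int core = 0; core < m; core++) {
    double area = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      d.clear();
      e.clear();
      extend_side(H, pos, core, dir, lo[core], hi[core], truncation,
                  max_gap, d, e);
      area += trapz_side(d, e, truncation);
    }
    out[core] = area;
  }
  return out;
}
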