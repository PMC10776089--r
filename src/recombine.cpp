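#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>
using namespace Rcpp;

// Splice two tract lists (sorted end positions + ancestries) at the given
// crossover positions, starting from homolog 1 when start_first != 0.
// Returns the maximal-merged gamete tract list. Single O(n) sweep over the
// merged event positions; ties (crossover exactly on a tract boundary)
// collapse into one event.
// [[Rcpp::export(name = ".recombine_cpp")]]
List recombine_cpp(NumericVector ends1, IntegerVector anc1,
                   NumericVector ends2, IntegerVector anc2,
                   NumericVector cx_in, int start_first) {
  std::vector<double> cx(cx_in.begin(), cx_in.end());
  std::sort(cx.begin(), cx.end());
  const int n1 = ends1.size(), n2 = ends2.size(), nc = (int)cx.size();
  const double L = ends1[n1 - 1];
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> out_ends;
  std::vector<int> out_anc;
  out_ends.reserve(n1 + n2 + nc);
  out_anc.reserve(n1 + n2 + nc);
  int i1 = 0, i2 = 0, ic = 0;
  bool from_first = start_first != 0;
  double pos = 0.0;
  while (pos < L) {
    double e1 = ends1[i1], e2 = ends2[i2];
    double ec = ic < nc ? cx[ic] : inf;
    double nxt = std::min(e1, std::min(e2, ec));
    if (nxt > L) nxt = L;
    int a = from_first ? anc1[i1] : anc2[i2];
    if (nxt > pos) {
      if (!out_anc.empty() && out_anc.back() == a) {
        out_ends.back() = nxt;
      } else {
        out_ends.push_back(nxt);
        out_anc.push_back(a);
      }
    }
    if (e1 == nxt && i1 < n1 - 1) ++i1;
    if (e2 == nxt && i2 < n2 - 1) ++i2;
    if (ec == nxt) { ++ic; from_first = !from_first; }
    pos = nxt;
  }
  if (!out_ends.empty()) out_ends.back() = L;
  return List::create(_["ends"] = NumericVector(out_ends.begin(), out_ends.end()),
                      _["anc"] = IntegerVector(out_anc.begin(), out_anc.end()));
}

// Genetic length carried per ancestry (1..3) across a flat list of
// haplotypes, each a list(ends, anc).
// [[Rcpp::export(name = ".anc_lengths_cpp")]]
NumericVector anc_lengths_cpp(List haps) {
  NumericVector tot(3);
  for (int i = 0; i < haps.size(); ++i) {
    List h = haps[i];
    NumericVector ends = h["ends"];
    IntegerVector anc = h["anc"];
    double prev = 0.0;
    for (int k = 0; k < ends.size(); ++k) {
      tot[anc[k] - 1] += ends[k] - prev;
      prev = ends[k];
    }
  }
  return tot;
}
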