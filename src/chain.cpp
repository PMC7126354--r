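#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
#include <vector>
using namespace Rcpp;

// Chain recursion over the putative exons of one (contig, strand,
// target) group. Exons arrive sorted in translation order (plus strand:
// SC ascending; minus strand: SC descending; ties broken upstream).
//
// Pair compatibility (i precedes j in translation order):
//   target order:       ST_i < ST_j
//   contig order:       SC_i < SC_j (plus) / SC_i > SC_j (minus)
//   intron length:      min_intron <= gap <= max_intron,
//                       gap = SC_j - EC_i (plus) / EC_i - SC_j (minus)
//   target overlap:     ST_j - ET_i >= -max_target_overlap
// A chain of k exons scores sum(bits) + sum(C(l)) + log2(k!) with
// l = ST_j - ET_i between consecutive exons, C(1) = 0, else -|l|.
//
// Because the ordering reward log2(k!) depends on the chain length, the
// state is layered over the number of exons in the chain: S[j][k] is
// the best score of a chain of exactly k exons ending at exon j. This
// keeps the recursion exact (equal to exhaustive enumeration over
// compatible subsets); a single-state recursion can discard a
// lower-score, higher-count chain that would overtake after the
// log2(k+1) reward of a later extension. Chain length is capped at 64
// exons (log2 increments are negligible far below that).
//
// Ties: equal scores prefer the smaller predecessor index; the global
// optimum prefers the chain whose first exon starts lowest on the
// contig, then the shorter chain, then the smaller final index.

// [[Rcpp::export(name = ".chain_exons_cpp")]]
List chain_exons_cpp(IntegerVector SC, IntegerVector EC,
                     IntegerVector ST, IntegerVector ET,
                     NumericVector bits, bool minus,
                     int min_intron, int max_intron, int max_target_overlap) {
  const int n = SC.size();
  const double NEG = -1e300;
  const int kcap = std::min(n, 64);
  // S[k-1][j]: best score of a k-exon chain ending at j; B: predecessor
  std::vector<std::vector<double> > S(kcap, std::vector<double>(n, NEG));
  std::vector<std::vector<int> > B(kcap, std::vector<int>(n, -1));
  int lmax = 0;
  for (int i = 0; i < n; ++i) {
    int w = std::abs(EC[i] - SC[i]);
    if (w > lmax) lmax = w;
  }
  int lo = 0;
  for (int j = 0; j < n; ++j) {
    S[0][j] = bits[j];
    // predecessors before lo can never satisfy the intron upper bound
    // for this or any later j (SC sorted in translation order)
    if (!minus) {
      while (lo < j && SC[lo] < SC[j] - max_intron - lmax) ++lo;
    } else {
      while (lo < j && SC[lo] > SC[j] + max_intron + lmax) ++lo;
    }
    for (int i = lo; i < j; ++i) {
      if (ST[i] >= ST[j]) continue;
      int gap;
      if (!minus) {
        if (SC[i] >= SC[j]) continue;
        gap = SC[j] - EC[i];
      } else {
        if (SC[i] <= SC[j]) continue;
        gap = EC[i] - SC[j];
      }
      if (gap < min_intron || gap > max_intron) continue;
      int l = ST[j] - ET[i];
      if (l < -max_target_overlap) continue;
      double step = bits[j] + ((l == 1) ? 0.0 : -(double)std::abs(l));
      for (int k = 1; k < kcap; ++k) {
        if (S[k - 1][i] <= NEG / 2) continue;
        double cand = S[k - 1][i] + step + std::log2((double)k + 1.0);
        if (cand > S[k][j]) { S[k][j] = cand; B[k][j] = i; }
      }
    }
  }
  // global optimum with deterministic tie-breaks
  double best = NEG;
  for (int k = 0; k < kcap; ++k)
    for (int j = 0; j < n; ++j)
      if (S[k][j] > best) best = S[k][j];
  std::vector<int> bestpath;
  int best_first_sc = 0;
  for (int k = 0; k < kcap; ++k) {
    for (int j = 0; j < n; ++j) {
      if (S[k][j] < best - 1e-9) continue;
      std::vector<int> path(k + 1);
      int jj = j;
      for (int kk = k; kk >= 0; --kk) {
        path[kk] = jj;
        jj = (kk > 0) ? B[kk][jj] : -1;
      }
      int fsc = SC[path[0]];
      bool better = bestpath.empty();
      if (!better && !minus) better = fsc < best_first_sc;
      if (!better && minus) better = fsc > best_first_sc;
      if (better) { bestpath = path; best_first_sc = fsc; }
    }
  }
  IntegerVector path(bestpath.size());
  for (size_t i = 0; i < bestpath.size(); ++i) path[i] = bestpath[i] + 1;
  return List::create(_["path"] = path, _["S_set"] = best);
}
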