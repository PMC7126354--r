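#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <climits>
using namespace Rcpp;

// Local alignment kernels. Gap of length k costs gap_open + k * gap_extend
// (BLAST convention, so BLOSUM62 11/1 matches blastp defaults).

namespace {

const int NEG = INT_MIN / 4;

struct EncTable {
  int tab[256];
  EncTable(const std::string &alphabet) {
    int x = alphabet.find('X');
    for (int i = 0; i < 256; ++i) tab[i] = x;
    for (size_t i = 0; i < alphabet.size(); ++i)
      tab[(unsigned char)alphabet[i]] = (int)i;
  }
};

inline void encode(const char *s, const EncTable &enc, std::vector<int> &out) {
  size_t n = std::strlen(s);
  out.resize(n);
  for (size_t i = 0; i < n; ++i) out[i] = enc.tab[(unsigned char)s[i]];
}

// Score-only affine SW; returns best score, 1-based end cell (bi, bj) with the
// earliest cell in row-major scan order winning ties.
int sw_forward(const std::vector<int> &q, const std::vector<int> &t,
               const int *sm, int nalpha, int go, int ge,
               int &bi, int &bj,
               std::vector<int> &H, std::vector<int> &F) {
  int m = (int)q.size(), n = (int)t.size();
  H.assign(n + 1, 0);
  F.assign(n + 1, NEG);
  int best = 0; bi = 0; bj = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = 0;       // H[i-1][j-1]
    int e = NEG;        // gap along the row
    const int *srow = sm + (size_t)q[i - 1] * nalpha;
    for (int j = 1; j <= n; ++j) {
      int hup = H[j];   // H[i-1][j]
      int f = F[j] - ge; int fo = hup - go - ge; if (fo > f) f = fo;
      int eo = H[j - 1] - go - ge; e -= ge; if (eo > e) e = eo;
      int h = diag + srow[t[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = hup;
      H[j] = h; F[j] = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return best;
}

// Global affine NW on short subsegments with traceback; fills alignment stats.
// Tie-break while tracing: diagonal, then up (gap in target), then left.
void nw_stats(const std::vector<int> &q, int qs, int qe,
              const std::vector<int> &t, int ts, int te,
              const int *sm, int nalpha, int go, int ge,
              int &alnlen, int &matches, int &mismatches, int &gapopens) {
  int m = qe - qs, n = te - ts;
  std::vector<int> H((m + 1) * (n + 1), NEG), E(H), F(H);
  int w = n + 1;
  H[0] = 0;
  for (int j = 1; j <= n; ++j) E[j] = H[j] = -go - ge * j;
  for (int i = 1; i <= m; ++i) F[i * w] = H[i * w] = -go - ge * i;
  for (int i = 1; i <= m; ++i) {
    const int *srow = sm + (size_t)q[qs + i - 1] * nalpha;
    for (int j = 1; j <= n; ++j) {
      int idx = i * w + j;
      int e = std::max(E[idx - 1] - ge, H[idx - 1] - go - ge);
      int f = std::max(F[idx - w] - ge, H[idx - w] - go - ge);
      int d = H[idx - w - 1] + srow[t[ts + j - 1]];
      E[idx] = e; F[idx] = f;
      H[idx] = std::max(d, std::max(e, f));
    }
  }
  alnlen = matches = mismatches = gapopens = 0;
  int i = m, j = n;
  // state 0 = main, 1 = E (gap left), 2 = F (gap up)
  int state = 0;
  while (i > 0 || j > 0) {
    int idx = i * w + j;
    if (state == 0) {
      int d = (i > 0 && j > 0)
                  ? H[idx - w - 1] + sm[(size_t)q[qs + i - 1] * nalpha + t[ts + j - 1]]
                  : NEG;
      if (i > 0 && j > 0 && H[idx] == d) {
        ++alnlen;
        if (q[qs + i - 1] == t[ts + j - 1]) ++matches; else ++mismatches;
        --i; --j;
        continue;
      }
      if (i > 0 && H[idx] == F[idx]) { state = 2; continue; }
      state = 1; continue;
    } else if (state == 1) {
      ++alnlen;
      if (H[idx - 1] - go - ge == E[idx]) { ++gapopens; state = 0; }
      // else stay in E (extension)
      --j;
    } else {
      ++alnlen;
      if (H[idx - w] - go - ge == F[idx]) { ++gapopens; state = 0; }
      --i;
    }
  }
}

// Locate the start of the optimal local alignment ending at (bi, bj) by
// running the score-only pass on the reversed prefixes.
void sw_locate_start(const std::vector<int> &q, const std::vector<int> &t,
                     int bi, int bj, const int *sm, int nalpha, int go, int ge,
                     int &qs, int &ts,
                     std::vector<int> &H, std::vector<int> &F,
                     std::vector<int> &qr, std::vector<int> &tr) {
  qr.clear(); tr.clear();
  qr.reserve(bi); tr.reserve(bj);
  for (int i = bi - 1; i >= 0; --i) qr.push_back(q[i]);
  for (int j = bj - 1; j >= 0; --j) tr.push_back(t[j]);
  int ri, rj;
  sw_forward(qr, tr, sm, nalpha, go, ge, ri, rj, H, F);
  qs = bi - ri;
  ts = bj - rj;
}

// k-mer codes over the 20 standard residues (alphabet indices 0..19);
// returns sorted unique codes, skipping windows with non-standard letters
void kmer_codes(const std::vector<int> &s, int k, std::vector<long long> &out) {
  out.clear();
  if ((int)s.size() < k) return;
  for (size_t i = 0; i + k <= s.size(); ++i) {
    long long code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      if (s[i + j] >= 20) { ok = false; break; }
      code = code * 20 + s[i + j];
    }
    if (ok) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

} // namespace

// [[Rcpp::export(name = ".sw_search_cpp")]]
DataFrame sw_search_cpp(CharacterVector qseqs, CharacterVector tseqs,
                        IntegerMatrix submat, std::string alphabet,
                        int gap_open, int gap_extend,
                        NumericVector min_raw, int prefilter_k) {
  int nalpha = (int)alphabet.size();
  if (submat.nrow() != nalpha || submat.ncol() != nalpha)
    stop("substitution matrix does not match alphabet");
  std::vector<int> sm(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j) sm[(size_t)i * nalpha + j] = submat(i, j);
  EncTable enc(alphabet);

  std::vector<std::vector<int> > ts(tseqs.size());
  for (int k = 0; k < tseqs.size(); ++k) encode(CHAR(STRING_ELT(tseqs, k)), enc, ts[k]);

  // prefilter index: sorted (k-mer code, target) pairs over all targets
  std::vector<std::pair<long long, int> > tindex;
  std::vector<long long> codes;
  if (prefilter_k > 0) {
    for (int b = 0; b < (int)ts.size(); ++b) {
      kmer_codes(ts[b], prefilter_k, codes);
      for (size_t c = 0; c < codes.size(); ++c)
        tindex.push_back(std::make_pair(codes[c], b));
    }
    std::sort(tindex.begin(), tindex.end());
  }

  std::vector<int> qi_v, ti_v, raw_v, qs_v, qe_v, ts_v, te_v;
  std::vector<int> al_v, ma_v, mm_v, gp_v;
  std::vector<int> H, F, qr, tr, q;
  std::vector<int> cand;
  std::vector<char> seen(ts.size(), 0);

  for (int a = 0; a < qseqs.size(); ++a) {
    encode(CHAR(STRING_ELT(qseqs, a)), enc, q);
    int thr = (int)min_raw[a];
    if (thr < 1) thr = 1;
    // candidate targets: all, or those sharing a k-mer with the fragment
    cand.clear();
    if (prefilter_k > 0) {
      kmer_codes(q, prefilter_k, codes);
      for (size_t c = 0; c < codes.size(); ++c) {
        std::pair<long long, int> lo(codes[c], -1);
        std::vector<std::pair<long long, int> >::const_iterator it =
            std::lower_bound(tindex.begin(), tindex.end(), lo);
        for (; it != tindex.end() && it->first == codes[c]; ++it) {
          if (!seen[it->second]) { seen[it->second] = 1; cand.push_back(it->second); }
        }
      }
      std::sort(cand.begin(), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) seen[cand[c]] = 0;
    } else {
      for (int b = 0; b < (int)ts.size(); ++b) cand.push_back(b);
    }
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int b = cand[ci];
      int bi, bj;
      int best = sw_forward(q, ts[b], sm.data(), nalpha, gap_open, gap_extend, bi, bj, H, F);
      if (best < thr) continue;
      int qs, tstart;
      sw_locate_start(q, ts[b], bi, bj, sm.data(), nalpha, gap_open, gap_extend,
                      qs, tstart, H, F, qr, tr);
      int alnlen, matches, mismatches, gapopens;
      nw_stats(q, qs, bi, ts[b], tstart, bj, sm.data(), nalpha, gap_open, gap_extend,
               alnlen, matches, mismatches, gapopens);
      qi_v.push_back(a + 1); ti_v.push_back(b + 1); raw_v.push_back(best);
      qs_v.push_back(qs); qe_v.push_back(bi); ts_v.push_back(tstart); te_v.push_back(bj);
      al_v.push_back(alnlen); ma_v.push_back(matches); mm_v.push_back(mismatches);
      gp_v.push_back(gapopens);
    }
    if (a % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["qi"] = qi_v, _["ti"] = ti_v, _["raw"] = raw_v,
      _["qstart"] = qs_v, _["qend"] = qe_v, _["tstart"] = ts_v, _["tend"] = te_v,
      _["alnlen"] = al_v, _["matches"] = ma_v, _["mismatches"] = mm_v,
      _["gapopens"] = gp_v);
}

// Single-pair local alignment; returns score, coordinates and stats.
// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string qseq, std::string tseq, IntegerMatrix submat,
                 std::string alphabet, int gap_open, int gap_extend) {
  int nalpha = (int)alphabet.size();
  std::vector<int> sm(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j) sm[(size_t)i * nalpha + j] = submat(i, j);
  EncTable enc(alphabet);
  std::vector<int> q, t, H, F, qr, tr;
  encode(qseq.c_str(), enc, q);
  encode(tseq.c_str(), enc, t);
  int bi, bj;
  int best = sw_forward(q, t, sm.data(), nalpha, gap_open, gap_extend, bi, bj, H, F);
  if (best <= 0) {
    return List::create(_["raw"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0, _["alnlen"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0, _["gapopens"] = 0);
  }
  int qs, ts;
  sw_locate_start(q, t, bi, bj, sm.data(), nalpha, gap_open, gap_extend,
                  qs, ts, H, F, qr, tr);
  int alnlen, matches, mismatches, gapopens;
  nw_stats(q, qs, bi, t, ts, bj, sm.data(), nalpha, gap_open, gap_extend,
           alnlen, matches, mismatches, gapopens);
  return List::create(_["raw"] = best, _["qstart"] = qs, _["qend"] = bi,
                      _["tstart"] = ts, _["tend"] = bj, _["alnlen"] = alnlen,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gapopens"] = gapopens);
}
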