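#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state DP).
// Gap convention: a gap run of length L scores gap_open + (L - 1) * gap_extend,
// i.e. gap_open is the score of the first gapped column and gap_extend of each
// additional column. All gap scores are <= 0, match > 0.
//
// States: H = alignment ending in a substitution column at (i, j);
//         E = ending in a gap column consuming subject base j (gap in query);
//         F = ending in a gap column consuming query base i (gap in subject).
//
// Values are kept in rolling rows (cache resident); per-cell traceback
// decisions are packed into one byte: bits 0-1 the H provenance (0 local
// start, 1 diagonal, 2 close E, 3 close F), bit 2 the E provenance
// (0 open, 1 extend), bit 3 the F provenance. The DP runs in integer
// arithmetic when all scores are whole numbers (the common case), in
// doubles otherwise.

template <typename T>
static List sw_core(const std::string& q, const std::string& s,
                    T match, T mismatch, T gap_open, T gap_extend, T NEG) {
  const int m = (int)q.size();
  const int n = (int)s.size();
  const int W = n + 1;

  std::vector<T> Hprev((size_t)W, (T)0), Hcur((size_t)W, (T)0);
  std::vector<T> Frow((size_t)W, NEG);
  std::vector<unsigned char> ptr((size_t)(m + 1) * W, 0);
  const char* qc = q.data();
  const char* sc = s.data();

  T best = (T)0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    const char qi = qc[i - 1];
    unsigned char* prow = ptr.data() + (size_t)i * W;
    T e = NEG;
    Hcur[0] = (T)0;
    for (int j = 1; j <= n; ++j) {
      const T e_open = Hcur[j - 1] + gap_open;
      const T e_ext = e + gap_extend;
      unsigned char pe;
      if (e_ext > e_open) { e = e_ext; pe = 1; } else { e = e_open; pe = 0; }

      const T f_open = Hprev[j] + gap_open;
      const T f_ext = Frow[j] + gap_extend;
      unsigned char pf;
      T f;
      if (f_ext > f_open) { f = f_ext; pf = 1; } else { f = f_open; pf = 0; }
      Frow[j] = f;

      const T diag = Hprev[j - 1] + (qi == sc[j - 1] ? match : mismatch);
      T h = (T)0; unsigned char ph = 0;
      if (diag > h) { h = diag; ph = 1; }
      if (e > h)    { h = e;    ph = 2; }
      if (f > h)    { h = f;    ph = 3; }
      Hcur[j] = h;
      prow[j] = (unsigned char)(ph | (pe << 2) | (pf << 3));

      if (h > best) { best = h; bi = i; bj = j; }
    }
    Hprev.swap(Hcur);
  }

  int matches = 0, mismatches = 0, gap_openings = 0, aln_len = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;

  if (best > (T)0) {
    q_end = bi; s_end = bj;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (true) {
      const unsigned char pc = ptr[(size_t)i * W + j];
      if (state == 0) {
        const unsigned char ph = pc & 3u;
        if (ph == 0) break;                 // local start
        if (ph == 1) {                      // substitution column
          ++aln_len;
          if (qc[i - 1] == sc[j - 1]) ++matches; else ++mismatches;
          --i; --j;
        } else if (ph == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {              // E: gap in query, consumes s[j]
        ++aln_len;
        const unsigned char pe = (pc >> 2) & 1u;
        --j;
        if (pe == 0) { ++gap_openings; state = 0; }
      } else {                              // F: gap in subject, consumes q[i]
        ++aln_len;
        const unsigned char pf = (pc >> 3) & 1u;
        --i;
        if (pf == 0) { ++gap_openings; state = 0; }
      }
    }
    q_start = i + 1; s_start = j + 1;
  }

  return List::create(
    _["score"] = (double)best,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["s_start"] = s_start, _["s_end"] = s_end,
    _["aln_length"] = aln_len,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_openings"] = gap_openings);
}

static bool is_whole(double x) {
  return std::floor(x) == x && std::fabs(x) < 1e6;
}

// [[Rcpp::export]]
List sw_align_cpp(const std::string& q, const std::string& s,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (is_whole(match) && is_whole(mismatch) &&
      is_whole(gap_open) && is_whole(gap_extend)) {
    // integer scores cannot overflow: |score| <= 1e6 * max(m, n) << 2^31
    const int NEG = INT_MIN / 4;
    return sw_core<long long>(q, s, (long long)match, (long long)mismatch,
                              (long long)gap_open, (long long)gap_extend,
                              (long long)NEG);
  }
  return sw_core<double>(q, s, match, mismatch, gap_open, gap_extend, -1e300);
}
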