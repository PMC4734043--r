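#include <Rcpp.h>
#include <unordered_map>
#include <set>
using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Seed-and-extend local alignment score.
//
// Exact word_size matches between query and subject define candidate
// diagonals; each distinct diagonal is explored with a banded affine-gap
// Smith-Waterman (half band width `band` around the diagonal).  The return
// value is the best local score over all candidate diagonals, or 0 when the
// two sequences share no word.  A gap of length L costs
// gap_open + L * gap_extend (both negative).
// [[Rcpp::export]]
double align_raw_score_cpp(std::string q, std::string s,
                           double match, double mismatch,
                           double gap_open, double gap_extend,
                           int word_size, int band) {
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (word_size < 4 || word_size > 15) stop("word size must be in [4, 15]");
  if (n < word_size || m < word_size) return 0.0;

  std::vector<int> qc(n), sc(m);
  for (int i = 0; i < n; i++) qc[i] = bcode(q[i]);
  for (int j = 0; j < m; j++) sc[j] = bcode(s[j]);

  // hash subject words -> positions
  const long mask = (1L << (2 * word_size)) - 1;
  std::unordered_map<long, std::vector<int> > words;
  {
    long code = 0; int valid = 0;
    for (int j = 0; j < m; j++) {
      if (sc[j] < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | sc[j]) & mask;
      if (++valid >= word_size) words[code].push_back(j - word_size + 1);
    }
  }

  // candidate diagonals d = j - i from shared words
  std::set<int> diags;
  {
    long code = 0; int valid = 0;
    for (int i = 0; i < n; i++) {
      if (qc[i] < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | qc[i]) & mask;
      if (++valid >= word_size) {
        std::unordered_map<long, std::vector<int> >::iterator it = words.find(code);
        if (it != words.end()) {
          int qi = i - word_size + 1;
          for (size_t t = 0; t < it->second.size(); t++)
            diags.insert(it->second[t] - qi);
        }
      }
    }
  }
  if (diags.empty()) return 0.0;

  // Banded DP per diagonal.  Offsets o in [0, 2*band] map to subject
  // position j = i + d + o - band.  All scores are >= 0 after the local
  // floor, so a large negative sentinel stands in for -infinity outside
  // the band; it can never reach a floored cell.
  const double NEG = -1e18;
  const int W = 2 * band + 1;
  std::vector<double> Hprev(W + 1), H(W + 1), Fprev(W + 1), F(W + 1);
  double best = 0.0;

  for (std::set<int>::iterator dit = diags.begin(); dit != diags.end(); ++dit) {
    int d = *dit;
    int ilo = std::max(0, -d - band);
    int ihi = std::min(n - 1, m - 1 - d + band);
    if (ilo > ihi) continue;
    std::fill(Hprev.begin(), Hprev.end(), NEG);
    std::fill(Fprev.begin(), Fprev.end(), NEG);
    for (int i = ilo; i <= ihi; i++) {
      const int jstart = i + d - band;               // j at offset 0
      const int olo = std::max(0, -jstart);
      const int ohi = std::min(W - 1, m - 1 - jstart);
      std::fill(H.begin(), H.end(), NEG);
      std::fill(F.begin(), F.end(), NEG);
      const int qi = qc[i];
      const bool first_row = (i == 0);
      double e = NEG, hlast = NEG;
      for (int o = olo; o <= ohi; o++) {
        const int j = jstart + o;
        const double fval =
          std::max(Hprev[o + 1] + gap_open, Fprev[o + 1]) + gap_extend;
        const double diagbase =
          (first_row || j == 0) ? 0.0 : Hprev[o];
        const double sub = (qi >= 0 && qi == sc[j]) ? match : mismatch;
        e = std::max(hlast + gap_open, e) + gap_extend;
        double h = diagbase + sub;
        if (h < 0.0) h = 0.0;
        if (e > h) h = e;
        if (fval > h) h = fval;
        H[o] = h;
        F[o] = fval;
        if (h > best) best = h;
        hlast = h;
      }
      std::swap(Hprev, H);
      std::swap(Fprev, F);
    }
  }
  return best;
}
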