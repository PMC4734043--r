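#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N and anything else: non-informative
  }
}

// Count canonical k-mers (lexicographic min of a k-mer and its reverse
// complement under A<C<G<T) over all windows free of non-ACGT characters.
// Returns the count vector over the full 4^k code space (non-canonical
// slots stay zero) plus the number of counted windows.
// [[Rcpp::export]]
List kmer_counts_cpp(std::string seq, int k) {
  if (k < 1 || k > 10)
    stop("k must be between 1 and 10");
  const long n = (long)seq.size();
  const long nspace = 1L << (2 * k);
  const long mask = nspace - 1;
  const int rc_shift = 2 * (k - 1);
  IntegerVector counts(nspace, 0);
  long total = 0, code = 0, rc = 0;
  int valid = 0;
  for (long i = 0; i < n; i++) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0; rc = 0; continue; }
    code = ((code << 2) | b) & mask;
    rc = (rc >> 2) | ((long)(3 - b) << rc_shift);
    if (++valid >= k) {
      long canon = code < rc ? code : rc;
      counts[canon]++;
      total++;
    }
  }
  return List::create(_["counts"] = counts, _["total"] = (double)total);
}

// Enumerate forward-strand word codes (2-bit encoding) with their 0-based
// offsets, skipping windows that contain non-ACGT characters.
// [[Rcpp::export]]
List word_codes_cpp(std::string seq, int w) {
  if (w < 4 || w > 15)
    stop("word size must be between 4 and 15");
  const long n = (long)seq.size();
  const long mask = (1L << (2 * w)) - 1;
  std::vector<int> codes, offs;
  long code = 0;
  int valid = 0;
  for (long i = 0; i < n; i++) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= w) {
      codes.push_back((int)code);
      offs.push_back((int)(i - w + 1));
    }
  }
  return List::create(_["code"] = wrap(codes), _["offset"] = wrap(offs));
}
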