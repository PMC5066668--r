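#include <Rcpp.h>
using namespace Rcpp;

// Pairwise count of identical characters between equal-length strings.
// Used by the seed-and-extend mapper to score ungapped candidate placements.
// [[Rcpp::export]]
IntegerVector pair_match_count(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *pa = CHAR(STRING_ELT(a, i));
    const char *pb = CHAR(STRING_ELT(b, i));
    int m = 0;
    while (*pa && *pb) {
      if (*pa == *pb) ++m;
      ++pa; ++pb;
    }
    out[i] = m;
  }
  return out;
}

// Leftmost occurrence (1-based start; NA if none) of `pattern` in each subject
// allowing up to max_mismatch mismatches. Plain sliding scan; subjects and
// pattern are expected to be plain ACGTN text.
// [[Rcpp::export]]
IntegerVector leftmost_inexact_match(CharacterVector subjects, std::string pattern,
                                     int max_mismatch) {
  R_xlen_t n = subjects.size();
  int plen = (int) pattern.size();
  IntegerVector out(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(subjects, i));
    int slen = (int) LENGTH(STRING_ELT(subjects, i));
    for (int start = 0; start + plen <= slen; ++start) {
      int mm = 0;
      for (int j = 0; j < plen; ++j) {
        if (s[start + j] != pattern[j] && ++mm > max_mismatch) break;
      }
      if (mm <= max_mismatch) { out[i] = start + 1; break; }
    }
  }
  return out;
}
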