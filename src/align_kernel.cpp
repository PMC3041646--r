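#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Count mismatches of full-length ungapped read placements on targets.
// offset is the 1-based start of the read on the target; the caller
// guarantees the placement is in bounds. 'N' in either sequence never
// counts as a match. Counting stops early once cap+1 is reached, so
// returned values above cap only mean "more than cap".
// [[Rcpp::export(name = ".mismatch_counts")]]
IntegerVector mismatch_counts(CharacterVector reads, CharacterVector targets,
                              IntegerVector read_idx, IntegerVector target_idx,
                              IntegerVector offset, int cap) {
  R_xlen_t n = read_idx.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, read_idx[i] - 1));
    const char *t = CHAR(STRING_ELT(targets, target_idx[i] - 1));
    const char *tp = t + (offset[i] - 1);
    int mm = 0;
    for (const char *p = r; *p; ++p, ++tp) {
      if (*p != *tp || *p == 'N') {
        if (++mm > cap) break;
      }
    }
    out[i] = mm;
  }
  return out;
}
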