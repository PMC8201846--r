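#include <Rcpp.h>
using namespace Rcpp;

// Hamming verification of candidate read placements against a concatenated
// subject string. For candidate i, compares reads[idx[i]-1] with the subject
// substring starting at starts[i] (1-based) and reports whether the distance
// is <= max_mm. Early-exits once the budget is exceeded. Positions are
// trusted to be in range (the caller bounds-checks against subject spans).
// [[Rcpp::export]]
LogicalVector verify_candidates(CharacterVector subject, IntegerVector starts,
                                CharacterVector reads, IntegerVector idx,
                                int max_mm) {
  const char *big = CHAR(STRING_ELT(subject, 0));
  R_xlen_t n = starts.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, idx[i] - 1));
    const char *s = big + (starts[i] - 1);
    int mm = 0;
    for (; *r != '\0'; ++r, ++s) {
      if (*r != *s && ++mm > max_mm) break;
    }
    out[i] = mm <= max_mm;
  }
  return out;
}

// Per-position occurrence counts of each sequence's canonical k-mers in a
// sorted table of canonical k-mers (with parallel counts). Used by the
// k-mer profiling and masking steps: for every k-mer start position of seq,
// the canonical form (lexicographic min of forward and reverse complement)
// is binary-searched in the table. Positions whose window contains a
// non-ACGT character get NA.
static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// [[Rcpp::export]]
IntegerVector kmer_count_lookup(CharacterVector sequence, int k,
                                CharacterVector table, IntegerVector counts) {
  const char *seq = CHAR(STRING_ELT(sequence, 0));
  int n = (int) strlen(seq);
  int npos = n - k + 1;
  if (npos < 1) return IntegerVector(0);
  IntegerVector out(npos);
  std::string fwd(k, 'N'), rc(k, 'N');
  R_xlen_t ntab = table.size();
  for (int p = 0; p < npos; ++p) {
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = seq[p + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
      fwd[j] = c;
      rc[k - 1 - j] = comp_base(c);
    }
    if (!ok) { out[p] = NA_INTEGER; continue; }
    const std::string &can = (rc < fwd) ? rc : fwd;
    // binary search in the sorted table
    R_xlen_t lo = 0, hi = ntab;
    int cnt = 0;
    while (lo < hi) {
      R_xlen_t mid = (lo + hi) / 2;
      int cmp = strcmp(CHAR(STRING_ELT(table, mid)), can.c_str());
      if (cmp < 0) lo = mid + 1;
      else if (cmp > 0) hi = mid;
      else { cnt = counts[mid]; break; }
    }
    out[p] = cnt;
  }
  return out;
}
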