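#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Hash-backed canonical k-mer counter used by the repeat-masking step, where
// the same k-mer table is queried position-by-position over megabases: build
// once as an external pointer, then stream per-position lookups.

typedef std::unordered_map<std::string, int> KmerHash;

static inline char comp_base3(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static inline bool canon_at(const char *seq, int p, int k, std::string &fwd,
                            std::string &rc, const std::string *&out) {
  for (int j = 0; j < k; ++j) {
    char c = seq[p + j];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
    fwd[(size_t) j] = c;
    rc[(size_t) (k - 1 - j)] = comp_base3(c);
  }
  out = (rc < fwd) ? &rc : &fwd;
  return true;
}

// [[Rcpp::export]]
SEXP kmer_hash_build(CharacterVector seqs, int k) {
  KmerHash *h = new KmerHash();
  std::string fwd((size_t) k, 'N'), rc((size_t) k, 'N');
  const std::string *can;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    int n = (int) strlen(seq);
    for (int p = 0; p + k <= n; ++p) {
      if (canon_at(seq, p, k, fwd, rc, can)) (*h)[*can]++;
    }
  }
  XPtr<KmerHash> xp(h, true);
  return xp;
}

// per-position counts of sequence k-mers in the hash (NA for non-ACGT)
// [[Rcpp::export]]
IntegerVector kmer_hash_lookup(SEXP xp_, CharacterVector sequence, int k) {
  XPtr<KmerHash> xp(xp_);
  KmerHash *h = xp.get();
  const char *seq = CHAR(STRING_ELT(sequence, 0));
  int n = (int) strlen(seq);
  int npos = n - k + 1;
  if (npos < 1) return IntegerVector(0);
  IntegerVector out(npos);
  std::string fwd((size_t) k, 'N'), rc((size_t) k, 'N');
  const std::string *can;
  for (int p = 0; p < npos; ++p) {
    if (!canon_at(seq, p, k, fwd, rc, can)) { out[p] = NA_INTEGER; continue; }
    KmerHash::const_iterator it = h->find(*can);
    out[p] = (it == h->end()) ? 0 : it->second;
  }
  return out;
}
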