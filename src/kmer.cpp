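#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline char comp_base2(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// Canonical k-mer occurrence table over a set of sequences: every length-k
// window is counted under its canonical form (lexicographic min of the
// window and its reverse complement); windows containing non-ACGT are
// skipped. Returns k-mers sorted bytewise (so binary-search lookups can use
// strcmp) with parallel counts.
// [[Rcpp::export]]
List kmer_count_table(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> tab;
  std::string fwd((size_t) k, 'N'), rc((size_t) k, 'N');
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    int n = (int) strlen(seq);
    for (int p = 0; p + k <= n; ++p) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = seq[p + j];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
        fwd[(size_t) j] = c;
        rc[(size_t) (k - 1 - j)] = comp_base2(c);
      }
      if (!ok) continue;
      tab[(rc < fwd) ? rc : fwd]++;
    }
  }
  std::vector<const std::string *> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(&kv.first);
  std::sort(keys.begin(), keys.end(),
            [](const std::string *a, const std::string *b) { return *a < *b; });
  CharacterVector kmer(keys.size());
  IntegerVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = *keys[i];
    count[i] = tab[*keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}
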