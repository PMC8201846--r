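#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Subject-side seed index: every seed_len-mer of the concatenated subject
// string (2-bit packed; windows containing non-ACGT are skipped, which
// excludes the N separators) maps to its sorted list of 0-based positions.
// Built once per subject set and streamed against by read queries, in the
// spirit of suffix-array/k-mer mappers: seed hits anchor candidate
// placements, which are verified by Hamming comparison with early exit.

struct SeedIndex {
  int seed_len;
  std::string big;
  std::unordered_map<uint64_t, std::pair<uint32_t, uint32_t> > dir;
  std::vector<int> postings;
};

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char rc_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// pack seed at p; returns false when it contains non-ACGT
static inline bool pack_seed(const char *s, int len, uint64_t &key) {
  uint64_t k = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    k = (k << 2) | (uint64_t) b;
  }
  key = k;
  return true;
}

// [[Rcpp::export]]
SEXP seed_index_build(CharacterVector subject, int seed_len) {
  SeedIndex *ix = new SeedIndex();
  ix->seed_len = seed_len;
  ix->big = CHAR(STRING_ELT(subject, 0));
  const char *s = ix->big.c_str();
  int n = (int) ix->big.size();
  std::vector<std::pair<uint64_t, int> > kp;
  kp.reserve(n);
  for (int p = 0; p + seed_len <= n; ++p) {
    uint64_t key;
    if (pack_seed(s + p, seed_len, key)) kp.push_back(std::make_pair(key, p));
  }
  std::sort(kp.begin(), kp.end());
  ix->postings.resize(kp.size());
  ix->dir.reserve(kp.size());
  size_t i = 0;
  while (i < kp.size()) {
    size_t j = i;
    while (j < kp.size() && kp[j].first == kp[i].first) ++j;
    ix->dir[kp[i].first] = std::make_pair((uint32_t) i, (uint32_t) (j - i));
    for (size_t t = i; t < j; ++t) ix->postings[t] = kp[t].second;
    i = j;
  }
  XPtr<SeedIndex> xp(ix, true);
  return xp;
}

// Query reads against a seed index. spans_start/spans_end are 1-based
// inclusive subject spans inside the concatenated string. n_seeds disjoint
// seeds at offsets 0, seed_len, 2*seed_len anchor candidates (pigeonhole:
// any placement with <= n_seeds-1 mismatches keeps one seed intact).
// Returns per-read verified distinct placement counts (capped at cap_count:
// callers only distinguish unique from multi-mapping), and the placements
// themselves for reads with at most max_report of them.
// [[Rcpp::export]]
List seed_index_query(SEXP xp_, CharacterVector reads,
                      IntegerVector spans_start, IntegerVector spans_end,
                      int max_mm, int n_seeds, int max_report,
                      int cap_count) {
  XPtr<SeedIndex> xp(xp_);
  SeedIndex *ix = xp.get();
  const char *big = ix->big.c_str();
  int nbig = (int) ix->big.size();
  int ns = spans_start.size();
  R_xlen_t nr = reads.size();
  IntegerVector counts(nr);
  std::vector<int> out_idx, out_si, out_start;
  std::vector<int> out_strand;
  std::vector<int> cand_seen;
  for (R_xlen_t r = 0; r < nr; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int len = (int) strlen(rd);
    if (len < n_seeds * ix->seed_len) { counts[r] = NA_INTEGER; continue; }
    std::string fwd(rd);
    std::string rcs(len, 'N');
    for (int i = 0; i < len; ++i) rcs[(size_t)(len - 1 - i)] = rc_base(rd[i]);
    int total = 0;
    std::vector<std::pair<int, int> > found;  // (strand, start0)
    for (int strand = 0; strand < 2 && (cap_count < 0 || total < cap_count);
         ++strand) {
      const char *q = strand == 0 ? fwd.c_str() : rcs.c_str();
      cand_seen.clear();
      for (int sd = 0; sd < n_seeds; ++sd) {
        if (cap_count >= 0 && total >= cap_count) break;
        int off = sd * ix->seed_len;
        uint64_t key;
        if (!pack_seed(q + off, ix->seed_len, key)) continue;
        std::unordered_map<uint64_t, std::pair<uint32_t, uint32_t> >::
          const_iterator it = ix->dir.find(key);
        if (it == ix->dir.end()) continue;
        for (uint32_t t = 0; t < it->second.second; ++t) {
          if (cap_count >= 0 && total >= cap_count) break;
          int cand = ix->postings[it->second.first + t] - off;  // 0-based
          if (cand < 0 || cand + len > nbig) continue;
          if (n_seeds > 1) {
            if (std::find(cand_seen.begin(), cand_seen.end(), cand) !=
                cand_seen.end()) continue;
            cand_seen.push_back(cand);
          }
          // subject span containment (1-based span of cand+1 .. cand+len)
          int lo = 0, hi = ns;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (spans_start[mid] <= cand + 1) lo = mid + 1; else hi = mid;
          }
          int si = lo - 1;
          if (si < 0 || cand + 1 < spans_start[si] ||
              cand + len > spans_end[si]) continue;
          int mm = 0;
          const char *sp = big + cand;
          bool okv = true;
          for (int i = 0; i < len; ++i) {
            if (q[i] != sp[i] && ++mm > max_mm) { okv = false; break; }
          }
          if (!okv) continue;
          ++total;
          if ((int) found.size() < max_report || max_report < 0) {
            found.push_back(std::make_pair(strand, cand));
          }
        }
      }
    }
    counts[r] = total;
    if (total > 0 && (max_report < 0 || total <= max_report)) {
      for (size_t f = 0; f < found.size(); ++f) {
        out_idx.push_back((int) r + 1);
        out_strand.push_back(found[f].first);
        out_start.push_back(found[f].second);
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["idx"] = wrap(out_idx),
                      _["strand"] = wrap(out_strand),
                      _["start"] = wrap(out_start));
}
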