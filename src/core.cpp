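// Compiled kernels: exact-substring read mapping against a hashed k-mer
// index, bulk reverse complement, and canonical k-mer counting. The mapper
// reports a read as mapped iff it occurs exactly in the reference or its
// reverse complement; multi-placement reads take one placement uniformly at
// random (R RNG, so seeded runs are reproducible).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const signed char CODE4_TAB[256] = {
  /* built so that A=0, C=1, G=2, T=3, everything else -1 */
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1, 0,-1, 1,-1,-1,-1, 2,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1, 3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1
};

static inline int code4(char c) {
  return CODE4_TAB[static_cast<unsigned char>(c)];
}

static inline char comp4(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
  }
  return c;
}


// branchless byte-level complement table
static const unsigned char* comp_table() {
  static unsigned char tab[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) tab[i] = static_cast<unsigned char>(i);
    tab[static_cast<unsigned char>('A')] = 'T';
    tab[static_cast<unsigned char>('T')] = 'A';
    tab[static_cast<unsigned char>('C')] = 'G';
    tab[static_cast<unsigned char>('G')] = 'C';
    tab[static_cast<unsigned char>('a')] = 't';
    tab[static_cast<unsigned char>('t')] = 'a';
    tab[static_cast<unsigned char>('c')] = 'g';
    tab[static_cast<unsigned char>('g')] = 'c';
    init = true;
  }
  return tab;
}

struct RefIndex {
  std::string seq;
  int k;
  std::vector<int> pos;  // k-mer start positions grouped by code
  std::unordered_map<std::uint64_t, std::pair<std::uint32_t, std::uint32_t>>
      ranges;            // code -> (offset, count) into pos
};

// [[Rcpp::export]]
SEXP cpp_ref_index(std::string seq, int k) {
  RefIndex* idx = new RefIndex();
  idx->seq = std::move(seq);
  idx->k = k;
  const std::string& s = idx->seq;
  const std::size_t n = s.size();
  if (n >= static_cast<std::size_t>(k)) {
    std::vector<std::pair<std::uint64_t, int>> tmp;
    tmp.reserve(n - k + 1);
    std::uint64_t code = 0;
    const std::uint64_t mask =
        (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    int valid = 0;
    for (std::size_t i = 0; i < n; ++i) {
      int c = code4(s[i]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | static_cast<std::uint64_t>(c)) & mask;
      if (++valid >= k) tmp.emplace_back(code, static_cast<int>(i) - k + 1);
    }
    std::sort(tmp.begin(), tmp.end());
    idx->pos.reserve(tmp.size());
    idx->ranges.reserve(tmp.size());
    std::size_t i = 0;
    while (i < tmp.size()) {
      std::size_t j = i;
      while (j < tmp.size() && tmp[j].first == tmp[i].first) ++j;
      idx->ranges.emplace(tmp[i].first,
                          std::make_pair(static_cast<std::uint32_t>(i),
                                         static_cast<std::uint32_t>(j - i)));
      for (std::size_t t = i; t < j; ++t) idx->pos.push_back(tmp[t].second);
      i = j;
    }
  }
  XPtr<RefIndex> xp(idx, true);
  xp.attr("class") = "ref_index_ptr";
  return xp;
}

static inline bool leading_code(const char* s, int k, std::uint64_t& out) {
  std::uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int c = code4(s[i]);
    if (c < 0) return false;
    code = (code << 2) | static_cast<std::uint64_t>(c);
  }
  out = code;
  return true;
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP idxp, CharacterVector reads) {
  XPtr<RefIndex> idx(idxp);
  const std::string& ref = idx->seq;
  const int k = idx->k;
  const int n = reads.size();
  IntegerVector start(n, -1);
  IntegerVector strand(n, NA_INTEGER);
  RNGScope rng;
  std::vector<int> cand_pos;
  std::vector<int> cand_str;
  std::string rc;
  for (int i = 0; i < n; ++i) {
    const char* rd = CHAR(STRING_ELT(reads, i));
    const int L = LENGTH(STRING_ELT(reads, i));
    if (L < k) stop("read shorter than seed_k");
    cand_pos.clear();
    cand_str.clear();
    std::uint64_t code;
    if (leading_code(rd, k, code)) {
      auto it = idx->ranges.find(code);
      if (it != idx->ranges.end()) {
        for (std::uint32_t t = 0; t < it->second.second; ++t) {
          int p = idx->pos[it->second.first + t];
          if (p + L <= static_cast<int>(ref.size()) &&
              ref.compare(p, L, rd, L) == 0) {
            cand_pos.push_back(p);
            cand_str.push_back(0);
          }
        }
      }
    }
    const unsigned char* CMP = comp_table();
    rc.resize(L);
    for (int j = 0; j < L; ++j)
      rc[j] = static_cast<char>(CMP[static_cast<unsigned char>(rd[L - 1 - j])]);
    if (rc.compare(0, L, rd, L) != 0 &&
        leading_code(rc.c_str(), k, code)) {
      auto it = idx->ranges.find(code);
      if (it != idx->ranges.end()) {
        for (std::uint32_t t = 0; t < it->second.second; ++t) {
          int p = idx->pos[it->second.first + t];
          if (p + L <= static_cast<int>(ref.size()) &&
              ref.compare(p, L, rc.c_str(), L) == 0) {
            cand_pos.push_back(p);
            cand_str.push_back(1);
          }
        }
      }
    }
    if (!cand_pos.empty()) {
      int pick = 0;
      if (cand_pos.size() > 1) {
        pick = static_cast<int>(unif_rand() * cand_pos.size());
        if (pick >= static_cast<int>(cand_pos.size()))
          pick = cand_pos.size() - 1;
      }
      start[i] = cand_pos[pick];
      strand[i] = cand_str[pick];
    }
  }
  return List::create(_["start"] = start, _["strand"] = strand);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    const int L = LENGTH(STRING_ELT(x, i));
    buf.resize(L);
    const unsigned char* CMP = comp_table();
    for (int j = 0; j < L; ++j)
      buf[j] = static_cast<char>(CMP[static_cast<unsigned char>(s[L - 1 - j])]);
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf.data(), L));
  }
  return out;
}

// Count canonical k-mers (lexicographic min of k-mer and its reverse
// complement) over a set of sequences; windows containing non-ACGT
// characters are skipped. Returns distinct canonical k-mers and counts.
// [[Rcpp::export]]
List cpp_count_canonical(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  std::string fwd, rc;
  fwd.resize(k);
  rc.resize(k);
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const int L = LENGTH(STRING_ELT(seqs, i));
    if (L < k) continue;
    // positions of the next non-ACGT character at or after each start
    int bad_until = -1;  // last seen bad index
    for (int j = 0; j < k - 1; ++j) {
      if (code4(s[j]) < 0) bad_until = j;
    }
    for (int p = 0; p + k <= L; ++p) {
      if (code4(s[p + k - 1]) < 0) bad_until = p + k - 1;
      if (bad_until >= p) continue;
      fwd.assign(s + p, k);
      for (int j = 0; j < k; ++j)
        rc[j] = static_cast<char>(comp_table()[static_cast<unsigned char>(s[p + k - 1 - j])]);
      const std::string& canon = (rc < fwd) ? rc : fwd;
      ++counts[canon];
    }
  }
  const std::size_t m = counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  std::size_t i = 0;
  for (auto& kv : counts) {
    kmer[i] = kv.first;
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Extract reads as ONE concatenated string (offsets = cumsum of len),
// avoiding millions of individual R string allocations. hap_idx selects
// hap1/hap2 per read (1-based).
// [[Rcpp::export]]
CharacterVector cpp_extract_concat(std::string hap1, std::string hap2,
                                   IntegerVector hap_idx, IntegerVector start,
                                   IntegerVector len, bool rc) {
  const int n = start.size();
  std::size_t total = 0;
  for (int i = 0; i < n; ++i) total += len[i];
  std::string buf;
  buf.reserve(total);
  for (int i = 0; i < n; ++i) {
    const std::string& hap = (hap_idx[i] == 1) ? hap1 : hap2;
    const int s = start[i];
    const int L = len[i];
    if (s < 0 || s + L > static_cast<int>(hap.size()))
      stop("read interval out of bounds");
    if (rc) {
      const unsigned char* CMP = comp_table();
      const std::size_t base = buf.size();
      buf.resize(base + L);
      char* dst = &buf[base];
      const char* srcp = hap.data() + s;
      for (int j = 0; j < L; ++j)
        dst[j] = static_cast<char>(CMP[static_cast<unsigned char>(srcp[L - 1 - j])]);
    } else {
      buf.append(hap, s, L);
    }
  }
  CharacterVector out(1);
  out[0] = buf;
  return out;
}

// Map reads stored in a concatenated blob (see cpp_map_reads for semantics).
// [[Rcpp::export]]
List cpp_map_blob(SEXP idxp, CharacterVector blob, IntegerVector offset,
                  IntegerVector len) {
  XPtr<RefIndex> idx(idxp);
  const std::string& ref = idx->seq;
  const int k = idx->k;
  const char* base = CHAR(STRING_ELT(blob, 0));
  const int n = offset.size();
  IntegerVector start(n, -1);
  IntegerVector strand(n, NA_INTEGER);
  RNGScope rng;
  std::vector<int> cand_pos;
  std::vector<int> cand_str;
  std::string rc;
  for (int i = 0; i < n; ++i) {
    const char* rd = base + offset[i];
    const int L = len[i];
    if (L < k) stop("read shorter than seed_k");
    cand_pos.clear();
    cand_str.clear();
    std::uint64_t code;
    if (leading_code(rd, k, code)) {
      auto it = idx->ranges.find(code);
      if (it != idx->ranges.end()) {
        for (std::uint32_t t = 0; t < it->second.second; ++t) {
          int p = idx->pos[it->second.first + t];
          if (p + L <= static_cast<int>(ref.size()) &&
              ref.compare(p, L, rd, L) == 0) {
            cand_pos.push_back(p);
            cand_str.push_back(0);
          }
        }
      }
    }
    const unsigned char* CMP = comp_table();
    rc.resize(L);
    for (int j = 0; j < L; ++j)
      rc[j] = static_cast<char>(CMP[static_cast<unsigned char>(rd[L - 1 - j])]);
    if (rc.compare(0, L, rd, L) != 0 &&
        leading_code(rc.c_str(), k, code)) {
      auto it = idx->ranges.find(code);
      if (it != idx->ranges.end()) {
        for (std::uint32_t t = 0; t < it->second.second; ++t) {
          int p = idx->pos[it->second.first + t];
          if (p + L <= static_cast<int>(ref.size()) &&
              ref.compare(p, L, rc.c_str(), L) == 0) {
            cand_pos.push_back(p);
            cand_str.push_back(1);
          }
        }
      }
    }
    if (!cand_pos.empty()) {
      int pick = 0;
      if (cand_pos.size() > 1) {
        pick = static_cast<int>(unif_rand() * cand_pos.size());
        if (pick >= static_cast<int>(cand_pos.size()))
          pick = cand_pos.size() - 1;
      }
      start[i] = cand_pos[pick];
      strand[i] = cand_str[pick];
    }
  }
  return List::create(_["start"] = start, _["strand"] = strand);
}
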