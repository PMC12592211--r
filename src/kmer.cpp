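// 2-bit packed k-mer counting and exact read placement.
// k is capped at 26 so packed codes (< 2^52) survive round-trips through
// R doubles exactly.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <cstring>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Scan one string, calling f(pos, code) for every valid k-mer start.
// Positions containing non-ACGT bases (or bases failing the quality
// predicate) restart the window.
template <typename F, typename Q>
static void scan_kmers(const char* s, size_t n, int k, bool canonical,
                       Q qual_ok, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0 || !qual_ok(i)) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++run >= k) {
      uint64_t code = canonical ? std::min(fwd, rev) : fwd;
      f(i + 1 - k, code);
    }
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, Nullable<CharacterVector> quals,
                     int k, bool canonical, int min_qual, int qual_offset,
                     int min_count) {
  std::unordered_map<uint64_t, int> counts;
  size_t total_bases = 0;
  for (R_xlen_t r = 0; r < seqs.size(); ++r)
    total_bases += LENGTH(STRING_ELT(seqs, r));
  counts.reserve(total_bases / 8);
  bool use_qual = quals.isNotNull() && min_qual >= 0;
  CharacterVector qv;
  if (use_qual) qv = quals.get();
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    size_t n = LENGTH(STRING_ELT(seqs, r));
    if ((int)n < k) continue;
    if (use_qual) {
      const char* q = CHAR(STRING_ELT(qv, r));
      scan_kmers(s, n, k, canonical,
                 [&](size_t i) { return q[i] - qual_offset >= min_qual; },
                 [&](size_t, uint64_t code) { counts[code]++; });
    } else {
      scan_kmers(s, n, k, canonical,
                 [](size_t) { return true; },
                 [&](size_t, uint64_t code) { counts[code]++; });
    }
  }
  std::vector<std::pair<uint64_t, int>> kept;
  kept.reserve(counts.size());
  for (auto& kv : counts)
    if (kv.second >= min_count) kept.push_back(kv);
  std::sort(kept.begin(), kept.end());
  NumericVector code(kept.size());
  IntegerVector cnt(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    code[i] = (double)kept[i].first;
    cnt[i] = kept[i].second;
  }
  return List::create(_["code"] = code, _["count"] = cnt);
}

// Genome-wide single-copy k-mers with their chromosome and start position.
// [[Rcpp::export]]
List cpp_single_copy_kmers(CharacterVector seqs, int k, bool canonical) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    size_t n = LENGTH(STRING_ELT(seqs, r));
    scan_kmers(s, n, k, canonical, [](size_t) { return true; },
               [&](size_t, uint64_t code) { counts[code]++; });
  }
  std::vector<int> chrom_idx;
  std::vector<int> pos;
  std::vector<double> code_out;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    size_t n = LENGTH(STRING_ELT(seqs, r));
    scan_kmers(s, n, k, canonical, [](size_t) { return true; },
               [&](size_t i, uint64_t code) {
                 if (counts[code] == 1) {
                   chrom_idx.push_back((int)r + 1);
                   pos.push_back((int)i);
                   code_out.push_back((double)code);
                 }
               });
  }
  return List::create(_["chrom_idx"] = wrap(chrom_idx),
                      _["pos"] = wrap(pos),
                      _["code"] = wrap(code_out));
}

// [[Rcpp::export]]
LogicalVector cpp_codes_in_set(NumericVector codes, NumericVector set) {
  std::unordered_set<uint64_t> s;
  s.reserve(set.size() * 2);
  for (double v : set) s.insert((uint64_t)v);
  LogicalVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = s.count((uint64_t)codes[i]) > 0;
  return out;
}

// ---- exact read placement -------------------------------------------------

static const uint64_t HASH_BASE = 1099511628211ULL;

static uint64_t poly_hash(const char* s, int L) {
  uint64_t h = 0;
  for (int i = 0; i < L; ++i) h = h * HASH_BASE + (uint8_t)s[i];
  return h;
}

// Place fixed-length reads at their unique exact match (either strand) in
// the assembly. Returns per-chromosome coverage vectors plus counts of
// unplaced and multi-mapping reads.
// [[Rcpp::export]]
List cpp_place_reads(CharacterVector seqs, CharacterVector reads) {
  if (reads.size() == 0)
    stop("no reads to place");
  int L = LENGTH(STRING_ELT(reads, 0));
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    if (LENGTH(STRING_ELT(reads, i)) != L)
      stop("all reads must have equal length");

  // read hash -> read indices (forward and reverse-complement forms)
  std::unordered_map<uint64_t, std::vector<int>> lookup;
  std::vector<std::string> fwd(reads.size()), rc(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    fwd[i].assign(s, L);
    std::string r(L, 'N');
    for (int j = 0; j < L; ++j) {
      char c = s[L - 1 - j];
      r[j] = c == 'A' ? 'T' : c == 'C' ? 'G' : c == 'G' ? 'C'
           : c == 'T' ? 'A' : 'N';
    }
    rc[i] = r;
    lookup[poly_hash(fwd[i].c_str(), L)].push_back((int)i);
    if (rc[i] != fwd[i])
      lookup[poly_hash(rc[i].c_str(), L)].push_back((int)i);
  }

  // power of HASH_BASE for rolling removal of the leading character
  uint64_t pw = 1;
  for (int i = 0; i < L - 1; ++i) pw *= HASH_BASE;

  std::vector<int> n_match(reads.size(), 0);
  std::vector<int> m_chrom(reads.size(), -1), m_pos(reads.size(), -1);

  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    const char* g = CHAR(STRING_ELT(seqs, c));
    int n = LENGTH(STRING_ELT(seqs, c));
    if (n < L) continue;
    uint64_t h = poly_hash(g, L);
    for (int p = 0; p + L <= n; ++p) {
      if (p > 0) h = (h - (uint8_t)g[p - 1] * pw) * HASH_BASE +
                     (uint8_t)g[p + L - 1];
      auto it = lookup.find(h);
      if (it != lookup.end()) {
        for (int ri : it->second) {
          if (std::memcmp(g + p, fwd[ri].c_str(), L) == 0 ||
              std::memcmp(g + p, rc[ri].c_str(), L) == 0) {
            // palindromic double-count guard: forward and RC identical
            if (fwd[ri] == rc[ri] && m_chrom[ri] == (int)c &&
                m_pos[ri] == p) continue;
            n_match[ri]++;
            m_chrom[ri] = (int)c;
            m_pos[ri] = p;
          }
        }
      }
    }
  }

  List cov(seqs.size());
  std::vector<std::vector<int>> covv(seqs.size());
  for (R_xlen_t c = 0; c < seqs.size(); ++c)
    covv[c].assign(LENGTH(STRING_ELT(seqs, c)), 0);
  int multi = 0, unplaced = 0;
  for (size_t i = 0; i < fwd.size(); ++i) {
    if (n_match[i] == 1) {
      auto& v = covv[m_chrom[i]];
      for (int j = 0; j < L; ++j) v[m_pos[i] + j]++;
    } else if (n_match[i] > 1) {
      multi++;
    } else {
      unplaced++;
    }
  }
  for (R_xlen_t c = 0; c < seqs.size(); ++c) cov[c] = wrap(covv[c]);
  cov.names() = seqs.names();
  return List::create(_["coverage"] = cov,
                      _["n_multi"] = multi,
                      _["n_unplaced"] = unplaced);
}

// Decode packed k-mer codes back to strings (for display and tests).
// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  const char* B = "ACGT";
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = B[c & 3]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}
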