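#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit avalanche, used both to derive the
// per-seed tweak and to hash packed k-mer codes.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Hash values are truncated to 53 bits so they are exactly representable as
// R doubles; the sketch order statistics are unaffected at desk scale.
static inline double hash_code(uint64_t canon, uint64_t seed_mix) {
  return static_cast<double>(mix64(canon ^ seed_mix) >> 11);
}

// Walk one sequence with a rolling 2-bit encoding (first base in the highest
// bits, so numeric order of codes == lexicographic order of k-mer strings).
// Windows containing a non-ACGT character are skipped; the canonical code is
// min(forward, reverse-complement).
template <typename F>
static void walk_canonical(const std::string& s, int k, F&& emit) {
  const int n = static_cast<int>(s.size());
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    const int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - c) << shift);
    if (++run >= k) emit(std::min(fwd, rev));
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = alpha[code & 3ULL];
    code >>= 2;
  }
  return out;
}

// Distinct canonical k-mer strings of one sequence (k <= 32).
// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(std::string seq, int k) {
  std::vector<uint64_t> codes;
  walk_canonical(seq, k, [&](uint64_t c) { codes.push_back(c); });
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = decode_kmer(codes[i], k);
  return out;
}

// Sorted distinct canonical k-mer hash values pooled over all sequences.
// [[Rcpp::export]]
NumericVector cpp_kmer_hash_set(CharacterVector seqs, int k, double seed) {
  const uint64_t seed_mix = mix64(static_cast<uint64_t>(static_cast<int64_t>(seed)));
  std::vector<double> hashes;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const std::string s = as<std::string>(seqs[j]);
    walk_canonical(s, k, [&](uint64_t c) { hashes.push_back(hash_code(c, seed_mix)); });
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  return wrap(hashes);
}

// Hash each supplied k-mer string (canonicalized first); NA for windows with
// non-ACGT characters or length != k.
// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers, int k, double seed) {
  const uint64_t seed_mix = mix64(static_cast<uint64_t>(static_cast<int64_t>(seed)));
  NumericVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const std::string s = as<std::string>(kmers[j]);
    bool done = false;
    if (static_cast<int>(s.size()) == k) {
      walk_canonical(s, k, [&](uint64_t c) {
        out[j] = hash_code(c, seed_mix);
        done = true;
      });
    }
    if (!done) out[j] = NA_REAL;
  }
  return out;
}

// Bloom filter over 53-bit hash values, double hashing with nh probes.
static inline uint64_t bloom_h1(uint64_t h) { return mix64(h ^ 0xA5A5A5A5A5A5A5A5ULL); }
static inline uint64_t bloom_h2(uint64_t h) { return mix64(h + 0x0123456789ABCDEFULL) | 1ULL; }

// [[Rcpp::export]]
RawVector cpp_bloom_build(NumericVector hashes, double m_bits, int nh) {
  const uint64_t m = static_cast<uint64_t>(m_bits);
  RawVector bits((m + 7) / 8);
  std::fill(bits.begin(), bits.end(), 0);
  for (R_xlen_t j = 0; j < hashes.size(); ++j) {
    const uint64_t h = static_cast<uint64_t>(hashes[j]);
    const uint64_t a = bloom_h1(h), b = bloom_h2(h);
    for (int i = 0; i < nh; ++i) {
      const uint64_t idx = (a + static_cast<uint64_t>(i) * b) % m;
      bits[idx >> 3] |= static_cast<Rbyte>(1 << (idx & 7));
    }
  }
  return bits;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_query(RawVector bits, double m_bits, int nh, NumericVector hashes) {
  const uint64_t m = static_cast<uint64_t>(m_bits);
  LogicalVector out(hashes.size());
  for (R_xlen_t j = 0; j < hashes.size(); ++j) {
    const uint64_t h = static_cast<uint64_t>(hashes[j]);
    const uint64_t a = bloom_h1(h), b = bloom_h2(h);
    bool hit = true;
    for (int i = 0; i < nh && hit; ++i) {
      const uint64_t idx = (a + static_cast<uint64_t>(i) * b) % m;
      hit = (bits[idx >> 3] >> (idx & 7)) & 1;
    }
    out[j] = hit;
  }
  return out;
}

// Count positions with equal characters over the common prefix of each pair.
// [[Rcpp::export]]
IntegerVector cpp_match_count(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    const char* pa = CHAR(STRING_ELT(a, j));
    const char* pb = CHAR(STRING_ELT(b, j));
    int m = 0;
    while (*pa && *pb) {
      if (*pa == *pb) ++m;
      ++pa; ++pb;
    }
    out[j] = m;
  }
  return out;
}

// Apply i.i.d. substitution errors (to a different base, uniform) using R's
// RNG stream so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_add_substitutions(CharacterVector reads, double rate) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(reads.size());
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    std::string s = as<std::string>(reads[j]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < rate) {
        const int c = base_code(s[i]);
        if (c >= 0) {
          int sub = static_cast<int>(unif_rand() * 3.0);
          if (sub > 2) sub = 2;
          s[i] = alpha[(c + 1 + sub) & 3];
        }
      }
    }
    out[j] = s;
  }
  return out;
}
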