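#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// splitmix64: well-mixed 64-bit finalizer; seed folded in additively so the
// same k-mer maps to unrelated values under different sketch seeds.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
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

// Hash every canonical (strand-minimal) k-mer of the input sequences and
// return the `size` smallest distinct hash values, sorted ascending.
// K-mers spanning a non-ACGT symbol are skipped. Hashes are truncated to
// 53 bits so they are exactly representable as R doubles.
// min_mult drops k-mers seen fewer than that many times (the read-mode
// minimum-copy filter used to suppress sequencing-error k-mers).
// [[Rcpp::export(name = ".minhash_hashes")]]
NumericVector minhash_hashes(CharacterVector sequences, int k, int size,
                             double seed, int min_mult) {
  if (k < 1) stop("k must be >= 1");
  if (k > 31) stop("k must be <= 31");
  if (size < 1) stop("sketch size must be >= 1");
  const uint64_t seed64 = (uint64_t)seed;
  const uint64_t mask53 = (1ULL << 53) - 1ULL;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t s = 0; s < sequences.size(); ++s) {
    const char* seq = CHAR(STRING_ELT(sequences, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char* p = seq; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(fwd, rev);
        counts[canon] += 1;
      }
    }
  }

  std::vector<uint64_t> hashes;
  hashes.reserve(counts.size());
  for (const auto& kv : counts) {
    if (kv.second >= min_mult) {
      hashes.push_back(mix64(kv.first + seed64) & mask53);
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  R_xlen_t n = std::min((R_xlen_t)hashes.size(), (R_xlen_t)size);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (double)hashes[i];
  return out;
}

// Distinct canonical k-mers as strings; the brute-force side of exact
// Jaccard cross-checks and the reference for full-cardinality sketches.
// [[Rcpp::export(name = ".canonical_kmers")]]
CharacterVector canonical_kmers(CharacterVector sequences, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  static const char bases[] = {'A', 'C', 'G', 'T'};
  std::unordered_map<uint64_t, int> seen;
  std::vector<uint64_t> order;
  const uint64_t kmask = (1ULL << (2 * k)) - 1ULL;
  for (R_xlen_t s = 0; s < sequences.size(); ++s) {
    const char* seq = CHAR(STRING_ELT(sequences, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char* p = seq; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(fwd, rev);
        if (seen.insert({canon, 1}).second) order.push_back(canon);
      }
    }
  }
  CharacterVector out(order.size());
  std::string buf(k, 'A');
  for (size_t i = 0; i < order.size(); ++i) {
    uint64_t v = order[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = bases[v & 3ULL]; v >>= 2; }
    out[i] = buf;
  }
  return out;
}
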