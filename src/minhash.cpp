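#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <set>
using namespace Rcpp;

// splitmix64: fast, well-mixed, seedable; not cryptographic.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Bottom-s distinct hashes of canonical k-mers over all input sequences.
// 2-bit packing (A<C<G<T) preserves lexicographic order, so min(fwd, rev)
// on packed integers equals the lexicographic min of k-mer and its reverse
// complement. Hashes are masked to 53 bits so R doubles hold them exactly.
// [[Rcpp::export(name = ".minhashSketchCpp")]]
NumericVector minhashSketchCpp(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (s < 1) stop("sketch size must be >= 1");
  const uint64_t mask53 = (1ULL << 53) - 1;
  const uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const uint64_t sd = splitmix64((uint64_t) seed + 0x5bd1e995ULL);
  std::set<uint64_t> best;
  bool anyKmer = false;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *str = CHAR(STRING_ELT(seqs, i));
    const size_t n = std::strlen(str);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t pos = 0; pos < n; ++pos) {
      const int code = baseCode(str[pos]);
      if (code < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) code) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << (2 * (k - 1)));
      if (++run >= k) {
        anyKmer = true;
        const uint64_t canon = fwd < rev ? fwd : rev;
        const uint64_t h = splitmix64(canon ^ sd) & mask53;
        if ((int) best.size() < s) {
          best.insert(h);
        } else if (h < *best.rbegin() && best.find(h) == best.end()) {
          best.insert(h);
          best.erase(std::prev(best.end()));
        }
      }
    }
  }
  if (!anyKmer) stop("no k-mer of length k could be extracted from the sequences");
  return NumericVector(best.begin(), best.end());
}
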