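#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64: small, fast, well-mixed PRNG; one explicit 64-bit state per
// call keeps every permutation stream reproducible from its integer seed
// independently of R's global RNG.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Lemire's multiply-shift bounded draw in [0, bound).
static inline uint32_t bounded(uint64_t &state, uint32_t bound) {
  uint32_t x = static_cast<uint32_t>(splitmix64(state) >> 32);
  return static_cast<uint32_t>((static_cast<uint64_t>(x) * bound) >> 32);
}

// Batched Fisher-Yates shuffles: an n x n_perm matrix whose columns are
// independent uniform random permutations of 1..n, determined by `seed`.
// [[Rcpp::export]]
IntegerMatrix perm_indices_cpp(int n, int n_perm, double seed) {
  IntegerMatrix out(n, n_perm);
  uint64_t state = static_cast<uint64_t>(seed);
  // decorrelate nearby integer seeds before use
  for (int w = 0; w < 4; ++w) splitmix64(state);
  std::vector<int> idx(n);
  for (int c = 0; c < n_perm; ++c) {
    for (int i = 0; i < n; ++i) idx[i] = i + 1;
    for (int j = n - 1; j > 0; --j) {
      int k = static_cast<int>(bounded(state, static_cast<uint32_t>(j + 1)));
      std::swap(idx[j], idx[k]);
    }
    for (int i = 0; i < n; ++i) out(i, c) = idx[i];
  }
  return out;
}
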