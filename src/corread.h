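#ifndef CORREAD_H
#define CORREAD_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

// nucleotide codes: A=0, C=1, G=2, T=3, N(=anything else)=4
inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

inline char code_base(int c) {
  static const char b[5] = {'A', 'C', 'G', 'T', 'N'};
  return b[c];
}

inline std::vector<uint8_t> encode_codes(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

// splitmix64 finalizer: full-avalanche 64-bit mixer
inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

// 48-bit hash values are exactly representable as doubles on the R side
const uint64_t HASH_MASK48 = (1ULL << 48) - 1;

#endif
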