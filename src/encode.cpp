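#include "corread.h"
using namespace Rcpp;

// Pack a nucleotide string into a 2-bit code vector (4 bases/byte) plus a
// 1-bit N mask (8 bases/byte). N is stored as A in the 2-bit lane; the mask
// restores it on decode.

// [[Rcpp::export]]
List cpp_encode_2bit(std::string seq) {
  int n = (int) seq.size();
  RawVector bits((n + 3) / 4);
  RawVector nmask((n + 7) / 8);
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    int two = (c == 4) ? 0 : c;
    bits[i / 4] = (Rbyte)(bits[i / 4] | (two << (2 * (i % 4))));
    if (c == 4) nmask[i / 8] = (Rbyte)(nmask[i / 8] | (1 << (i % 8)));
  }
  return List::create(_["bits"] = bits, _["nmask"] = nmask, _["length"] = n);
}

// [[Rcpp::export]]
std::string cpp_decode_2bit(RawVector bits, RawVector nmask, int length) {
  std::string out(length, 'A');
  for (int i = 0; i < length; ++i) {
    if (nmask[i / 8] & (1 << (i % 8))) {
      out[i] = 'N';
    } else {
      out[i] = code_base((bits[i / 4] >> (2 * (i % 4))) & 3);
    }
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  int n = (int) seq.size();
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[n - 1 - i]);
    out[i] = (c == 4) ? 'N' : code_base(3 - c);
  }
  return out;
}
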