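#include "corread.h"
using namespace Rcpp;

// Per-table seeds: a splitmix64 stream from the user seed.
// [[Rcpp::export]]
NumericVector cpp_hash_seeds(double seed, int h) {
  NumericVector out(h);
  uint64_t state = (uint64_t) seed;
  for (int l = 0; l < h; ++l) {
    state += 0x9e3779b97f4a7c15ULL;
    out[l] = (double)(mix64(state) & HASH_MASK48);
  }
  return out;
}

// Enumerate canonical k-mer codes of a sequence with a rolling 2-bit encoding.
// Windows containing N yield no code. Returns one code (< 4^k, k <= 20 keeps
// it inside 48 bits... k <= 24 inside 2^48; hash values are masked to 48 bits
// regardless) per valid window, -1 for invalid windows.
static std::vector<int64_t> canonical_codes(const std::string &seq, int k) {
  int n = (int) seq.size();
  std::vector<int64_t> out;
  if (n < k) return out;
  out.assign(n - k + 1, -1);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0; // bases since last N
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c == 4) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
    ++valid;
    if (valid >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      out[i - k + 1] = (int64_t) canon;
    }
  }
  return out;
}

// Minhash signature per read: for each hash table l, the minimum of
// mix64(code ^ seed_l) & 2^48-1 over all canonical k-mer codes. Rows with no
// valid k-mer (too short, or all windows contain N) are all-NA.
// [[Rcpp::export]]
NumericMatrix cpp_signatures(CharacterVector seqs, int k, NumericVector seeds) {
  int n = seqs.size(), h = seeds.size();
  NumericMatrix sig(n, h);
  std::fill(sig.begin(), sig.end(), NA_REAL);
  std::vector<uint64_t> sd(h);
  for (int l = 0; l < h; ++l) sd[l] = (uint64_t) seeds[l];
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int64_t> codes = canonical_codes(s, k);
    bool any = false;
    std::vector<uint64_t> mins(h, ~0ULL);
    for (size_t w = 0; w < codes.size(); ++w) {
      if (codes[w] < 0) continue;
      any = true;
      uint64_t code = (uint64_t) codes[w];
      for (int l = 0; l < h; ++l) {
        uint64_t hv = mix64(code ^ sd[l]) & HASH_MASK48;
        if (hv < mins[l]) mins[l] = hv;
      }
    }
    if (any) for (int l = 0; l < h; ++l) sig(i, l) = (double) mins[l];
  }
  return sig;
}

// All per-window hash values of one read (rows = windows, cols = tables),
// NA for windows containing N. Support for brute-force oracles.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_hashes(std::string seq, int k, NumericVector seeds) {
  std::vector<int64_t> codes = canonical_codes(seq, k);
  int h = seeds.size(), w = (int) codes.size();
  NumericMatrix out(w, h);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < w; ++i) {
    if (codes[i] < 0) continue;
    for (int l = 0; l < h; ++l)
      out(i, l) = (double)(mix64((uint64_t) codes[i] ^ (uint64_t) seeds[l]) & HASH_MASK48);
  }
  return out;
}
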