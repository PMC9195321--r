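#include "corread.h"
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Canonical k-mer machinery for the lost-true-k-mer spectrum report.
// k <= 31 fits a 2-bit code into 64 bits. Windows containing N are skipped.

static void collect_codes(const CharacterVector &seqs, int k,
                          std::unordered_map<uint64_t, int> *count_map,
                          std::unordered_set<uint64_t> *set_out) {
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c == 4) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) c) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        if (count_map) ++(*count_map)[canon];
        if (set_out) set_out->insert(canon);
      }
    }
  }
}

// Distinct canonical k-mers present in the uncorrected reads AND the
// reference but absent from the corrected reads, binned by their coverage
// (multiplicity) in the uncorrected reads, bins 1..max_bin.
// [[Rcpp::export]]
IntegerVector cpp_lost_true_kmer_bins(CharacterVector uncorrected,
                                      CharacterVector corrected,
                                      CharacterVector reference,
                                      int k, int max_bin) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, int> unc;
  std::unordered_set<uint64_t> corr, ref;
  collect_codes(uncorrected, k, &unc, NULL);
  collect_codes(corrected, k, NULL, &corr);
  collect_codes(reference, k, NULL, &ref);
  IntegerVector bins(max_bin);
  for (std::unordered_map<uint64_t, int>::const_iterator it = unc.begin();
       it != unc.end(); ++it) {
    if (it->second > max_bin) continue;
    if (ref.count(it->first) && !corr.count(it->first)) ++bins[it->second - 1];
  }
  return bins;
}

// Multiplicity table of canonical k-mers as strings -> counts (used by the
// spectrum report and as a convenience for small inputs).
// [[Rcpp::export]]
List cpp_canonical_kmer_table(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, int> map;
  collect_codes(seqs, k, &map, NULL);
  int n = (int) map.size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  int i = 0;
  for (std::unordered_map<uint64_t, int>::const_iterator it = map.begin();
       it != map.end(); ++it, ++i) {
    std::string s(k, 'A');
    for (int p = 0; p < k; ++p)
      s[p] = code_base((int)((it->first >> (2 * (k - 1 - p))) & 3));
    kmers[i] = s;
    counts[i] = it->second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}
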