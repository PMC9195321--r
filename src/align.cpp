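#include "corread.h"
using namespace Rcpp;

// Gapless semi-global alignment by shifted Hamming distance.
//
// For every shift placing the candidate at columns [s, s + len_cand) against
// the anchor at [0, len_anchor), and for both candidate orientations, count
// mismatches inside the overlap. Positions where either base is N are
// mismatch-neutral: excluded from both the mismatch count and the reported
// overlap. Only shifts whose geometric overlap reaches
// ceil(min_overlap_ratio * len_anchor) are considered. The best placement
// minimizes mismatches/overlap; ties prefer the smaller |shift|, then the
// forward orientation. Ratio ties are compared exactly (cross-multiplied).

struct ShdBest {
  long long mism, ov;
  int shift;
  bool rev, valid;
};

static void shd_one_orientation(const std::vector<uint8_t> &a,
                                const std::vector<uint8_t> &b,
                                int min_ov, bool rev, ShdBest &best) {
  int la = (int) a.size(), lb = (int) b.size();
  for (int s = -(lb - min_ov); s <= la - min_ov; ++s) {
    int lo = std::max(0, s), hi = std::min(la, s + lb); // anchor columns
    long long geo = hi - lo;                            // geometric overlap
    if (geo < min_ov) continue;
    long long mism = 0, ov = 0;
    for (int p = lo; p < hi; ++p) {
      uint8_t x = a[p], y = b[p - s];
      if (x == 4 || y == 4) continue;
      ++ov;
      if (x != y) {
        ++mism;
        // exact early abort: the final ratio is at least mism/geo, so once
        // mism/geo strictly exceeds the best ratio this shift cannot win
        // (ties require equality, so strict comparison is safe)
        if (best.valid && mism * best.ov > best.mism * geo) { mism = -1; break; }
      }
    }
    if (mism < 0) continue;
    if (ov == 0) continue;
    bool better;
    if (!best.valid) {
      better = true;
    } else {
      long long lhs = mism * best.ov, rhs = best.mism * ov;
      if (lhs != rhs) {
        better = lhs < rhs;
      } else if (std::abs(s) != std::abs(best.shift)) {
        better = std::abs(s) < std::abs(best.shift);
      } else {
        better = (!rev && best.rev);
      }
    }
    if (better) { best.mism = mism; best.ov = ov; best.shift = s; best.rev = rev; best.valid = true; }
  }
}

// [[Rcpp::export]]
List cpp_align_shd(std::string anchor, CharacterVector cands,
                   double min_overlap_ratio) {
  int n = cands.size();
  int la = (int) anchor.size();
  int min_ov = (int) std::ceil(min_overlap_ratio * la);
  if (min_ov < 1) min_ov = 1;
  std::vector<uint8_t> a = encode_codes(anchor);
  IntegerVector shift(n), overlap(n), mism(n);
  LogicalVector rev(n), valid(n);
  NumericVector ratio(n);
  for (int i = 0; i < n; ++i) {
    std::string c = as<std::string>(cands[i]);
    std::vector<uint8_t> b = encode_codes(c);
    std::vector<uint8_t> brc(b.size());
    for (size_t j = 0; j < b.size(); ++j) {
      uint8_t x = b[b.size() - 1 - j];
      brc[j] = (x == 4) ? 4 : (uint8_t)(3 - x);
    }
    ShdBest best; best.valid = false; best.mism = 0; best.ov = 0; best.shift = 0; best.rev = false;
    if (!b.empty() && la > 0) {
      shd_one_orientation(a, b, min_ov, false, best);
      shd_one_orientation(a, brc, min_ov, true, best);
    }
    valid[i] = best.valid;
    shift[i] = best.valid ? best.shift : NA_INTEGER;
    overlap[i] = best.valid ? (int) best.ov : NA_INTEGER;
    mism[i] = best.valid ? (int) best.mism : NA_INTEGER;
    rev[i] = best.valid ? best.rev : NA_LOGICAL;
    ratio[i] = best.valid ? (double) best.mism / (double) best.ov : NA_REAL;
  }
  return List::create(_["shift"] = shift, _["overlap"] = overlap,
                      _["mismatches"] = mism, _["reverse"] = rev,
                      _["ratio"] = ratio, _["valid"] = valid);
}
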