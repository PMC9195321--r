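#include "corread.h"
using namespace Rcpp;

// Anchor-centered gapless MSA. Row 0 is the anchor at shift 0; candidate
// rows sit at their alignment shift, already re-oriented to the anchor
// strand (qualities reversed alongside). Per column and nucleotide we keep
// the read count, the weight sum and the Phred sum. The weight of one base
// is row_factor * (1 - 10^(-Q/10)): the row factor reflects alignment
// quality, the second term the base call reliability. N bases contribute
// nothing (no count, no weight, no coverage).
//
// Consensus per column: the nucleotide with the greatest weight sum; on an
// exact weight tie the anchor's base wins if it is among the tied, else the
// smallest code. If a column's total weight is zero (possible only with
// Phred 0 everywhere) counts break the tie the same way. Support is the
// consensus weight divided by the column's total weight.

static void add_row(IntegerMatrix &counts, NumericMatrix &weights,
                    NumericMatrix &qualsum, const std::string &seq,
                    const IntegerVector &qual, int shift, int first,
                    double factor, int sign) {
  int len = (int) seq.size();
  for (int p = 0; p < len; ++p) {
    int c = base_code(seq[p]);
    if (c == 4) continue;
    int col = shift + p - first;
    double q = (double) qual[p];
    // quantize to multiples of 2^-20: column sums and incremental
    // subtraction are then exact in double arithmetic, so consensus
    // tie-breaks cannot drift between incremental and batch construction
    double w = factor * (1.0 - std::pow(10.0, -q / 10.0));
    w = std::nearbyint(w * 1048576.0) / 1048576.0;
    counts(c, col) += sign;
    weights(c, col) += sign * w;
    qualsum(c, col) += sign * q;
  }
}

static void recompute_consensus(List &msa) {
  IntegerMatrix counts = msa["counts"];
  NumericMatrix weights = msa["weights"];
  IntegerVector anchor_code = msa["anchor_code"];
  int first = msa["first"];
  int ncol = counts.ncol();
  int la = anchor_code.size();
  IntegerVector coverage(ncol), consensus(ncol);
  NumericVector support(ncol);
  for (int j = 0; j < ncol; ++j) {
    int cov = 0; double wtot = 0.0;
    for (int c = 0; c < 4; ++c) { cov += counts(c, j); wtot += weights(c, j); }
    coverage[j] = cov;
    if (cov == 0) { consensus[j] = -1; support[j] = NA_REAL; continue; }
    int apos = first + j; // anchor coordinate of this column
    int abase = (apos >= 0 && apos < la) ? anchor_code[apos] : -1;
    int best = 0;
    bool use_weights = wtot > 0.0;
    for (int c = 1; c < 4; ++c) {
      double wc = use_weights ? weights(c, j) : (double) counts(c, j);
      double wb = use_weights ? weights(best, j) : (double) counts(best, j);
      if (wc > wb) best = c;
      else if (wc == wb && c == abase) best = c;
    }
    // anchor preference also when the anchor base was scanned before a tie
    if (abase >= 0) {
      double wa = use_weights ? weights(abase, j) : (double) counts(abase, j);
      double wb = use_weights ? weights(best, j) : (double) counts(best, j);
      if (wa == wb) best = abase;
    }
    consensus[j] = best;
    support[j] = use_weights ? weights(best, j) / wtot
                             : (double) counts(best, j) / (double) cov;
  }
  msa["coverage"] = coverage;
  msa["consensus"] = consensus;
  msa["support"] = support;
}

// [[Rcpp::export]]
List cpp_msa_build(std::string anchor_seq, IntegerVector anchor_qual,
                   CharacterVector cand_seqs, List cand_quals,
                   IntegerVector shifts, NumericVector row_factors) {
  int la = (int) anchor_seq.size();
  int n = cand_seqs.size();
  int first = 0, last = la;
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) {
    seqs[i] = as<std::string>(cand_seqs[i]);
    first = std::min(first, shifts[i]);
    last = std::max(last, shifts[i] + (int) seqs[i].size());
  }
  int ncol = last - first;
  IntegerMatrix counts(4, ncol);
  NumericMatrix weights(4, ncol), qualsum(4, ncol);
  add_row(counts, weights, qualsum, anchor_seq, anchor_qual, 0, first, 1.0, 1);
  for (int i = 0; i < n; ++i) {
    add_row(counts, weights, qualsum, seqs[i], cand_quals[i], shifts[i],
            first, row_factors[i], 1);
  }
  std::vector<int> acode(la);
  for (int p = 0; p < la; ++p) acode[p] = base_code(anchor_seq[p]);
  List msa = List::create(
    _["first"] = first, _["ncol"] = ncol,
    _["counts"] = counts, _["weights"] = weights, _["qualsum"] = qualsum,
    _["anchor_code"] = IntegerVector(acode.begin(), acode.end()),
    _["anchor_seq"] = anchor_seq,
    _["anchor_qual"] = anchor_qual,
    _["anchor_len"] = la,
    _["cand_seqs"] = cand_seqs, _["cand_quals"] = cand_quals,
    _["shifts"] = shifts, _["row_factors"] = row_factors,
    _["active"] = LogicalVector(n, true),
    _["coverage"] = R_NilValue, _["consensus"] = R_NilValue,
    _["support"] = R_NilValue);
  recompute_consensus(msa);
  msa.attr("class") = "corread_msa";
  return msa;
}

// Incremental removal of candidate rows (0-based candidate indices): their
// contributions are subtracted from the column tallies and the consensus is
// recomputed. The anchor row is not addressable here and can never be
// removed.
// [[Rcpp::export]]
List cpp_msa_remove_rows(List msa_in, IntegerVector remove) {
  List msa = clone(msa_in);
  IntegerMatrix counts = msa["counts"];
  NumericMatrix weights = msa["weights"], qualsum = msa["qualsum"];
  CharacterVector cand_seqs = msa["cand_seqs"];
  List cand_quals = msa["cand_quals"];
  IntegerVector shifts = msa["shifts"];
  NumericVector factors = msa["row_factors"];
  LogicalVector active = msa["active"];
  int first = msa["first"];
  for (int r = 0; r < remove.size(); ++r) {
    int i = remove[r];
    if (i < 0 || i >= cand_seqs.size()) stop("candidate row index out of range");
    if (!active[i]) continue;
    std::string s = as<std::string>(cand_seqs[i]);
    add_row(counts, weights, qualsum, s, cand_quals[i], shifts[i], first,
            factors[i], -1);
    active[i] = false;
  }
  msa["active"] = active;
  recompute_consensus(msa);
  msa.attr("class") = "corread_msa";
  return msa;
}
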