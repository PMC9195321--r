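#' Per-base three-way correction evaluation
#'
#' Compares each base of the uncorrected (`u`), error-free (`e`) and
#' corrected (`c`) version of the same read: a true positive is
#' `u != e & e == c`, a false positive `u == e & e != c`, a false negative
#' `u != e & c == u`, a true negative `u == e & c == u`. The remaining case
#' (`u != e & c` differs from both), a miscorrection, is reported in its own
#' column and excluded from TP and from the FP-rate formula.
#'
#' @param uncorrected,error_free,corrected `read_set`s (or character
#'   vectors) with identical read counts, lengths and order.
#' @return an `eval_counts` list: `TP`, `FP`, `FN`, `TN`, `miscorrection`,
#'   `total`, `fp_rate_per_million` (`NA` when `FP + TP == 0`).
#' @export
compare_three_way <- function(uncorrected, error_free, corrected) {
  u <- eval_raw(uncorrected)
  e <- eval_raw(error_free)
  c_ <- eval_raw(corrected)
  if (length(u) != length(e) || length(u) != length(c_)) {
    stop("comparison error: the three inputs differ in total base count")
  }
  err <- u != e
  counts <- list(TP = sum(err & e == c_),
                 FP = sum(!err & c_ != e),
                 FN = sum(err & c_ == u),
                 TN = sum(!err & c_ == u),
                 miscorrection = sum(err & c_ != u & c_ != e),
                 total = length(u))
  counts$fp_rate_per_million <- if (counts$FP + counts$TP > 0) {
    1e6 * counts$FP / (counts$FP + counts$TP)
  } else NA_real_
  structure(counts, class = "eval_counts")
}

eval_raw <- function(x) {
  seqs <- if (inherits(x, "read_set")) x$sequence else as.character(x)
  charToRaw(paste(seqs, collapse = ""))
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  miscorrections %d  (FP rate/M: %s)\n",
              x$TP, x$FP, x$FN, x$TN, x$miscorrection,
              if (is.na(x$fp_rate_per_million)) "n/a"
              else format(x$fp_rate_per_million, digits = 4)))
  invisible(x)
}

#' False-positive rate per million corrections
#'
#' `10^6 * FP / (FP + TP)`.
#'
#' @param counts an [compare_three_way()] result (or any list with `TP`,
#'   `FP`).
#' @return rate per million; `NA` with a warning when no corrections were
#'   made.
#' @export
fp_rate <- function(counts) {
  if (counts$FP + counts$TP == 0) {
    warning("no corrections made; FP rate is undefined")
    return(NA_real_)
  }
  1e6 * counts$FP / (counts$FP + counts$TP)
}

#' Lost-true-k-mer spectrum report
#'
#' A *true* k-mer occurs in the reference genome; a *lost true* k-mer is
#' present (canonically) in the uncorrected reads and the reference but
#' absent from the corrected reads. Lost true k-mers are binned by their
#' coverage (multiplicity) in the uncorrected reads; low-coverage bins are
#' where overzealous correctors erase genuine genomic sequence.
#'
#' @param uncorrected,corrected `read_set`s or character vectors of read
#'   sequences.
#' @param reference reference genome sequence(s).
#' @param k k-mer length (default 21).
#' @param max_bin highest coverage bin reported (default 10).
#' @return data.frame with `coverage` (1..`max_bin`) and `lost` (distinct
#'   lost true k-mers in that bin).
#' @export
lost_true_kmers <- function(uncorrected, corrected, reference, k = 21L,
                            max_bin = 10L) {
  unc <- if (inherits(uncorrected, "read_set")) uncorrected$sequence else as.character(uncorrected)
  corr <- if (inherits(corrected, "read_set")) corrected$sequence else as.character(corrected)
  if (k > min(nchar(unc))) stop("k exceeds the shortest read length")
  bins <- cpp_lost_true_kmer_bins(unc, corr, as.character(reference),
                                  as.integer(k), as.integer(max_bin))
  data.frame(coverage = seq_len(max_bin), lost = bins)
}

#' Canonical k-mer multiplicities
#'
#' Counts every canonical k-mer (the lexicographic minimum of a k-mer and
#' its reverse complement) of the input sequences; windows containing `N`
#' are skipped.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length (1..31).
#' @return data.frame with `kmer` and `count`, sorted by k-mer.
#' @export
canonical_kmer_counts <- function(seqs, k) {
  tab <- cpp_canonical_kmer_table(as.character(seqs), as.integer(k))
  df <- data.frame(kmer = tab$kmer, count = tab$count, stringsAsFactors = FALSE)
  df[order(df$kmer), , drop = FALSE]
}
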