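BASES <- c("A", "C", "G", "T")

#' Build an anchor-centered MSA
#'
#' Stacks the anchor (at shift 0) and its aligned candidates into a gapless
#' column pile. Reverse-complement candidates are re-oriented to the anchor
#' strand (qualities reversed alongside). Per column and nucleotide the MSA
#' stores the read count, the weight sum and the Phred sum; the consensus of
#' a column is the nucleotide with the greatest weight sum, and its support
#' is the consensus weight relative to the column's total weight.
#'
#' The weight of a base is `max(1 - 3*r, 0.25) * (1 - 10^(-Q/10))` where `r`
#' is the mismatch/overlap ratio of its row's alignment (0 for the anchor)
#' and `Q` the (possibly binned) Phred score: better alignments and better
#' base calls carry more weight, with a floor so no surviving candidate is
#' voiceless. `N` bases contribute neither count nor weight nor coverage.
#'
#' @param anchor_seq anchor sequence (string).
#' @param anchor_phred integer Phred scores of the anchor.
#' @param cand_seqs candidate sequences in their original orientation.
#' @param cand_phreds list of integer Phred vectors, original orientation.
#' @param alignments data.frame from [align_shd()] for these candidates; all
#'   rows must be valid.
#' @return a `corread_msa` object (column matrices `counts`, `weights`,
#'   `qualsum` are 4 x ncol with rows A,C,G,T; `first` is the anchor
#'   coordinate of the leftmost column; `consensus` holds codes 0..3 or -1
#'   for uncovered columns).
#' @export
build_msa <- function(anchor_seq, anchor_phred, cand_seqs = character(0),
                      cand_phreds = list(), alignments = NULL) {
  n <- length(cand_seqs)
  if (n == 0L) {
    return(cpp_msa_build(anchor_seq, as.integer(anchor_phred), character(0),
                         list(), integer(0), numeric(0)))
  }
  stopifnot(nrow(alignments) == n, all(alignments$valid))
  oriented <- as.character(cand_seqs)
  phreds <- lapply(cand_phreds, as.integer)
  rev <- which(alignments$reverse)
  if (length(rev)) {
    oriented[rev] <- revcomp(oriented[rev])
    phreds[rev] <- lapply(phreds[rev], base::rev)
  }
  factors <- pmax(1 - 3 * alignments$ratio, 0.25)
  cpp_msa_build(anchor_seq, as.integer(anchor_phred), oriented, phreds,
                as.integer(alignments$shift), factors)
}

#' Column indices of the anchor region
#'
#' @param msa a `corread_msa`.
#' @return 1-based column indices of the anchor-covered range `[b, e)`.
#' @export
anchor_columns <- function(msa) {
  seq(-msa$first + 1L, length.out = msa$anchor_len)
}

#' Consensus sequence over a column range
#'
#' @param msa a `corread_msa`.
#' @param cols 1-based column indices (default: the anchor columns).
#' @param fallback characters substituted at uncovered columns.
#' @return character vector of single bases.
#' @export
msa_consensus <- function(msa, cols = anchor_columns(msa), fallback = NULL) {
  code <- msa$consensus[cols]
  out <- character(length(code))
  covered <- code >= 0L
  out[covered] <- BASES[code[covered] + 1L]
  if (any(!covered)) {
    out[!covered] <- if (is.null(fallback)) "N" else fallback[!covered]
  }
  out
}

#' @export
print.corread_msa <- function(x, ...) {
  cat(sprintf("corread_msa: %d columns [%d, %d), anchor length %d, %d/%d candidates active\n",
              x$ncol, x$first, x$first + x$ncol, x$anchor_len,
              sum(x$active), length(x$active)))
  invisible(x)
}

#' Refine an MSA by evicting off-pattern candidate rows
#'
#' Repeatedly (at most `max_iterations` times) scans the anchor-covered
#' columns for a nucleotide `X` different from the column consensus whose
#' count reaches `frequency_factor * estimated_coverage`. If several
#' columns trigger, only the one with the highest discordant count is
#' processed per iteration (ties: leftmost column, then smallest base).
#' If `X` equals the anchor's base in that column, candidate rows covering
#' the column that do **not** carry `X` there are removed (the anchor's
#' haplotype wins); otherwise the rows carrying `X` are removed. The
#' consensus is recomputed after each eviction and refinement stops early
#' once an iteration removes nothing. The anchor row is never removed.
#'
#' @param msa a `corread_msa`.
#' @param estimated_coverage user-supplied fold coverage of the dataset.
#' @param frequency_factor fraction of the estimated coverage that a
#'   discordant nucleotide must reach (default 0.3).
#' @param max_iterations iteration cap (default 5).
#' @return list with `msa` (refined), `removed` (0-based candidate row
#'   indices, in eviction order) and `iterations` used.
#' @export
refine_msa <- function(msa, estimated_coverage, frequency_factor = 0.3,
                       max_iterations = 5L) {
  stopifnot(estimated_coverage > 0)
  threshold <- frequency_factor * estimated_coverage
  removed_all <- integer(0)
  iterations <- 0L
  lens <- nchar(msa$cand_seqs)
  for (it in seq_len(max_iterations)) {
    iterations <- it
    acols <- anchor_columns(msa)
    cnt <- msa$counts[, acols, drop = FALSE]
    cons <- msa$consensus[acols]
    # discordant counts: zero out each column's consensus row
    disc <- cnt
    covered <- which(cons >= 0L)
    disc[cbind(cons[covered] + 1L, covered)] <- 0L
    trig <- which(disc >= threshold & disc > 0)
    if (!length(trig)) break
    best <- trig[which.max(disc[trig])] # column-major: leftmost col, smallest base on ties
    X <- (best - 1L) %% 4L              # 0-based nucleotide code
    j <- (best - 1L) %/% 4L + 1L        # index into acols
    pos0 <- acols[j] - 1L + msa$first   # 0-based anchor coordinate
    abase <- msa$anchor_code[pos0 + 1L]

    active <- which(msa$active)
    p <- pos0 - msa$shifts[active]      # 0-based position within each row
    covers <- p >= 0L & p < lens[active]
    rows <- active[covers]
    base_at <- substring(msa$cand_seqs[rows], p[covers] + 1L, p[covers] + 1L)
    carries_X <- base_at == BASES[X + 1L]
    evict <- if (X == abase) rows[!carries_X] else rows[carries_X]
    if (!length(evict)) break
    msa <- cpp_msa_remove_rows(msa, evict - 1L)
    removed_all <- c(removed_all, evict - 1L)
  }
  list(msa = msa, removed = removed_all, iterations = iterations)
}

#' Classify an MSA as high or low quality
#'
#' Aggregates column support and coverage over the anchor-covered columns;
#' the MSA is high-quality iff the minimum support, average support and
#' minimum coverage all reach their thresholds. High-quality MSAs are
#' corrected by unconditional consensus replacement, low-quality ones
#' conservatively (or by the classifier in forest mode).
#'
#' @param msa a `corread_msa`.
#' @param min_support,avg_support,min_coverage thresholds (defaults 0.75,
#'   0.90, 5).
#' @return an `msa_quality` list: `min_support`, `avg_support`,
#'   `min_coverage`, `avg_coverage`, `max_coverage`, `is_high_quality`.
#' @export
classify_msa <- function(msa, min_support = 0.75, avg_support = 0.90,
                         min_coverage = 5L) {
  acols <- anchor_columns(msa)
  sup <- msa$support[acols]
  cov <- msa$coverage[acols]
  sup[is.na(sup)] <- 0
  q <- list(min_support = min(sup), avg_support = mean(sup),
            min_coverage = min(cov), avg_coverage = mean(cov),
            max_coverage = max(cov))
  q$is_high_quality <- q$min_support >= min_support &&
    q$avg_support >= avg_support && q$min_coverage >= min_coverage
  structure(q, class = "msa_quality")
}
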