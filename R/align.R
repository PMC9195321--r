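#' Gapless semi-global alignment by shifted Hamming distance
#'
#' Aligns each candidate against the anchor at every shift whose geometric
#' overlap reaches `min_overlap_ratio * nchar(anchor)`, in both the forward
#' and reverse-complement orientation, and returns the placement minimizing
#' the mismatch/overlap ratio (ties: smaller `|shift|`, then forward).
#' Positions where either base is `N` are mismatch-neutral: excluded from
#' both the mismatch count and the reported overlap.
#'
#' @param anchor anchor sequence (string).
#' @param candidates character vector of candidate sequences.
#' @param min_overlap_ratio minimum overlap as a fraction of the anchor
#'   length (default 0.3).
#' @return data.frame with one row per candidate: `shift` (candidate start
#'   relative to anchor start), `overlap`, `mismatches`, `reverse`, `ratio`,
#'   `valid` (`FALSE`, with `NA` elsewhere, when no shift meets the overlap
#'   floor).
#' @export
align_shd <- function(anchor, candidates, min_overlap_ratio = 0.3) {
  stopifnot(nchar(anchor) > 0)
  if (min_overlap_ratio <= 0 || min_overlap_ratio > 1) {
    stop("min_overlap_ratio must be in (0, 1]")
  }
  out <- cpp_align_shd(anchor, as.character(candidates), min_overlap_ratio)
  structure(out, class = "data.frame",
            row.names = if (length(out$shift)) seq_along(out$shift) else integer(0))
}

#' Single-end candidate filter
#'
#' Keeps exactly the candidates whose alignment is valid and whose
#' mismatch/overlap ratio does not surpass `max_mismatch_ratio`; order is
#' preserved. Removal happens only when the ratio is strictly above the
#' threshold.
#'
#' @param alignments data.frame from [align_shd()].
#' @param max_mismatch_ratio threshold on mismatches/overlap (default 0.2).
#' @return logical vector: which candidates are kept.
#' @export
filter_single <- function(alignments, max_mismatch_ratio = 0.2) {
  keep <- alignments$valid & alignments$ratio <= max_mismatch_ratio
  keep & !is.na(keep)
}

#' Paired-end candidate filter
#'
#' For an anchor pair `(a0, a1)`, a candidate of `a0` whose mate is itself a
#' candidate of `a1` passes unconditionally (and vice versa) — both reads of
#' such a candidate pair very likely originate from the anchor pair's
#' genomic region. All other candidates pass only if their mismatch/overlap
#' ratio is strictly below `t_paired`. Candidates with invalid alignments
#' never pass (they cannot be placed in the MSA).
#'
#' @param ids0,ids1 0-based candidate read ids for anchor `a0` / `a1`.
#' @param aln0,aln1 matching [align_shd()] rows for the two candidate sets.
#' @param t_paired threshold (default 0.06).
#' @return list with logical vectors `keep0`, `keep1`.
#' @export
filter_paired <- function(ids0, aln0, ids1, aln1, t_paired = 0.06) {
  stopifnot(length(ids0) == nrow(aln0), length(ids1) == nrow(aln1))
  pair0 <- mate_id(ids0) %in% ids1
  pair1 <- mate_id(ids1) %in% ids0
  ok0 <- aln0$valid & !is.na(aln0$valid)
  ok1 <- aln1$valid & !is.na(aln1$valid)
  keep0 <- ok0 & (pair0 | (!is.na(aln0$ratio) & aln0$ratio < t_paired))
  keep1 <- ok1 & (pair1 | (!is.na(aln1$ratio) & aln1$ratio < t_paired))
  list(keep0 = keep0, keep1 = keep1)
}
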