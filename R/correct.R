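#' Rule-based anchor correction
#'
#' High-quality MSAs: every anchor position is replaced by the column
#' consensus unconditionally. Low-quality MSAs: a position is changed to the
#' consensus only if the column support is strictly greater than 0.90 and
#' the anchor's own nucleotide appears at most twice in the column.
#' Uncovered columns (possible only for `N` anchor bases without candidate
#' coverage) keep the original base.
#'
#' @param msa a refined `corread_msa`.
#' @param quality an [classify_msa()] result.
#' @param support_threshold low-quality support rule (default 0.90, strict).
#' @param max_orig_count low-quality count rule (default 2).
#' @return a correction record: list with `corrected_sequence`, `edits`
#'   (data.frame `position` 0-based, `old`, `new`) and `kind = "anchor"`.
#' @export
correct_anchor_classic <- function(msa, quality, support_threshold = 0.90,
                                   max_orig_count = 2L) {
  acols <- anchor_columns(msa)
  orig <- strsplit(msa$anchor_seq, "")[[1L]]
  cons <- msa_consensus(msa, acols, fallback = orig)
  if (quality$is_high_quality) {
    corrected <- cons
  } else {
    sup <- msa$support[acols]
    code <- msa$anchor_code[seq_along(acols)] # 0..3, 4 for N
    orig_count <- integer(length(acols))
    real <- code < 4L
    orig_count[real] <- msa$counts[, acols, drop = FALSE][cbind(code[real] + 1L,
                                                                which(real))]
    change <- !is.na(sup) & sup > support_threshold & orig_count <= max_orig_count
    corrected <- ifelse(change, cons, orig)
  }
  correction_record(orig, corrected, "anchor")
}

correction_record <- function(orig, corrected, kind) {
  diff <- which(corrected != orig)
  edits <- structure(list(position = diff - 1L, old = orig[diff],
                          new = corrected[diff]),
                     class = "data.frame",
                     row.names = if (length(diff)) seq_along(diff) else integer(0))
  list(corrected_sequence = paste(corrected, collapse = ""),
       edits = edits, kind = kind)
}

#' Candidate corrections from a high-quality MSA
#'
#' A surviving candidate fully contained in the column range `[b - x, e + x)`
#' around the anchor region `[b, e)` is rewritten to the column consensus
#' across its columns; candidates reaching outside that range produce no
#' record. Reverse-complement candidates are re-complemented so the
#' corrected sequence and its edits are reported in the read's original
#' orientation.
#'
#' @param msa a refined `corread_msa`.
#' @param quality an [classify_msa()] result; must be high-quality.
#' @param reverse logical vector: was each candidate aligned as a reverse
#'   complement?
#' @param x column margin around the anchor region (default 15).
#' @return list of correction records (`kind = "candidate"`), each with a
#'   `cand_index` (0-based index into the MSA's candidate rows).
#' @export
correct_candidates <- function(msa, quality, reverse, x = 15L) {
  if (!quality$is_high_quality) {
    stop("candidate corrections are only produced from high-quality MSAs")
  }
  idx <- eligible_candidates(msa, x)
  lapply(idx, function(i) {
    rec <- candidate_consensus_record(msa, i, reverse[i])
    rec$cand_index <- i - 1L
    rec
  })
}

# 1-based indices of active candidates fully inside [b - x, e + x)
eligible_candidates <- function(msa, x) {
  lens <- nchar(msa$cand_seqs)
  ok <- msa$active & msa$shifts >= -x & (msa$shifts + lens) <= msa$anchor_len + x
  which(ok)
}

candidate_consensus_record <- function(msa, i, is_reverse, keep = NULL) {
  len <- nchar(msa$cand_seqs[i])
  cols <- seq(msa$shifts[i] - msa$first + 1L, length.out = len)
  oriented_orig <- strsplit(msa$cand_seqs[i], "")[[1L]]
  oriented_new <- msa_consensus(msa, cols, fallback = oriented_orig)
  if (!is.null(keep)) { # positions (1-based, oriented) to leave unchanged
    oriented_new[keep] <- oriented_orig[keep]
  }
  if (is_reverse) {
    orig <- strsplit(revcomp(paste(oriented_orig, collapse = "")), "")[[1L]]
    corrected <- strsplit(revcomp(paste(oriented_new, collapse = "")), "")[[1L]]
  } else {
    orig <- oriented_orig
    corrected <- oriented_new
  }
  correction_record(orig, corrected, "candidate")
}
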