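#' Reconcile anchor and candidate corrections into final reads
#'
#' Corrections proposed for the same read are merged per read: (i) with
#' fewer than three candidate corrections the anchor correction wins if
#' present; (ii) with three or more, the anchor correction is used only if
#' it is string-equal to every candidate correction, otherwise the original
#' read is kept; (iii) a read with no anchor correction adopts its candidate
#' corrections only if there are at least three and they all agree, else it
#' stays original. Reconciliation is order-independent in the record stream.
#'
#' @param originals character vector of the original read sequences
#'   (position `i` = read id `i - 1`).
#' @param anchor_seqs character vector parallel to `originals` with each
#'   read's anchor-corrected sequence, or `NA` where no anchor record
#'   exists.
#' @param cand_read_ids 0-based read ids of the candidate records.
#' @param cand_seqs corrected sequences of the candidate records.
#' @return list with `sequence` (final corrected reads) and `decision`
#'   (per read: `anchor_used`, `candidates_agree`, `kept_original`,
#'   `no_records`).
#' @export
merge_corrections <- function(originals, anchor_seqs, cand_read_ids = integer(0),
                              cand_seqs = character(0)) {
  n <- length(originals)
  stopifnot(length(anchor_seqs) == n, length(cand_read_ids) == length(cand_seqs))
  if (length(cand_read_ids) && (min(cand_read_ids) < 0L || max(cand_read_ids) >= n)) {
    stop("consistency error: candidate record for unknown read id")
  }
  final <- originals
  decision <- rep("no_records", n)
  has_anchor <- !is.na(anchor_seqs)
  final[has_anchor] <- anchor_seqs[has_anchor]
  decision[has_anchor] <- "anchor_used"

  by_read <- split(cand_seqs, factor(cand_read_ids, levels = 0:(n - 1L)))
  ncand <- lengths(by_read)
  for (i in which(ncand > 0L)) {
    cands <- by_read[[i]]
    if (has_anchor[i]) {
      if (length(cands) < 3L) next # anchor already in place
      if (all(cands == anchor_seqs[i])) next
      final[i] <- originals[i]
      decision[i] <- "kept_original"
    } else {
      if (length(cands) >= 3L && length(unique(cands)) == 1L) {
        final[i] <- cands[1L]
        decision[i] <- "candidates_agree"
      } else {
        final[i] <- originals[i]
        decision[i] <- "kept_original"
      }
    }
  }
  list(sequence = final, decision = decision)
}

#' Write corrected reads, preserving input layout
#'
#' Emits the final sequences with the original headers and (unbinned)
#' quality strings, in input order; paired read sets keep their R1/R2
#' split. A run with zero corrections reproduces the input byte-identically.
#'
#' @param reads the original `read_set`.
#' @param final_sequences character vector of final per-read sequences.
#' @param path,paired_path output FASTQ path(s).
#' @return invisibly, the path(s) written.
#' @export
write_output <- function(reads, final_sequences, path, paired_path = NULL) {
  stopifnot(length(final_sequences) == length(reads$sequence))
  if (any(nchar(final_sequences) != nchar(reads$sequence))) {
    stop("corrected sequence length differs from original read length")
  }
  out <- new_read_set(final_sequences, reads$quality, reads$header,
                      paired = reads$paired)
  write_fastq(out, path, paired_path)
}
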