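#' Correct a read set end to end
#'
#' Runs the three phases over an in-memory read set: *construction* (minhash
#' index over canonical k-mers), *correction* (per anchor: candidate
#' retrieval, shifted-Hamming alignment, single- or paired-end filtering,
#' weighted MSA construction and refinement, rule-based or forest-based
#' per-base correction of the anchor and, from high-quality MSAs, of
#' candidates), and *merge* (per-read reconciliation of anchor and candidate
#' corrections). The pipeline is deterministic for a fixed seed: the only
#' randomness is the hash-seed derivation.
#'
#' Reads that cannot be indexed (shorter than `k`, or no N-free k-mer
#' window) are passed through uncorrected.
#'
#' @param reads a `read_set` from [read_fastq()] or [simulate_reads()].
#' @param coverage estimated dataset fold coverage (required; drives MSA
#'   refinement).
#' @param mode `"classic"` (rule-based low-quality correction) or
#'   `"forest"` (classifier-based; requires both models).
#' @param paired use the paired-end candidate filter (defaults to the read
#'   set's pairing).
#' @param k k-mer length (default 20).
#' @param num_tables minhash tables (default 48).
#' @param anchor_model,candidate_model `forest_model`s (forest mode).
#' @param threshold forest correction threshold (default 0.9).
#' @param quality_bits quality representation used for MSA weights: 8 (raw),
#'   2 or 1 (binned); output qualities are always the originals.
#' @param min_overlap_ratio,max_mismatch_ratio,t_paired alignment/filter
#'   parameters (defaults 0.3, 0.2, 0.06).
#' @param refinement_factor,max_refinement_iters MSA refinement parameters
#'   (defaults 0.3, 5).
#' @param hq_min_support,hq_avg_support,hq_min_coverage high-quality MSA
#'   thresholds (defaults 0.75, 0.90, 5).
#' @param candidate_margin column margin `x` for candidate corrections
#'   (default 15).
#' @param max_candidates per-query candidate cap (default 1000).
#' @param candidate_correction produce candidate corrections (default TRUE)?
#' @param seed hash seed.
#' @param harvest collect classifier training features instead of
#'   correcting (requires `truth`).
#' @param truth error-free twin `read_set` (harvest mode).
#' @param audit include a per-read decision log in the report.
#' @return list with `reads` (corrected `read_set`), `report` (parameters
#'   and per-phase counts), and in harvest mode `harvest` (anchor and
#'   candidate feature data.frames with a logical `label` column).
#' @export
correct_read_set <- function(reads, coverage,
                             mode = c("classic", "forest"),
                             paired = reads$paired,
                             k = 20L, num_tables = 48L,
                             anchor_model = NULL, candidate_model = NULL,
                             threshold = 0.9, quality_bits = 8L,
                             min_overlap_ratio = 0.3, max_mismatch_ratio = 0.2,
                             t_paired = 0.06,
                             refinement_factor = 0.3, max_refinement_iters = 5L,
                             hq_min_support = 0.75, hq_avg_support = 0.90,
                             hq_min_coverage = 5L,
                             candidate_margin = 15L, max_candidates = 1000L,
                             candidate_correction = TRUE,
                             seed = 1L, harvest = FALSE, truth = NULL,
                             audit = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(reads, "read_set"))
  if (coverage <= 0) stop("config error: coverage must be positive")
  if (mode == "forest" && !harvest &&
      (is.null(anchor_model) || is.null(candidate_model))) {
    stop("startup error: forest mode requires an anchor and a candidate model")
  }
  if (harvest && (is.null(truth) || length(truth) != length(reads))) {
    stop("harvest mode requires the error-free twin read set")
  }
  if (paired && !reads$paired) stop("paired mode requires a paired read set")
  binning <- quality_binning(switch(as.character(quality_bits),
                                    "8" = "raw8", "2" = "bins2", "1" = "bins1",
                                    stop("quality_bits must be 8, 2 or 1")))
  n <- length(reads)
  phreds <- binned_phred_list(reads, binning)
  index <- build_index(reads, k, num_tables, seed, max_candidates)

  env <- new.env(parent = emptyenv())
  env$anchor_corr <- reads$sequence # pass-through default
  env$cand_ids <- vector("list", n)
  env$cand_seqs <- vector("list", n)
  env$harvest_anchor <- vector("list", n)
  env$harvest_cand <- vector("list", n)
  env$retrieved <- 0L; env$kept <- 0L; env$refined_away <- 0L
  env$hq <- 0L; env$anchors <- 0L; env$anchor_edits <- 0L

  process_anchor <- function(aid0, cand_ids, aln, keep) {
    env$anchors <- env$anchors + 1L
    env$retrieved <- env$retrieved + length(cand_ids)
    kept_ids <- cand_ids[keep]
    env$kept <- env$kept + length(kept_ids)
    i1 <- aid0 + 1L
    if (!length(kept_ids)) return(invisible())
    kept_aln <- aln[keep, , drop = FALSE]
    msa <- build_msa(reads$sequence[i1], phreds[[i1]],
                     reads$sequence[kept_ids + 1L], phreds[kept_ids + 1L],
                     kept_aln)
    ref <- refine_msa(msa, coverage, refinement_factor, max_refinement_iters)
    msa <- ref$msa
    env$refined_away <- env$refined_away + length(ref$removed)
    qual <- classify_msa(msa, hq_min_support, hq_avg_support, hq_min_coverage)
    if (qual$is_high_quality) env$hq <- env$hq + 1L

    if (harvest) {
      harvest_from_msa(env, msa, qual, kept_ids, kept_aln, aid0, reads, truth,
                       coverage, candidate_margin)
      return(invisible())
    }
    rec <- if (mode == "forest") {
      correct_anchor_forest(msa, qual, anchor_model, threshold, coverage)
    } else {
      correct_anchor_classic(msa, qual)
    }
    env$anchor_corr[i1] <- rec$corrected_sequence
    env$anchor_edits <- env$anchor_edits + nrow(rec$edits)

    if (qual$is_high_quality && candidate_correction) {
      recs <- if (mode == "forest") {
        correct_candidates_forest(msa, qual, kept_aln$reverse, kept_aln,
                                  candidate_model, threshold,
                                  candidate_margin, coverage)
      } else {
        correct_candidates(msa, qual, kept_aln$reverse, candidate_margin)
      }
      if (length(recs)) {
        env$cand_ids[[i1]] <- kept_ids[vapply(recs, `[[`, integer(1L), "cand_index") + 1L]
        env$cand_seqs[[i1]] <- vapply(recs, `[[`, character(1L), "corrected_sequence")
      }
    }
    invisible()
  }

  query_and_align <- function(aid0) {
    ids <- query_candidates(index, aid0)
    if (!length(ids)) {
      return(list(ids = ids, aln = align_shd("A", character(0), 1)))
    }
    list(ids = ids,
         aln = align_shd(reads$sequence[aid0 + 1L], reads$sequence[ids + 1L],
                         min_overlap_ratio))
  }

  if (paired) {
    for (pi in seq_len(n %/% 2L) - 1L) {
      a0 <- 2L * pi; a1 <- a0 + 1L
      q0 <- query_and_align(a0); q1 <- query_and_align(a1)
      fp <- filter_paired(q0$ids, q0$aln, q1$ids, q1$aln, t_paired)
      process_anchor(a0, q0$ids, q0$aln, fp$keep0)
      process_anchor(a1, q1$ids, q1$aln, fp$keep1)
    }
  } else {
    for (aid0 in seq_len(n) - 1L) {
      q <- query_and_align(aid0)
      process_anchor(aid0, q$ids, q$aln, filter_single(q$aln, max_mismatch_ratio))
    }
  }

  if (harvest) {
    return(list(reads = reads,
                harvest = list(anchor = rbind_or_empty(env$harvest_anchor),
                               candidate = rbind_or_empty(env$harvest_cand)),
                report = list(anchors_processed = env$anchors)))
  }

  cand_ids_all <- as.integer(unlist(env$cand_ids, use.names = FALSE))
  cand_seqs_all <- as.character(unlist(env$cand_seqs, use.names = FALSE))
  merged <- merge_corrections(reads$sequence, env$anchor_corr,
                              cand_ids_all, cand_seqs_all)
  corrected <- new_read_set(merged$sequence, reads$quality, reads$header,
                            paired = reads$paired)
  report <- list(
    parameters = list(mode = mode, paired = paired, coverage = coverage,
                      k = k, num_tables = num_tables, threshold = threshold,
                      quality_bits = quality_bits,
                      min_overlap_ratio = min_overlap_ratio,
                      max_mismatch_ratio = max_mismatch_ratio,
                      t_paired = t_paired,
                      refinement_factor = refinement_factor,
                      max_refinement_iters = max_refinement_iters,
                      hq_min_support = hq_min_support,
                      hq_avg_support = hq_avg_support,
                      hq_min_coverage = hq_min_coverage,
                      candidate_margin = candidate_margin,
                      max_candidates = max_candidates, seed = seed,
                      version = as.character(utils::packageVersion("corread"))),
    n_reads = n,
    anchors_processed = env$anchors,
    candidates_retrieved = env$retrieved,
    candidates_kept = env$kept,
    removed_by_refinement = env$refined_away,
    high_quality_msas = env$hq,
    anchor_edit_positions = env$anchor_edits,
    candidate_records = length(cand_ids_all),
    reads_changed = sum(merged$sequence != reads$sequence),
    merge_decisions = table(merged$decision))
  if (audit) {
    report$audit <- data.frame(read_id = seq_len(n) - 1L,
                               decision = merged$decision,
                               stringsAsFactors = FALSE)
  }
  list(reads = corrected, report = report)
}

rbind_or_empty <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, lst)
}

# Collect training examples from one refined MSA: anchor examples from
# low-quality MSAs, candidate examples from high-quality ones, at positions
# where the observed base differs from the consensus. Label: the consensus
# equals the error-free base (the proposed correction would be right).
harvest_from_msa <- function(env, msa, qual, kept_ids, kept_aln, aid0, reads,
                             truth, coverage, candidate_margin) {
  i1 <- aid0 + 1L
  if (!qual$is_high_quality) {
    acols <- anchor_columns(msa)
    orig <- strsplit(msa$anchor_seq, "")[[1L]]
    cons <- msa_consensus(msa, acols, fallback = orig)
    pos <- which(cons != orig & msa$consensus[acols] >= 0L)
    if (length(pos)) {
      fv <- extract_features(msa, pos - 1L, "anchor", estimated_coverage = coverage)
      e <- strsplit(truth$sequence[i1], "")[[1L]]
      fv$label <- cons[pos] == e[pos]
      env$harvest_anchor[[i1]] <- fv
    }
  } else {
    idx <- eligible_candidates(msa, candidate_margin)
    out <- lapply(idx, function(i) {
      len <- nchar(msa$cand_seqs[i])
      cols <- seq(msa$shifts[i] - msa$first + 1L, length.out = len)
      codes <- match(strsplit(msa$cand_seqs[i], "")[[1L]], BASES) - 1L
      codes[is.na(codes)] <- 4L
      dpos <- which(msa$consensus[cols] >= 0L & codes != msa$consensus[cols])
      if (!length(dpos)) return(NULL)
      fv <- extract_features(msa, dpos - 1L, "candidate", cand_index = i - 1L,
                             alignment = kept_aln[i, , drop = FALSE],
                             estimated_coverage = coverage)
      tr <- truth$sequence[kept_ids[i] + 1L]
      if (kept_aln$reverse[i]) tr <- revcomp(tr)
      e <- strsplit(tr, "")[[1L]]
      fv$label <- BASES[msa$consensus[cols[dpos]] + 1L] == e[dpos]
      fv
    })
    out <- Filter(Negate(is.null), out)
    if (length(out)) env$harvest_cand[[i1]] <- do.call(rbind, out)
  }
  invisible()
}

#' File-level correction driver
#'
#' Reads FASTQ input, runs [correct_read_set()] and writes the corrected
#' FASTQ (mirroring the single/paired input layout) plus an optional JSON
#' run report.
#'
#' @param input FASTQ path (R1 in paired mode).
#' @param input2 optional R2 FASTQ path.
#' @param out_prefix output prefix; writes `<prefix>.fastq` or
#'   `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @param report_path optional path for the JSON run report.
#' @param ... passed to [correct_read_set()] (`coverage` is required).
#' @return invisibly, the [correct_read_set()] result.
#' @export
run_correction <- function(input, input2 = NULL, out_prefix,
                           report_path = NULL, ...) {
  reads <- read_fastq(input, input2)
  res <- correct_read_set(reads, ...)
  if (reads$paired) {
    write_fastq(res$reads, paste0(out_prefix, "_1.fastq"),
                paste0(out_prefix, "_2.fastq"))
  } else {
    write_fastq(res$reads, paste0(out_prefix, ".fastq"))
  }
  if (!is.null(report_path)) {
    rep <- res$report
    rep$merge_decisions <- as.list(rep$merge_decisions)
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(res)
}
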