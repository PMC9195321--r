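# Independent oracles, kept deliberately naive.

oracle_revcomp <- function(s) {
  # independent of the package's C++ path
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# Naive shifted-Hamming oracle: try every shift and both orientations,
# count mismatches over non-N positions, minimize mismatches/overlap with
# the smaller-|shift|-then-forward tie-break.
oracle_align <- function(anchor, cand, min_overlap_ratio = 0.3) {
  a <- strsplit(anchor, "")[[1L]]
  la <- length(a)
  min_ov <- max(1L, ceiling(min_overlap_ratio * la))
  best <- NULL
  for (orient in c(FALSE, TRUE)) {
    b <- strsplit(if (orient) oracle_revcomp(cand) else cand, "")[[1L]]
    lb <- length(b)
    for (s in seq(-(lb - min_ov), la - min_ov)) {
      lo <- max(0L, s); hi <- min(la, s + lb)
      if (hi - lo < min_ov) next
      ai <- a[(lo + 1L):hi]; bi <- b[(lo - s + 1L):(hi - s)]
      use <- ai != "N" & bi != "N"
      ov <- sum(use)
      if (ov == 0L) next
      mism <- sum(ai[use] != bi[use])
      cand_res <- list(shift = s, overlap = ov, mismatches = mism,
                       reverse = orient, ratio = mism / ov)
      if (is.null(best)) { best <- cand_res; next }
      better <- FALSE
      if (cand_res$mismatches * best$overlap != best$mismatches * cand_res$overlap) {
        better <- cand_res$mismatches * best$overlap < best$mismatches * cand_res$overlap
      } else if (abs(s) != abs(best$shift)) {
        better <- abs(s) < abs(best$shift)
      } else {
        better <- !orient && best$reverse
      }
      if (better) best <- cand_res
    }
  }
  best
}

# Brute-force minhash query: recompute every read's signature from the
# per-window hash matrix, then take the union of exact-key matches.
oracle_query <- function(seqs, anchor_idx1, k, num_tables, seed) {
  seeds <- corread:::cpp_hash_seeds(seed, num_tables)
  sigs <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(rep(NA_real_, num_tables))
    hm <- corread:::cpp_kmer_hashes(s, k, seeds)
    if (all(is.na(hm))) return(rep(NA_real_, num_tables))
    apply(hm, 2L, min, na.rm = TRUE)
  })
  q <- sigs[[anchor_idx1]]
  if (anyNA(q)) return(integer(0))
  hits <- integer(0)
  for (l in seq_len(num_tables)) {
    for (j in seq_along(seqs)) {
      if (!anyNA(sigs[[j]]) && sigs[[j]][l] == q[l]) hits <- c(hits, j - 1L)
    }
  }
  sort(setdiff(unique(hits), anchor_idx1 - 1L))
}

# vectorized canonical form of equal-length k-mers
canon_vec <- function(kmers) {
  k <- nchar(kmers[1L])
  comp <- chartr("ACGT", "TGCA", kmers)
  rc <- do.call(paste0, lapply(k:1, function(i) substring(comp, i, i)))
  pmin(kmers, rc)
}

all_kmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s)))
  }), use.names = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

phred_string <- function(q) intToUtf8(q + 33L)
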