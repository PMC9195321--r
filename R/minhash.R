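#' Minhash signatures of reads
#'
#' The signature of a read is, for each of `h` hash functions, the smallest
#' hash value over all canonical k-mers of the read (a k-mer and its reverse
#' complement hash identically, so signatures are strand-invariant). Windows
#' containing `N` are skipped; a read shorter than `k` (or with no valid
#' window) has an all-`NA` signature and is unindexable.
#'
#' @param seqs character vector of read sequences.
#' @param k k-mer length (default 20).
#' @param num_tables number of hash functions / tables `h` (default 48).
#' @param seed integer seed from which the per-function hash seeds derive.
#' @return numeric matrix, `length(seqs)` rows by `num_tables` columns.
#' @export
compute_signatures <- function(seqs, k = 20L, num_tables = 48L, seed = 1L) {
  seeds <- cpp_hash_seeds(as.double(seed), as.integer(num_tables))
  cpp_signatures(as.character(seqs), as.integer(k), seeds)
}

#' Build a minhash index over a read set
#'
#' Inserts every indexable read into `num_tables` hash tables, table `l`
#' keyed by the read's signature value `S[l]`.
#'
#' @param reads a `read_set` or character vector of sequences.
#' @param k k-mer length.
#' @param num_tables number of hash tables.
#' @param seed hash seed.
#' @param max_candidates cap on the number of candidate ids a single query
#'   may return; over-full queries drop the most populous table buckets
#'   first.
#' @return a `minhash_index` object.
#' @export
build_index <- function(reads, k = 20L, num_tables = 48L, seed = 1L,
                        max_candidates = 1000L) {
  seqs <- if (inherits(reads, "read_set")) reads$sequence else as.character(reads)
  sig <- compute_signatures(seqs, k, num_tables, seed)
  indexable <- !is.na(sig[, 1L])
  ids0 <- which(indexable) - 1L # 0-based read ids
  tables <- vector("list", num_tables)
  for (l in seq_len(num_tables)) {
    keys <- sprintf("%.0f", sig[indexable, l])
    tables[[l]] <- list2env(split(ids0, keys), hash = TRUE,
                            size = max(29L, length(ids0)))
  }
  structure(list(tables = tables, signatures = sig, k = as.integer(k),
                 num_tables = as.integer(num_tables), seed = as.integer(seed),
                 max_candidates = as.integer(max_candidates),
                 n_reads = length(seqs), unindexable = which(!indexable) - 1L),
            class = "minhash_index")
}

#' @export
print.minhash_index <- function(x, ...) {
  cat(sprintf("minhash_index: %d reads (%d unindexable), k=%d, %d tables\n",
              x$n_reads, length(x$unindexable), x$k, x$num_tables))
  invisible(x)
}

#' Query candidate reads for an anchor
#'
#' Looks up the anchor's signature value in each hash table and returns the
#' union of the bucket contents, with the anchor's own id removed. If the
#' union would exceed `max_candidates`, buckets are admitted smallest first
#' and the most populous buckets are dropped.
#'
#' @param index a [build_index()] result.
#' @param read_id 0-based id of an indexed anchor read, or `NULL` when
#'   querying by sequence.
#' @param seq anchor sequence (used when `read_id` is `NULL`; its signature
#'   is computed on the fly and no self-exclusion applies beyond `read_id`).
#' @return sorted integer vector of 0-based candidate read ids (possibly
#'   empty; empty for unindexable anchors).
#' @export
query_candidates <- function(index, read_id = NULL, seq = NULL) {
  stopifnot(inherits(index, "minhash_index"))
  if (!is.null(read_id)) {
    sig <- index$signatures[read_id + 1L, ]
  } else {
    sig <- compute_signatures(seq, index$k, index$num_tables, index$seed)[1L, ]
  }
  if (anyNA(sig)) return(integer(0))
  keys <- sprintf("%.0f", sig)
  buckets <- lapply(seq_len(index$num_tables), function(l) {
    b <- get0(keys[l], envir = index$tables[[l]], inherits = FALSE)
    if (is.null(b)) integer(0) else b
  })
  ids <- unique(unlist(buckets, use.names = FALSE))
  if (length(ids) > index$max_candidates) {
    # admit buckets smallest-first until the cap would be breached
    ord <- order(lengths(buckets))
    ids <- integer(0)
    for (l in ord) {
      nxt <- unique(c(ids, buckets[[l]]))
      if (length(nxt) > index$max_candidates) break
      ids <- nxt
    }
  }
  if (!is.null(read_id)) ids <- setdiff(ids, as.integer(read_id))
  sort(as.integer(ids))
}
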