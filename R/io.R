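#' Read FASTQ files into a read set
#'
#' Parses one FASTQ file (single-end) or two (paired-end R1/R2), plain or
#' gzipped, Sanger Phred+33 qualities. In paired mode the two files are
#' interleaved so that mates occupy indices `2*i` and `2*i + 1` (0-based):
#' read `2*i` comes from `path`, read `2*i + 1` from `paired_path`.
#'
#' @param path FASTQ file (R1 in paired mode).
#' @param paired_path optional second FASTQ file (R2); must contain the same
#'   number of records as `path`.
#' @return A `read_set`: list with `sequence` (character), `quality`
#'   (character, ASCII Phred+33), `header` (character, without the leading
#'   `@`), and `paired` (logical scalar).
#' @export
read_fastq <- function(path, paired_path = NULL) {
  r1 <- parse_fastq_file(path)
  if (is.null(paired_path)) {
    return(new_read_set(r1$sequence, r1$quality, r1$header, paired = FALSE))
  }
  r2 <- parse_fastq_file(paired_path)
  if (length(r1$sequence) != length(r2$sequence)) {
    stop(sprintf("pairing error: '%s' has %d records but '%s' has %d",
                 path, length(r1$sequence), paired_path, length(r2$sequence)))
  }
  n <- length(r1$sequence)
  idx <- rep(seq_len(n), each = 2L)
  take2 <- rep(c(FALSE, TRUE), n)
  seqs <- ifelse(take2, r2$sequence[idx], r1$sequence[idx])
  quals <- ifelse(take2, r2$quality[idx], r1$quality[idx])
  heads <- ifelse(take2, r2$header[idx], r1$header[idx])
  new_read_set(seqs, quals, heads, paired = TRUE)
}

parse_fastq_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  con <- gzfile(path, "rt") # gzfile transparently reads plain text too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("parse error in '%s': line count %d is not a multiple of 4",
                 path, length(lines)))
  }
  n <- length(lines) %/% 4L
  at <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(at, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("parse error in '%s': record %d is malformed (missing @ or + line)",
                 path, bad[1L]))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("parse error in '%s': record %d sequence length %d != quality length %d",
                 path, bad[1L], nchar(seqs[bad[1L]]), nchar(quals[bad[1L]])))
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    stop(sprintf("parse error in '%s': record %d contains a non-ACGTN character",
                 path, bad[1L]))
  }
  list(sequence = seqs, quality = quals, header = sub("^@", "", at))
}

new_read_set <- function(sequence, quality, header = NULL, paired = FALSE) {
  sequence <- as.character(sequence)
  quality <- as.character(quality)
  if (is.null(header)) header <- paste0("read", seq_along(sequence) - 1L)
  stopifnot(length(sequence) == length(quality),
            length(sequence) == length(header))
  if (any(nchar(sequence) != nchar(quality))) {
    stop("sequence and quality lengths differ")
  }
  if (paired && length(sequence) %% 2L != 0L) {
    stop("paired read set must contain an even number of reads")
  }
  structure(list(sequence = sequence, quality = quality,
                 header = as.character(header), paired = isTRUE(paired)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%s), lengths %d..%d\n",
              length(x$sequence), if (x$paired) "paired" else "single",
              if (length(x$sequence)) min(nchar(x$sequence)) else 0L,
              if (length(x$sequence)) max(nchar(x$sequence)) else 0L))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$sequence)

#' Mate index of a read
#'
#' Under the paired numbering convention reads `2*i` and `2*i + 1` (0-based)
#' form a pair, so the mate of id `j` is `j` with its lowest bit flipped.
#'
#' @param read_id 0-based read id(s).
#' @return 0-based mate id(s).
#' @export
mate_id <- function(read_id) {
  bitwXor(as.integer(read_id), 1L)
}

#' Write a read set to FASTQ
#'
#' Output mirrors the input layout: single-end read sets go to one file;
#' paired read sets are de-interleaved into `path` (R1, even indices) and
#' `paired_path` (R2, odd indices). Headers and qualities are written
#' verbatim, so `write_fastq(read_fastq(f), g)` reproduces `f` byte for
#' byte for well-formed input.
#'
#' @param reads a `read_set`.
#' @param path output FASTQ (R1 in paired mode).
#' @param paired_path output R2 FASTQ, required when `reads$paired`.
#' @return invisibly, the path(s) written.
#' @export
write_fastq <- function(reads, path, paired_path = NULL) {
  stopifnot(inherits(reads, "read_set"))
  emit <- function(idx, p) {
    out <- character(4L * length(idx))
    out[seq(1L, by = 4L, length.out = length(idx))] <- paste0("@", reads$header[idx])
    out[seq(2L, by = 4L, length.out = length(idx))] <- reads$sequence[idx]
    out[seq(3L, by = 4L, length.out = length(idx))] <- "+"
    out[seq(4L, by = 4L, length.out = length(idx))] <- reads$quality[idx]
    writeLines(out, p)
  }
  if (reads$paired) {
    if (is.null(paired_path)) stop("paired read set needs a second output path")
    n <- length(reads$sequence)
    emit(seq(1L, n, by = 2L), path)
    emit(seq(2L, n, by = 2L), paired_path)
    invisible(c(path, paired_path))
  } else {
    emit(seq_along(reads$sequence), path)
    invisible(path)
  }
}

#' Phred scores of a quality string
#'
#' @param qual ASCII Phred+33 quality string(s).
#' @return integer vector (single string) or list of integer vectors.
#' @export
phred_scores <- function(qual) {
  one <- function(q) as.integer(utf8ToInt(q)) - 33L
  if (length(qual) == 1L) one(qual) else lapply(qual, one)
}

#' 2-bit encode / decode a nucleotide sequence
#'
#' Sequences over `{A,C,G,T,N}` are packed four bases per byte; `N` is stored
#' as `A` in the 2-bit lane and flagged in a separate 1-bit mask so that
#' `decode_2bit(encode_2bit(s))` is the identity.
#'
#' @param seq nucleotide string.
#' @return `encode_2bit`: list with `bits` (raw), `nmask` (raw), `length`.
#' @export
encode_2bit <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_encode_2bit(toupper(seq))
}

#' @rdname encode_2bit
#' @param enc an object returned by `encode_2bit()`.
#' @export
decode_2bit <- function(enc) {
  cpp_decode_2bit(enc$bits, enc$nmask, enc$length)
}

#' Reverse complement
#'
#' @param seq nucleotide string(s) over `{A,C,G,T,N}`.
#' @return reverse-complemented string(s); `N` maps to `N`.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1L), USE.NAMES = FALSE)
}

#' Quality-score binning schemes
#'
#' Lossy binning of Phred scores to 2 bits (`"bins2"`: 4 bins, boundaries
#' 10/20/30, representatives 5/15/25/37), 1 bit (`"bins1"`: 2 bins, boundary
#' 20, representatives 6/37) or none (`"raw8"`, the identity). Binning is
#' monotone and idempotent: every representative lies inside its own bin.
#'
#' @param mode one of `"raw8"`, `"bins2"`, `"bins1"`.
#' @return a `quality_binning` object with `mode`, `boundaries`,
#'   `representative`.
#' @export
quality_binning <- function(mode = c("raw8", "bins2", "bins1")) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    raw8  = list(boundaries = integer(0), representative = integer(0)),
    bins2 = list(boundaries = c(10L, 20L, 30L),
                 representative = c(5L, 15L, 25L, 37L)),
    bins1 = list(boundaries = 20L, representative = c(6L, 37L)))
  structure(c(list(mode = mode), spec), class = "quality_binning")
}

#' Bin a Phred score
#'
#' @param q integer Phred score(s), 0..93.
#' @param binning a [quality_binning()] object.
#' @return the representative Phred value of each score's bin (`raw8`
#'   returns `q` unchanged).
#' @export
bin_quality <- function(q, binning) {
  stopifnot(inherits(binning, "quality_binning"))
  q <- as.integer(q)
  if (any(q < 0L | q > 93L)) stop("Phred score out of range 0..93")
  if (binning$mode == "raw8") return(q)
  bin <- findInterval(q, binning$boundaries) + 1L
  binning$representative[bin]
}

#' Map reads to the binned Phred representation used for MSA weights
#'
#' @param reads a `read_set`.
#' @param binning a [quality_binning()] object.
#' @return list of integer Phred vectors, one per read.
#' @keywords internal
binned_phred_list <- function(reads, binning) {
  lapply(reads$quality, function(q) bin_quality(utf8ToInt(q) - 33L, binning))
}
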