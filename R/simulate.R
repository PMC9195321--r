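#' Simulation configuration
#'
#' Conditions for the synthetic genome and Illumina-like read generator:
#' 100 bp reads at a mean per-base substitution error rate of 1%, the regime
#' of HiSeq-profile simulated benchmarks. Fragment sizes follow a normal
#' distribution (default 300 +/- 30 bp) in paired mode.
#'
#' @param genome_length genome size in bases.
#' @param coverage fold coverage; the number of reads is
#'   `ceiling(genome_length * coverage / read_length)`, rounded up to an even
#'   count in paired mode.
#' @param read_length read length in bases (default 100).
#' @param error_rate mean per-base substitution probability (default 0.01).
#' @param paired generate read pairs (mate reverse-complemented from the
#'   other fragment end)?
#' @param insert_mean,insert_sd fragment-size distribution (paired mode).
#' @param seed RNG seed.
#' @param repeat_spec optional `list(count=, unit_length=, divergence=)`
#'   planting near-identical repeat copies in the genome: each copy carries
#'   exactly `round(divergence * unit_length)` substitutions relative to the
#'   repeat unit, at positions disjoint across copies.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 10000L, coverage = 30, read_length = 100L,
                       error_rate = 0.01, paired = TRUE,
                       insert_mean = 300, insert_sd = 30,
                       seed = 1L, repeat_spec = NULL) {
  if (genome_length <= 0) stop("config error: genome_length must be positive")
  if (coverage <= 0) stop("config error: coverage must be positive")
  if (error_rate < 0 || error_rate > 0.75) stop("config error: error_rate out of [0, 0.75]")
  if (!is.null(repeat_spec)) {
    stopifnot(all(c("count", "unit_length", "divergence") %in% names(repeat_spec)))
    if (repeat_spec$unit_length > genome_length) {
      stop("config error: repeat unit longer than genome")
    }
  }
  structure(list(genome_length = as.integer(genome_length), coverage = coverage,
                 read_length = as.integer(read_length), error_rate = error_rate,
                 paired = isTRUE(paired), insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed),
                 repeat_spec = repeat_spec), class = "sim_config")
}

#' Simulate a genome
#'
#' Uniform random sequence over `{A,C,G,T}`; optionally plants inexact
#' repeat copies (see [sim_config()]) to exercise MSA refinement on reads
#' mapping to near-identical repeat regions.
#'
#' @param config a [sim_config()].
#' @return a single nucleotide string of length `config$genome_length`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, config$genome_length, replace = TRUE)
  rs <- config$repeat_spec
  if (!is.null(rs) && rs$count > 0) {
    unit <- sample(bases, rs$unit_length, replace = TRUE)
    nsub <- round(rs$divergence * rs$unit_length)
    # disjoint mutated positions across copies: pairwise copy distance is
    # exactly 2 * nsub, deterministic given the config
    pos_pool <- sample.int(rs$unit_length, nsub * rs$count)
    slots <- slot_starts(config$genome_length, rs$unit_length, rs$count)
    for (i in seq_len(rs$count)) {
      cp <- unit
      mut <- pos_pool[seq((i - 1L) * nsub + 1L, length.out = nsub)]
      for (p in mut) cp[p] <- sample(setdiff(bases, cp[p]), 1L)
      g[seq(slots[i], length.out = rs$unit_length)] <- cp
    }
  }
  paste(g, collapse = "")
}

# non-overlapping, evenly spread 1-based start positions for repeat copies
slot_starts <- function(genome_length, unit_length, count) {
  if (count * unit_length > genome_length) {
    stop("config error: repeat copies do not fit in the genome")
  }
  gap <- (genome_length - count * unit_length) %/% (count + 1L)
  cumsum(c(gap + 1L, rep(unit_length + gap, count - 1L)))
}

#' Simulate reads with substitution errors and an error-free twin
#'
#' Fragments are drawn uniformly along the genome; in paired mode the two
#' reads come from the fragment ends, the mate reverse-complemented, both
#' emitted in sequencing orientation. Per-base qualities are drawn from a
#' linearly degrading profile (mean Phred 38 at the first cycle to 30 at the
#' last, sd 3) and each base is substituted with a probability proportional
#' to `10^(-Q/10)`, rescaled so the mean per-base error probability equals
#' `config$error_rate`. A substituted base becomes one of the three other
#' nucleotides uniformly.
#'
#' @param genome nucleotide string (e.g. from [simulate_genome()]).
#' @param config a [sim_config()].
#' @return list with `reads` (erroneous `read_set`), `perfect` (error-free
#'   twin, identical qualities and headers), and `errors` (data.frame with
#'   0-based `read_id`, 0-based `position` in sequencing orientation, `true`
#'   and `observed` base).
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- nchar(genome)
  L <- config$read_length
  if (L > G) stop("config error: read_length exceeds genome length")
  set.seed(config$seed + 1L)
  n_reads <- as.integer(ceiling(G * config$coverage / L))
  if (config$paired && n_reads %% 2L == 1L) n_reads <- n_reads + 1L

  if (config$paired) {
    n_frag <- n_reads %/% 2L
    flen <- pmin(G, pmax(L, round(rnorm(n_frag, config$insert_mean, config$insert_sd))))
    fstart <- vapply(G - flen + 1L, function(m) sample.int(m, 1L), integer(1L)) # 1-based
    s1 <- substring(genome, fstart, fstart + L - 1L)
    s2 <- revcomp(substring(genome, fstart + flen - L, fstart + flen - 1L))
    perfect_seq <- as.vector(rbind(s1, s2))
    header <- as.vector(rbind(paste0("sim", seq_len(n_frag) - 1L, "/1"),
                              paste0("sim", seq_len(n_frag) - 1L, "/2")))
  } else {
    start <- sample.int(G - L + 1L, n_reads, replace = TRUE)
    fwd <- runif(n_reads) < 0.5
    perfect_seq <- substring(genome, start, start + L - 1L)
    perfect_seq[!fwd] <- revcomp(perfect_seq[!fwd])
    header <- paste0("sim", seq_len(n_reads) - 1L)
  }

  # position-dependent quality profile, then error probabilities rescaled to
  # hit the configured mean error rate exactly in expectation
  mq <- seq(38, 30, length.out = L)
  Q <- matrix(pmin(41L, pmax(2L, round(rnorm(n_reads * L, mean = rep(mq, each = n_reads), sd = 3)))),
              nrow = n_reads, ncol = L)
  p <- 10^(-Q / 10)
  if (config$error_rate > 0) {
    p <- pmin(0.75, p * (config$error_rate / mean(p)))
  } else {
    p[] <- 0
  }
  flip <- matrix(runif(n_reads * L) < p, nrow = n_reads, ncol = L)

  base_mat <- matrix(unlist(strsplit(perfect_seq, ""), use.names = FALSE),
                     nrow = n_reads, ncol = L, byrow = TRUE)
  err_idx <- which(flip)
  true_base <- base_mat[err_idx]
  observed <- vapply(true_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1L))
  base_mat[err_idx] <- observed
  read_seq <- apply(base_mat, 1L, paste, collapse = "")
  qual_str <- apply(Q, 1L, function(q) intToUtf8(q + 33L))

  errors <- data.frame(read_id = (err_idx - 1L) %% n_reads,
                       position = (err_idx - 1L) %/% n_reads,
                       true = true_base, observed = observed,
                       stringsAsFactors = FALSE)
  errors <- errors[order(errors$read_id, errors$position), , drop = FALSE]
  rownames(errors) <- NULL

  list(reads = new_read_set(read_seq, qual_str, header, paired = config$paired),
       perfect = new_read_set(perfect_seq, qual_str, header, paired = config$paired),
       errors = errors)
}
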