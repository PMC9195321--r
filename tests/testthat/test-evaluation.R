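test_that("per-base truth table over all (u, e, c) combinations", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(u = bases, e = bases, c = bases, stringsAsFactors = FALSE)
  ev <- compare_three_way(paste(grid$u, collapse = ""),
                          paste(grid$e, collapse = ""),
                          paste(grid$c, collapse = ""))
  # enumerate the definitions independently
  expect_equal(ev$TP, sum(grid$u != grid$e & grid$e == grid$c))
  expect_equal(ev$FP, sum(grid$u == grid$e & grid$e != grid$c))
  expect_equal(ev$FN, sum(grid$u != grid$e & grid$c == grid$u))
  expect_equal(ev$TN, sum(grid$u == grid$e & grid$c == grid$u))
  expect_equal(ev$miscorrection,
               sum(grid$u != grid$e & grid$c != grid$u & grid$c != grid$e))
  expect_equal(ev$TP + ev$FP + ev$FN + ev$TN + ev$miscorrection, nrow(grid))

  # spot checks: (A,C,C) is TP, (A,A,G) is FP
  expect_equal(compare_three_way("A", "C", "C")$TP, 1L)
  expect_equal(compare_three_way("A", "A", "G")$FP, 1L)
  # a no-op corrector turns every simulated error into an FN
  expect_equal(compare_three_way("AACGT", "CCCGT", "AACGT")$FN, 2L)
  expect_error(compare_three_way("AC", "ACG", "AC"), "differ")
})

test_that("FP rate per million corrections", {
  expect_equal(fp_rate(list(TP = 999999L, FP = 1L)), 1)
  expect_equal(fp_rate(list(TP = 10L, FP = 0L)), 0)
  expect_equal(fp_rate(list(TP = 5L, FP = 5L)), 5e5)
  expect_warning(r <- fp_rate(list(TP = 0L, FP = 0L)), "undefined")
  expect_true(is.na(r))
})

test_that("swapping corrected and uncorrected reflects the formulas", {
  # with u and c exchanged: TP' = (c != e & e == u) = FP, and symmetrically
  # FP' = TP; FN (u != e & no change) and miscorrections are invariant
  set.seed(14)
  u <- random_seq(500); e <- random_seq(500); c_ <- random_seq(500)
  # overlay agreement so every truth-table cell is populated
  keep <- sample(500, 350)
  for (i in keep[1:150]) substr(e, i, i) <- substring(u, i, i)
  for (i in keep[151:250]) substr(c_, i, i) <- substring(u, i, i)
  for (i in keep[251:350]) substr(c_, i, i) <- substring(e, i, i)
  fwd <- compare_three_way(u, e, c_)
  rev <- compare_three_way(c_, e, u)
  expect_equal(fwd$TP, rev$FP)
  expect_equal(fwd$FP, rev$TP)
  expect_equal(fwd$FN, rev$FN)
  expect_equal(fwd$miscorrection, rev$miscorrection)
  expect_equal(fwd$total, rev$total)
  expect_gt(fwd$TP, 0L); expect_gt(fwd$FP, 0L); expect_gt(fwd$miscorrection, 0L)
})

test_that("lost true k-mers equal brute-force set arithmetic", {
  set.seed(91)
  ref <- random_seq(2000)
  starts <- sample(1:1900, 120, replace = TRUE)
  unc <- substring(ref, starts, starts + 99L)
  corr <- unc
  # a 'corrector' that rewrites the middle of five reads
  for (i in 1:5) substr(corr[i], 40, 60) <- random_seq(21)
  got <- lost_true_kmers(unc, corr, ref, k = 21L, max_bin = 10L)

  brute_canon <- function(seqs, k) {
    km <- unlist(lapply(seqs, function(s) {
      substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s)))
    }))
    rc <- vapply(km, oracle_revcomp, character(1L), USE.NAMES = FALSE)
    pmin(km, rc)
  }
  uk <- brute_canon(unc, 21L)
  ck <- unique(brute_canon(corr, 21L))
  rk <- unique(brute_canon(ref, 21L))
  tab <- table(uk)
  lost <- setdiff(intersect(names(tab), rk), ck)
  want <- vapply(1:10, function(b) sum(tab[lost] == b), numeric(1L))
  expect_equal(got$lost, as.integer(want))
  expect_equal(got$coverage, 1:10)

  # identity correction loses nothing
  expect_true(all(lost_true_kmers(unc, unc, ref, 21L)$lost == 0L))

  # single-coverage region rewritten -> losses appear in bin 1
  solo <- substring(ref, 1500, 1599)
  unc2 <- c(solo, substring(ref, 1, 100))
  corr2 <- unc2; substr(corr2[1L], 30, 50) <- random_seq(21)
  rep2 <- lost_true_kmers(unc2, corr2, ref, 21L)
  expect_gt(rep2$lost[1L], 0L)
  # k-mers absent from the reference are never counted as lost true
  junk <- random_seq(100)
  rep3 <- lost_true_kmers(junk, substring(junk, 1, 50), ref, 21L)
  expect_true(all(rep3$lost == 0L))
})

test_that("canonical k-mer counting matches a string-level oracle", {
  set.seed(3)
  s <- c(random_seq(40), "ACGTNACGTACGTACG")
  got <- canonical_kmer_counts(s, 5L)
  km <- unlist(lapply(s, function(x) {
    out <- substring(x, seq_len(nchar(x) - 4L), seq(5L, nchar(x)))
    out[!grepl("N", out)]
  }))
  canon <- pmin(km, vapply(km, oracle_revcomp, character(1L), USE.NAMES = FALSE))
  want <- sort(table(canon))
  expect_equal(got$count[order(got$kmer)],
               as.integer(table(canon)[sort(unique(canon))]))
  expect_equal(sort(got$kmer), sort(unique(canon)))
})
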