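test_that("shifted Hamming alignment: identity, offsets, substitutions", {
  r <- align_shd("AAAA", "AAAA", 0.3)
  expect_equal(r$shift, 0L); expect_equal(r$overlap, 4L)
  expect_equal(r$mismatches, 0L); expect_false(r$reverse); expect_true(r$valid)

  r <- align_shd("AAAATTTT", "TTTTGGGG", 0.3)
  expect_equal(r$shift, 4L); expect_equal(r$overlap, 4L)
  expect_equal(r$mismatches, 0L); expect_false(r$reverse)

  r <- align_shd("ACGT", "ACGA", 0.3)
  expect_equal(r$shift, 0L); expect_equal(r$overlap, 4L)
  expect_equal(r$mismatches, 1L)

  # reverse-complement candidate is found in the reverse orientation
  a <- random_seq(60)
  r <- align_shd(a, oracle_revcomp(a), 0.3)
  expect_true(r$reverse); expect_equal(r$shift, 0L); expect_equal(r$mismatches, 0L)

  # no shift reaches the overlap floor -> invalid
  r <- align_shd("AAAAAAAAAA", "GG", 0.5)
  expect_false(r$valid); expect_true(is.na(r$shift))
})

test_that("N positions are mismatch-neutral", {
  r <- align_shd("ACGTACGT", "ACGTNCGT", 0.3)
  expect_equal(r$shift, 0L)
  expect_equal(r$overlap, 7L) # the N column drops out of the overlap
  expect_equal(r$mismatches, 0L)
})

test_that("alignment matches the naive oracle on random read pairs", {
  set.seed(99)
  for (i in 1:60) {
    la <- sample(30:120, 1L); lb <- sample(30:120, 1L)
    a <- random_seq(la)
    # half the pairs share a planted overlap so non-trivial shifts win
    b <- if (i %% 2L == 0L) random_seq(lb) else {
      ov <- sample(15:min(la, lb), 1L)
      paste0(substring(a, la - ov + 1L, la), random_seq(lb - ov))
    }
    if (i %% 3L == 0L) b <- oracle_revcomp(b)
    got <- align_shd(a, b, 0.3)
    want <- oracle_align(a, b, 0.3)
    expect_equal(got$shift, want$shift, info = paste("case", i))
    expect_equal(got$overlap, want$overlap, info = paste("case", i))
    expect_equal(got$mismatches, want$mismatches, info = paste("case", i))
    expect_equal(got$reverse, want$reverse, info = paste("case", i))
  }
})

test_that("mismatch counts are symmetric under anchor/candidate exchange", {
  set.seed(5)
  count_at_shift <- function(a, b, s) {
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    lo <- max(0L, s); hi <- min(length(av), s + length(bv))
    sum(av[(lo + 1L):hi] != bv[(lo - s + 1L):(hi - s)])
  }
  for (i in 1:20) {
    a <- random_seq(80); b <- random_seq(80)
    # the literal invariant: mismatches(a, b at s) == mismatches(b, a at -s)
    for (s in c(-40L, -7L, 0L, 13L, 52L)) {
      expect_equal(count_at_shift(a, b, s), count_at_shift(b, a, -s))
    }
    # best placements mirror up to sign (ties at +/-s are both optimal)
    ra <- align_shd(a, b, 0.3); rb <- align_shd(b, a, 0.3)
    expect_equal(ra$mismatches, rb$mismatches)
    expect_equal(ra$overlap, rb$overlap)
    expect_equal(abs(ra$shift), abs(rb$shift))
  }
})

test_that("single-end filter keeps exactly the sub-threshold ratios", {
  aln <- structure(list(shift = c(0L, 0L, NA), overlap = c(50L, 50L, NA),
                        mismatches = c(2L, 4L, NA),
                        reverse = c(FALSE, FALSE, NA),
                        ratio = c(0.04, 0.08, NA),
                        valid = c(TRUE, TRUE, FALSE)),
                   class = "data.frame", row.names = 1:3)
  keep <- filter_single(aln, max_mismatch_ratio = 0.06)
  expect_equal(keep, c(TRUE, FALSE, FALSE))
  # removal only when strictly above the threshold
  aln$ratio[2L] <- 0.06
  expect_equal(filter_single(aln, 0.06), c(TRUE, TRUE, FALSE))
})

test_that("paired filter: mated candidate pairs pass unconditionally", {
  mk_aln <- function(ratios) {
    n <- length(ratios)
    structure(list(shift = rep(0L, n), overlap = rep(100L, n),
                   mismatches = as.integer(ratios * 100),
                   reverse = rep(FALSE, n), ratio = ratios,
                   valid = rep(TRUE, n)),
              class = "data.frame", row.names = seq_len(n))
  }
  # the worked pairing: C(a0) = {r0, r5, r11}, C(a1) = {r4, r8, r14};
  # r4 and r5 form a read pair, so both always pass
  ids0 <- c(0L, 5L, 11L); ids1 <- c(4L, 8L, 14L)
  aln0 <- mk_aln(c(0.10, 0.10, 0.10)); aln1 <- mk_aln(c(0.10, 0.10, 0.10))
  fp <- filter_paired(ids0, aln0, ids1, aln1, t_paired = 0.06)
  expect_equal(fp$keep0, c(FALSE, TRUE, FALSE))
  expect_equal(fp$keep1, c(TRUE, FALSE, FALSE))

  # empty partner set: non-mated candidates pass iff ratio strictly below
  # t_paired (0.06 itself fails)
  fp <- filter_paired(ids0, mk_aln(c(0.05, 0.10, 0.06)),
                      integer(0), mk_aln(numeric(0)), 0.06)
  expect_equal(fp$keep0, c(TRUE, FALSE, FALSE))
  expect_equal(fp$keep1, logical(0))
})
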