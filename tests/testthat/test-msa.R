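test_that("MSA construction: counts, weights, consensus, support", {
  # anchor alone: consensus is the anchor, support 1, coverage 1
  m <- fx_msa("ACGT")
  expect_equal(m$ncol, 4L)
  expect_equal(paste(msa_consensus(m), collapse = ""), "ACGT")
  expect_equal(m$support[anchor_columns(m)], rep(1, 4L))
  expect_equal(m$coverage[anchor_columns(m)], rep(1L, 4L))

  # identical candidate at shift 0: coverage 2, support stays 1
  m <- fx_msa("ACGT", "ACGT", 0L)
  expect_equal(m$coverage[anchor_columns(m)], rep(2L, 4L))
  expect_equal(m$support[anchor_columns(m)], rep(1, 4L))

  # per-column: sum of counts == coverage
  m <- fx_msa("ACGTACGT", c("ACGTAC", "GTACGT", "TTTT"), c(0L, 2L, -2L))
  expect_equal(colSums(m$counts), as.numeric(m$coverage))
  expect_equal(m$first, -2L)
  expect_equal(m$ncol, 10L)

  # weight formula: max(1 - 3*ratio, 0.25) * (1 - 10^(-Q/10)); support is
  # the consensus weight over the total column weight (A 4.5 vs T 0.9 gives
  # 4.5/5.4 = 0.8333...)
  ma <- corread:::cpp_msa_build("A", 20L, c("A", "T"), list(10L, 30L),
                                c(0L, 0L), c(0.5, 0.25))
  expect_equal(ma$weights[1L, 1L], (1 - 1e-2) + 0.5 * (1 - 1e-1),
               tolerance = 1e-5) # anchor + candidate
  expect_equal(ma$weights[4L, 1L], 0.25 * (1 - 1e-3), tolerance = 1e-5)
  expect_equal(ma$support[1L], ma$weights[1L, 1L] / sum(ma$weights[, 1L]))
})

test_that("N bases contribute neither count, weight nor coverage", {
  m <- fx_msa("ACGT", "ANGT", 0L)
  expect_equal(m$coverage[anchor_columns(m)], c(2L, 1L, 2L, 2L))
  expect_equal(m$counts[2L, 2L], 1L) # only the anchor's C
  expect_equal(paste(msa_consensus(m), collapse = ""), "ACGT")
})

test_that("consensus ties prefer the anchor's base", {
  # one candidate disagrees with equal weight -> anchor base wins the tie
  m <- fx_msa("A", "T", 0L)
  expect_equal(m$consensus[1L], 0L)
  expect_equal(m$support[1L], 0.5)
})

test_that("incremental removal equals a from-scratch rebuild", {
  set.seed(21)
  for (case in 1:40) {
    la <- sample(20:60, 1L)
    anchor <- random_seq(la)
    n <- sample(1:8, 1L)
    shifts <- sample(-10:10, n, replace = TRUE)
    cands <- vapply(seq_len(n), function(i) random_seq(sample(15:60, 1L)),
                    character(1L))
    m <- fx_msa(anchor, cands, shifts)
    drop <- sample(seq_len(n), sample(0:n, 1L))
    m2 <- corread:::cpp_msa_remove_rows(m, drop - 1L)
    keep <- setdiff(seq_len(n), drop)
    rebuilt <- fx_msa(anchor, cands[keep], shifts[keep])
    # surviving-member tallies agree on the common (anchor-anchored) frame
    common <- seq(max(m2$first, rebuilt$first),
                  min(m2$first + m2$ncol, rebuilt$first + rebuilt$ncol) - 1L)
    j2 <- common - m2$first + 1L; jr <- common - rebuilt$first + 1L
    expect_equal(m2$counts[, j2], rebuilt$counts[, jr])
    expect_equal(m2$weights[, j2], rebuilt$weights[, jr])
    expect_equal(m2$coverage[j2], rebuilt$coverage[jr])
    expect_equal(m2$consensus[j2], rebuilt$consensus[jr])
    # columns outside the common frame are empty after removal
    expect_true(all(m2$coverage[-j2] == 0L))
  }
})

test_that("refinement evicts a planted second haplotype and spares the anchor", {
  # anchor haplotype: 12 rows carry C at one column (incl. anchor);
  # off-haplotype: 10 rows carry T. Coverage estimate 30 -> threshold 9:
  # T (10 >= 9, != anchor base C) rows are evicted, support rises to 1.
  base <- random_seq(50)
  hapC <- base; substr(hapC, 25, 25) <- "C"
  hapT <- base; substr(hapT, 25, 25) <- "T"
  m <- fx_msa(hapC, c(rep(hapC, 11L), rep(hapT, 10L)), rep(0L, 21L))
  expect_equal(m$counts[4L, 25L], 10L)
  ref <- refine_msa(m, estimated_coverage = 30, frequency_factor = 0.3)
  expect_equal(sort(ref$removed), 11:20) # the ten T rows (0-based)
  expect_lte(ref$iterations, 5L)
  expect_equal(ref$msa$support[25L], 1)
  expect_equal(sum(ref$msa$active), 11L)
  # threshold arithmetic: 0.3 x 30 = 9, so 8 discordant rows do not trigger
  m8 <- fx_msa(hapC, c(rep(hapC, 11L), rep(hapT, 8L)), rep(0L, 19L))
  ref8 <- refine_msa(m8, 30, 0.3)
  expect_equal(ref8$removed, integer(0))
  expect_equal(ref8$iterations, 1L) # early stop at the first fixpoint
})

test_that("refinement keeps rows matching the anchor at a discordant column", {
  # consensus disagrees with the anchor but the anchor's base reaches the
  # threshold: rows NOT carrying the anchor base are evicted
  base <- random_seq(40)
  hapA <- base; substr(hapA, 20, 20) <- "A"
  hapG <- base; substr(hapG, 20, 20) <- "G"
  # anchor + 9 A-rows vs 12 G-rows: consensus G, X = A (count 10 >= 9)
  m <- fx_msa(hapA, c(rep(hapA, 9L), rep(hapG, 12L)), rep(0L, 21L))
  expect_equal(m$consensus[20L], 2L)
  ref <- refine_msa(m, 30, 0.3)
  expect_equal(sort(ref$removed), 9:20) # all G rows (0-based)
  expect_equal(ref$msa$consensus[20L], 0L)
  # anchor row survives every refinement
  expect_equal(ref$msa$active[1:9], rep(TRUE, 9L))
})

test_that("refinement stops within five iterations with disjoint evictions", {
  set.seed(77)
  base <- random_seq(60)
  cands <- character(0)
  for (col in c(10L, 20L, 30L, 40L, 50L)) {
    h <- base
    substr(h, col, col) <- setdiff(c("A", "C", "G", "T"),
                                   substring(base, col, col))[1L]
    cands <- c(cands, rep(h, 10L))
  }
  m <- fx_msa(base, cands, rep(0L, length(cands)))
  ref <- refine_msa(m, 30, 0.3)
  expect_lte(ref$iterations, 5L)
  expect_equal(anyDuplicated(ref$removed), 0L)
})

test_that("MSA quality classification aggregates anchor columns", {
  m <- fx_msa("ACGT")
  q <- classify_msa(m, min_coverage = 5L)
  expect_false(q$is_high_quality) # coverage floor
  expect_equal(q$min_support, 1); expect_equal(q$avg_support, 1)

  m2 <- fx_msa("ACGT", rep("ACGT", 29L), rep(0L, 29L))
  q2 <- classify_msa(m2)
  expect_true(q2$is_high_quality)
  expect_equal(q2$min_coverage, 30L)

  # aggregates follow their definitions
  m3 <- fx_msa("AC", c("AC", "AC", "AC", "GC"), rep(0L, 4L))
  q3 <- classify_msa(m3)
  sup <- m3$support[anchor_columns(m3)]
  expect_equal(q3$min_support, min(sup))
  expect_equal(q3$avg_support, mean(sup))
  expect_true(q3$min_support <= q3$avg_support)
})
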