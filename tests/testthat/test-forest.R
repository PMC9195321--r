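test_that("feature extraction is deterministic with documented ranges", {
  anchor <- random_seq(50)
  err <- anchor; substr(err, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                                substring(anchor, 20, 20))[1L]
  m <- fx_msa(err, rep(anchor, 9L), rep(0L, 9L))
  fv <- extract_features(m, c(0L, 19L, 49L), "anchor", estimated_coverage = 30)
  expect_equal(names(fv), feature_schema("anchor"))
  expect_equal(nrow(fv), 3L)
  expect_identical(extract_features(m, c(0L, 19L, 49L), "anchor",
                                    estimated_coverage = 30), fv)
  # column counts {consensus 9, original 1} -> fractions 0.9 / 0.1
  expect_equal(fv$cons_count_frac[2L], 0.9)
  expect_equal(fv$orig_count_frac[2L], 0.1)
  frac_cols <- c("orig_count_frac", "cons_count_frac", "orig_weight_frac",
                 "cons_weight_frac", "orig_base_quality", "cons_mean_quality",
                 "column_support", "relative_position", "relative_column",
                 "msa_min_support", "msa_avg_support")
  for (col in frac_cols) {
    expect_true(all(fv[[col]] >= 0 & fv[[col]] <= 1), info = col)
  }
  # degenerate single-row MSA: everything collapses to the anchor itself
  m1 <- fx_msa("ACGTACGTACGTACGTACGT")
  fv1 <- extract_features(m1, 0L, "anchor", estimated_coverage = 30)
  expect_equal(fv1$orig_count_frac, 1)
  expect_equal(fv1$column_support, 1)
  expect_equal(fv1$column_coverage, 1L)
  expect_error(extract_features(m1, 25L, "anchor", estimated_coverage = 30),
               "outside")

  # candidate variant carries the alignment features
  aln <- structure(list(shift = 3L, overlap = 80L, mismatches = 4L,
                        reverse = FALSE, ratio = 0.05, valid = TRUE),
                   class = "data.frame", row.names = 1L)
  m2 <- fx_msa(random_seq(100), substring(random_seq(100), 1, 90), 3L)
  fvc <- extract_features(m2, 0L, "candidate", cand_index = 0L,
                          alignment = aln, estimated_coverage = 30)
  expect_equal(names(fvc), feature_schema("candidate"))
  expect_equal(fvc$mismatch_ratio, 0.05)
  expect_equal(fvc$overlap, 80L)
  expect_equal(fvc$abs_shift, 3L)
})

test_that("prediction thresholding is strict and monotone", {
  m <- fx_models()
  fv <- head(fx_harvest()$candidate, 200L)
  p <- corread:::forest_probability(m$candidate, fv)
  expect_true(all(p >= 0 & p <= 1))
  # strict "surpasses": a threshold equal to the probability leaves the base
  i <- which.max(p)
  if (p[i] < 1) {
    expect_false(predict_correction(m$candidate, fv[i, ], threshold = p[i]))
  }
  expect_true(predict_correction(m$candidate, fv[i, ], threshold = p[i] / 2))
  # lowering the threshold never flips correct -> leave
  prev <- rep(TRUE, nrow(fv))
  for (thr in c(0.3, 0.5, 0.7, 0.9, 0.99)) {
    dec <- predict_correction(m$candidate, fv, thr)
    expect_true(all(prev | !dec)) # dec subset of prev
    prev <- dec
  }
  expect_error(predict_correction(m$candidate, fv[, 1:3], 0.5), "schema")
})

test_that("training bookkeeping honors leave-one-genome-out exclusion", {
  m <- fx_models()
  expect_equal(m$anchor$metadata$training_genomes,
               c("genomeA", "genomeB", "genomeC"))
  expect_equal(m$anchor$num_trees, 128L)
  expect_equal(m$candidate$num_trees, 128L)
  expect_identical(m$anchor$schema, feature_schema("anchor"))
  expect_identical(m$candidate$schema, feature_schema("candidate"))

  # exclusion removes the tagged genome from training
  a <- fx_dataset(101L, list(count = 4L, unit_length = 500L, divergence = 0.02))
  b <- fx_dataset(202L)
  small <- list(
    list(reads = a$reads, perfect = a$perfect, tag = "genomeA", coverage = 30),
    list(reads = b$reads, perfect = b$perfect, tag = "genomeB", coverage = 30))
  expect_error(train_forests(small, exclude_tags = c("genomeA", "genomeB")),
               "no training datasets")
})

test_that("model round-trips through its serialized container", {
  m <- fx_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_forest_model(m$candidate, path)
  re <- load_forest_model(path)
  expect_identical(re$schema, m$candidate$schema)
  fv <- head(fx_harvest()$candidate, 50L)
  expect_equal(corread:::forest_probability(re, fv),
               corread:::forest_probability(m$candidate, fv))
})

test_that("held-out discrimination: AUROC well above chance", {
  m <- fx_models()
  # evaluation genome is disjoint from all training genomes
  fv <- fx_harvest()$candidate
  expect_gt(sum(fv$label), 10L)
  expect_gt(sum(!fv$label), 10L)
  p <- corread:::forest_probability(m$candidate, fv)
  auc <- as.numeric(pROC::auc(pROC::roc(response = fv$label, predictor = p,
                                        quiet = TRUE, direction = "<")))
  expect_gt(auc, 0.8)
})

test_that("labels follow the error-free twin", {
  # candidate examples are positions where observed != consensus; positive
  # iff consensus == error-free base. At 30x on a clean genome the
  # overwhelming majority of consensus calls are right, so positives dominate
  fv <- fx_harvest()$candidate
  expect_gt(mean(fv$label), 0.5)
  # wrong proposed corrections concentrate on badly aligned candidates
  # (mated pairs pass the paired filter unconditionally, so junk alignments
  # reach the MSA and their consensus rewrites are mostly wrong)
  expect_gt(mean(fv$mismatch_ratio[!fv$label]),
            2 * mean(fv$mismatch_ratio[fv$label]))
})
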