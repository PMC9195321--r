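#' Feature schema of the per-position classifiers
#'
#' The anchor classifier sees 16 features per scored position; the candidate
#' classifier sees the same 16 plus 4 alignment features. Local features
#' describe the scored column (relative count/weight of the read's original
#' base and of the consensus, their Phred-derived qualities, support,
#' coverage); global features summarize coverage and support over the
#' anchor-covered columns of the MSA. Extraction is deterministic and
#' identical between training and inference.
#'
#' @param role `"anchor"` or `"candidate"`.
#' @return character vector of ordered feature names.
#' @export
feature_schema <- function(role = c("anchor", "candidate")) {
  role <- match.arg(role)
  base <- c("orig_count_frac", "cons_count_frac", "orig_weight_frac",
            "cons_weight_frac", "orig_base_quality", "cons_mean_quality",
            "column_support", "column_coverage", "relative_position",
            "relative_column", "msa_min_coverage", "msa_avg_coverage",
            "msa_max_coverage", "msa_min_support", "msa_avg_support",
            "coverage_ratio_to_estimate")
  if (role == "candidate") {
    base <- c(base, "overlap", "mismatches", "mismatch_ratio", "abs_shift")
  }
  base
}

#' Extract classifier features for read positions in an MSA
#'
#' @param msa a refined `corread_msa`.
#' @param positions 0-based positions within the subject read (the anchor,
#'   or the candidate in its MSA orientation). All must be covered columns.
#' @param role `"anchor"` or `"candidate"`.
#' @param cand_index 0-based candidate row (candidate role).
#' @param alignment single [align_shd()] row for the candidate (candidate
#'   role).
#' @param estimated_coverage dataset fold coverage.
#' @return data.frame with the [feature_schema()] columns, one row per
#'   position.
#' @export
extract_features <- function(msa, positions, role = c("anchor", "candidate"),
                             cand_index = NULL, alignment = NULL,
                             estimated_coverage) {
  role <- match.arg(role)
  positions <- as.integer(positions)
  if (role == "anchor") {
    shift <- 0L
    len <- msa$anchor_len
    seq_codes <- msa$anchor_code
    quals <- msa$anchor_qual
  } else {
    stopifnot(!is.null(cand_index), !is.null(alignment))
    i <- cand_index + 1L
    shift <- msa$shifts[i]
    len <- nchar(msa$cand_seqs[i])
    seq_codes <- match(strsplit(msa$cand_seqs[i], "")[[1L]], BASES) - 1L
    seq_codes[is.na(seq_codes)] <- 4L
    quals <- msa$cand_quals[[i]]
  }
  if (any(positions < 0L | positions >= len)) {
    stop("position outside the subject read")
  }
  cols <- shift + positions - msa$first + 1L
  cov <- msa$coverage[cols]
  if (any(cov == 0L)) stop("position not covered by the MSA")
  cons <- msa$consensus[cols]
  orig <- seq_codes[positions + 1L]
  wtot <- colSums(msa$weights)[cols]
  get4 <- function(m, code) { # m[code+1, col], 0 for N codes
    out <- numeric(length(cols))
    real <- code < 4L
    out[real] <- m[cbind(code[real] + 1L, cols[real])]
    out
  }
  cons_count <- get4(msa$counts, cons)
  acols <- anchor_columns(msa)
  sup_a <- msa$support[acols]; sup_a[is.na(sup_a)] <- 0
  cov_a <- msa$coverage[acols]
  fv <- fast_df(
    orig_count_frac = get4(msa$counts, orig) / cov,
    cons_count_frac = cons_count / cov,
    orig_weight_frac = ifelse(wtot > 0, get4(msa$weights, orig) / wtot, 0),
    cons_weight_frac = ifelse(wtot > 0, get4(msa$weights, cons) / wtot, 0),
    orig_base_quality = quals[positions + 1L] / 93,
    cons_mean_quality = ifelse(cons_count > 0,
                               get4(msa$qualsum, cons) / pmax(cons_count, 1L) / 93, 0),
    column_support = ifelse(is.na(msa$support[cols]), 0, msa$support[cols]),
    column_coverage = cov,
    relative_position = positions / len,
    relative_column = (cols - 1L) / msa$ncol,
    msa_min_coverage = min(cov_a),
    msa_avg_coverage = mean(cov_a),
    msa_max_coverage = max(cov_a),
    msa_min_support = min(sup_a),
    msa_avg_support = mean(sup_a),
    coverage_ratio_to_estimate = cov / estimated_coverage)
  if (role == "candidate") {
    fv$overlap <- rep(alignment$overlap, length(cols))
    fv$mismatches <- rep(alignment$mismatches, length(cols))
    fv$mismatch_ratio <- rep(alignment$ratio, length(cols))
    fv$abs_shift <- rep(abs(alignment$shift), length(cols))
  }
  fv
}

# data.frame constructor without the data.frame() validation overhead;
# every column is recycled to full length by the caller
fast_df <- function(...) {
  cols <- list(...)
  n <- max(lengths(cols))
  cols <- lapply(cols, function(x) if (length(x) == n) x else rep(x, length.out = n))
  structure(cols, class = "data.frame",
            row.names = if (n) seq_len(n) else integer(0))
}

#' Decide corrections from classifier confidences
#'
#' A position is corrected iff the forest's mean positive-class probability
#' strictly surpasses the threshold.
#'
#' @param model a `forest_model`.
#' @param fv feature data.frame matching the model's schema.
#' @param threshold probability cutoff in (0, 1).
#' @return logical vector: correct (TRUE) or leave (FALSE) per row.
#' @export
predict_correction <- function(model, fv, threshold) {
  stopifnot(inherits(model, "forest_model"), threshold > 0, threshold < 1)
  forest_probability(model, fv) > threshold
}

forest_probability <- function(model, fv) {
  if (!all(model$schema %in% names(fv))) {
    stop("feature vector does not match the model's schema")
  }
  if (nrow(fv) == 0L) return(numeric(0))
  pred <- predict(model$forest, data = fv[, model$schema, drop = FALSE],
                  num.threads = 1L, verbose = FALSE)
  pred$predictions[, "yes"]
}

#' Anchor correction with the random-forest classifier
#'
#' High-quality MSAs are handled exactly like the rule-based path
#' (unconditional consensus replacement). For low-quality MSAs, every anchor
#' position whose observed base differs from the consensus is scored and
#' changed to the consensus iff the classifier confidence surpasses the
#' threshold; positions already matching the consensus are never scored.
#'
#' @inheritParams correct_anchor_classic
#' @param model anchor `forest_model`.
#' @param threshold correction threshold (default 0.9).
#' @param estimated_coverage dataset fold coverage (feature input).
#' @return a correction record (see [correct_anchor_classic()]).
#' @export
correct_anchor_forest <- function(msa, quality, model, threshold = 0.9,
                                  estimated_coverage) {
  if (quality$is_high_quality) {
    return(correct_anchor_classic(msa, quality))
  }
  acols <- anchor_columns(msa)
  orig <- strsplit(msa$anchor_seq, "")[[1L]]
  cons <- msa_consensus(msa, acols, fallback = orig)
  score_pos <- which(cons != orig & msa$consensus[acols] >= 0L) # 1-based
  corrected <- orig
  if (length(score_pos)) {
    fv <- extract_features(msa, score_pos - 1L, "anchor",
                           estimated_coverage = estimated_coverage)
    change <- predict_correction(model, fv, threshold)
    corrected[score_pos[change]] <- cons[score_pos[change]]
  }
  correction_record(orig, corrected, "anchor")
}

#' Candidate corrections vetted by the candidate classifier
#'
#' As [correct_candidates()] (high-quality MSAs, `[b - x, e + x)` range
#' rule), but every position where the candidate differs from the consensus
#' is additionally scored by the candidate forest; only changes whose
#' confidence surpasses the threshold are applied.
#'
#' @inheritParams correct_candidates
#' @param alignments [align_shd()] rows for the MSA's candidates.
#' @param model candidate `forest_model`.
#' @param threshold correction threshold (default 0.9).
#' @param estimated_coverage dataset fold coverage.
#' @return list of correction records, as [correct_candidates()].
#' @export
correct_candidates_forest <- function(msa, quality, reverse, alignments,
                                      model, threshold = 0.9, x = 15L,
                                      estimated_coverage) {
  if (!quality$is_high_quality) {
    stop("candidate corrections are only produced from high-quality MSAs")
  }
  idx <- eligible_candidates(msa, x)
  # gather the differing positions of every eligible candidate and score
  # them in a single forest call
  diffs <- lapply(idx, function(i) {
    len <- nchar(msa$cand_seqs[i])
    cols <- seq(msa$shifts[i] - msa$first + 1L, length.out = len)
    codes <- match(strsplit(msa$cand_seqs[i], "")[[1L]], BASES) - 1L
    codes[is.na(codes)] <- 4L
    which(msa$consensus[cols] >= 0L & codes != msa$consensus[cols])
  })
  fvs <- lapply(seq_along(idx), function(ii) {
    if (!length(diffs[[ii]])) return(NULL)
    extract_features(msa, diffs[[ii]] - 1L, "candidate",
                     cand_index = idx[ii] - 1L,
                     alignment = alignments[idx[ii], , drop = FALSE],
                     estimated_coverage = estimated_coverage)
  })
  nonempty <- which(lengths(diffs) > 0L)
  change_all <- logical(0)
  if (length(nonempty)) {
    change_all <- predict_correction(model, do.call(rbind, fvs[nonempty]),
                                     threshold)
  }
  offset <- 0L
  lapply(seq_along(idx), function(ii) {
    i <- idx[ii]
    keep <- integer(0)
    nd <- length(diffs[[ii]])
    if (nd) {
      change <- change_all[offset + seq_len(nd)]
      offset <<- offset + nd
      keep <- diffs[[ii]][!change]
    }
    rec <- candidate_consensus_record(msa, i, reverse[i], keep = keep)
    rec$cand_index <- i - 1L
    rec
  })
}

#' Train the anchor and candidate correction forests
#'
#' Runs the full correction pipeline in feature-harvest mode on each
#' training dataset (so training sees exactly the MSAs inference sees),
#' collects per-position examples — anchor examples from low-quality MSAs,
#' candidate examples from high-quality ones, in both cases at positions
#' where the observed base differs from the consensus — and fits one
#' probability forest of `num_trees` trees per role. An example is positive
#' iff the column consensus equals the error-free base (i.e. applying the
#' correction would be right), which requires each dataset's error-free
#' twin. Datasets whose `tag` is in `exclude_tags` are left out
#' (leave-one-genome-out protocol).
#'
#' @param datasets list of `list(reads=, perfect=, tag=, coverage=)` built
#'   e.g. from [simulate_reads()] output.
#' @param exclude_tags genome tags to exclude from training.
#' @param num_trees trees per forest (default 128).
#' @param seed RNG seed for the forest fit and the harvest pipelines.
#' @param ... further arguments passed to [correct_read_set()] (thresholds,
#'   `k`, `num_tables`, ...).
#' @return list with `anchor` and `candidate` `forest_model` objects.
#' @export
train_forests <- function(datasets, exclude_tags = character(0),
                          num_trees = 128L, seed = 1L, ...) {
  used <- Filter(function(d) !(d$tag %in% exclude_tags), datasets)
  if (!length(used)) stop("no training datasets left after exclusion")
  harvests <- lapply(used, function(d) {
    correct_read_set(d$reads, coverage = d$coverage, mode = "classic",
                     harvest = TRUE, truth = d$perfect, seed = seed,
                     ...)$harvest
  })
  anchor_df <- do.call(rbind, lapply(harvests, `[[`, "anchor"))
  cand_df <- do.call(rbind, lapply(harvests, `[[`, "candidate"))
  if (is.null(anchor_df) || nrow(anchor_df) == 0L) {
    stop("training-data error: no low-quality MSA positions harvested")
  }
  if (is.null(cand_df) || nrow(cand_df) == 0L) {
    stop("training-data error: no candidate positions harvested")
  }
  tags <- vapply(used, `[[`, character(1L), "tag")
  list(anchor = fit_forest(anchor_df, "anchor", num_trees, seed, tags),
       candidate = fit_forest(cand_df, "candidate", num_trees, seed, tags))
}

fit_forest <- function(df, role, num_trees, seed, tags) {
  schema <- feature_schema(role)
  df$label <- factor(ifelse(df$label, "yes", "no"), levels = c("no", "yes"))
  if (nlevels(droplevels(df$label)) < 2L) {
    # degenerate but legal training set: duplicate one flipped row so the
    # probability machinery stays two-class; the forest then predicts the
    # majority class with near-certainty
    flip <- df[1L, , drop = FALSE]
    flip$label <- factor(setdiff(c("no", "yes"), as.character(df$label[1L])),
                         levels = c("no", "yes"))
    df <- rbind(df, flip)
  }
  forest <- ranger::ranger(
    dependent.variable.name = "label",
    data = df[, c(schema, "label")],
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1L, verbose = FALSE)
  structure(list(forest = forest, schema = schema, role = role,
                 num_trees = num_trees,
                 metadata = list(training_genomes = tags, seed = seed,
                                 n_examples = nrow(df))),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model (%s): %d trees, %d features, trained on %s (%d examples)\n",
              x$role, x$num_trees, length(x$schema),
              paste(x$metadata$training_genomes, collapse = ", "),
              x$metadata$n_examples))
  invisible(x)
}

#' Save / load a trained forest model
#'
#' Models are stored as RDS containers holding the fitted trees, the ordered
#' feature schema and training metadata (genome tags, seed), so schema drift
#' is detectable at load time.
#'
#' @param model a `forest_model`.
#' @param path file path.
#' @export
save_forest_model <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_forest_model
#' @export
load_forest_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "forest_model") ||
      !identical(model$schema, feature_schema(model$role))) {
    stop(sprintf("'%s' is not a compatible forest model", path))
  }
  model
}
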