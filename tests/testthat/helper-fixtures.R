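# Shared simulation fixtures and trained models, built once per session.
# Study conditions: 10 kb genomes, 30x coverage, 100 bp paired reads, 1%
# substitution errors; classifiers are trained on three genomes disjoint
# from the evaluation genome (one repeat-rich, one clean, one mildly
# repetitive) following the leave-one-genome-out protocol.

.fx <- new.env(parent = emptyenv())

fx_dataset <- function(seed, repeat_spec = NULL, genome_length = 10000L,
                       coverage = 30) {
  key <- paste0("ds_", seed, "_", genome_length, "_",
                if (is.null(repeat_spec)) "plain" else "rep")
  if (is.null(.fx[[key]])) {
    cfg <- sim_config(genome_length = genome_length, coverage = coverage,
                      read_length = 100L, error_rate = 0.01, paired = TRUE,
                      seed = seed, repeat_spec = repeat_spec)
    g <- simulate_genome(cfg)
    .fx[[key]] <- c(simulate_reads(g, cfg), list(genome = g, config = cfg))
  }
  .fx[[key]]
}

fx_test_sim <- function() fx_dataset(7L)

fx_models <- function() {
  if (is.null(.fx$models)) {
    a <- fx_dataset(101L, list(count = 4L, unit_length = 500L, divergence = 0.02))
    b <- fx_dataset(202L)
    c_ <- fx_dataset(303L, list(count = 2L, unit_length = 400L, divergence = 0.02))
    datasets <- list(
      list(reads = a$reads, perfect = a$perfect, tag = "genomeA", coverage = 30),
      list(reads = b$reads, perfect = b$perfect, tag = "genomeB", coverage = 30),
      list(reads = c_$reads, perfect = c_$perfect, tag = "genomeC", coverage = 30))
    .fx$models <- train_forests(datasets, num_trees = 128L, seed = 5L)
  }
  .fx$models
}

fx_classic_run <- function() {
  if (is.null(.fx$classic_run)) {
    sim <- fx_test_sim()
    .fx$classic_run <- correct_read_set(sim$reads, coverage = 30,
                                        mode = "classic", seed = 1L)
  }
  .fx$classic_run
}

fx_forest_run <- function(threshold = 0.9) {
  key <- paste0("forest_run_", threshold)
  if (is.null(.fx[[key]])) {
    sim <- fx_test_sim()
    m <- fx_models()
    .fx[[key]] <- correct_read_set(sim$reads, coverage = 30, mode = "forest",
                                   anchor_model = m$anchor,
                                   candidate_model = m$candidate,
                                   threshold = threshold, seed = 1L)
  }
  .fx[[key]]
}

fx_harvest <- function() {
  if (is.null(.fx$harvest)) {
    sim <- fx_test_sim()
    .fx$harvest <- correct_read_set(sim$reads, coverage = 30, mode = "classic",
                                    seed = 1L, harvest = TRUE,
                                    truth = sim$perfect)$harvest
  }
  .fx$harvest
}

# small MSA construction helper for unit tests: perfect-quality reads with
# given shifts, forward orientation
fx_msa <- function(anchor, cands = character(0), shifts = integer(0),
                   quals = NULL, anchor_qual = NULL) {
  if (is.null(anchor_qual)) anchor_qual <- rep(40L, nchar(anchor))
  if (is.null(quals)) quals <- lapply(nchar(cands), function(l) rep(40L, l))
  aln <- structure(list(shift = as.integer(shifts),
                        overlap = pmin(nchar(cands), nchar(anchor)),
                        mismatches = rep(0L, length(cands)),
                        reverse = rep(FALSE, length(cands)),
                        ratio = rep(0, length(cands)),
                        valid = rep(TRUE, length(cands))),
                   class = "data.frame",
                   row.names = seq_along(cands))
  build_msa(anchor, anchor_qual, cands, quals, aln)
}
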