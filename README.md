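# corread

Context-aware correction of substitution errors in Illumina short reads,
built for pipelines where *false-positive* corrections — bases that were
right until the corrector touched them — matter as much as the errors
removed. Downstream k-mer spectra, assemblies and variant calls all suffer
from injected errors, so `corread` is tuned throughout for precision.

## Method in brief

Each read takes a turn as the **anchor** $r_i$ of its own correction
problem:

1. **Retrieval.** A minhash signature — for each of $h = 48$ hash
   functions, the minimum over all canonical 20-mers of the read — indexes
   every read into $h$ hash tables. Querying the anchor's signature returns
   the candidate set $C(r_i)$ of likely locus-mates, independent of strand.
2. **Alignment + filter.** Every candidate is aligned to the anchor by
   gapless shifted Hamming distance (all shifts, both orientations, best
   mismatches/overlap ratio). Poorly matching or barely overlapping
   candidates are dropped; in paired-end mode, a candidate whose mate is a
   candidate of the anchor's mate passes unconditionally, all others need
   ratio $< t_{paired} = 0.06$.
3. **Weighted MSA + refinement.** Survivors are stacked around the anchor;
   per column, each base contributes a weight
   $\max(1-3r, 0.25)(1-10^{-Q/10})$ (alignment ratio $r$, Phred $Q$).
   Columns where a non-consensus base reaches $0.3 \times$ the dataset
   coverage reveal repeat/haplotype mixtures; the off-anchor rows are
   evicted (at most 5 iterations).
4. **Correction + merge.** High-quality MSAs (min/avg support, min
   coverage thresholds) rewrite the anchor to the consensus and also
   correct fully-embedded candidates; low-quality MSAs correct only
   high-confidence positions — by a conservative support/count rule
   (classic mode) or by 128-tree random-forest classifiers over 16–20
   per-position MSA features (forest mode, threshold 0.9). Per read, the
   anchor correction must agree with ≥ 3 candidate corrections, when that
   many exist, or the read is left untouched.

A paired-end read simulator (error-free twin + exact error log), the
TP/FP evaluation machinery and a lost-true-k-mer spectrum report are
included; classifier training follows a genome-wise leave-one-out protocol.

## Worked example

```r
library(corread)

cfg <- sim_config(genome_length = 10000, coverage = 30, read_length = 100,
                  error_rate = 0.01, paired = TRUE, seed = 7)
genome <- simulate_genome(cfg)
sim <- simulate_reads(genome, cfg)
sim$reads
#> read_set: 3000 reads (paired), lengths 100..100

res <- correct_read_set(sim$reads, coverage = 30, mode = "classic", seed = 1)
compare_three_way(sim$reads, sim$perfect, res$reads)
#> TP 2949  FP 0  FN 70  TN 296981  miscorrections 0  (FP rate/M: 0)
```

Reading: the simulator planted 3 019 substitution errors in 300 000 bases;
classic-mode correction removed 2 949 of them (97.7% sensitivity), left 70
in place, and changed **no** correct base (0 false positives, so 0
false-positive corrections per million corrections). `res$report` holds the
per-phase counts (candidates retrieved/kept, rows evicted by refinement,
high-quality MSAs, merge decisions).

Forest mode needs two trained classifiers:

```r
models <- train_forests(list(
  list(reads = trainA$reads, perfect = trainA$perfect, tag = "gA", coverage = 30),
  list(reads = trainB$reads, perfect = trainB$perfect, tag = "gB", coverage = 30)),
  exclude_tags = "held_out_genome", num_trees = 128, seed = 5)
resf <- correct_read_set(sim$reads, coverage = 30, mode = "forest",
                         anchor_model = models$anchor,
                         candidate_model = models$candidate, threshold = 0.9)
```

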