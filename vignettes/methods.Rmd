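---
title: "MSA-based short-read error correction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSA-based short-read error correction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corread)
```

## The problem

Illumina sequencers deliver short reads (about 100 bp here) whose dominant
error mode is the base substitution, at roughly one error per hundred bases.
Error correctors remove most of these errors, but every *false-positive*
correction — changing a base that was right — injects a new error into the
dataset, and those propagate into k-mer spectra, assemblies and variant
calls. `corread` implements a context-aware, MSA-based corrector whose
design goal is a very low false-positive rate at a competitive
true-positive rate.

## The correction model

Every read takes a turn as the **anchor**. Correction of one anchor runs
through four stages:

1. **Candidate retrieval (minhash).** During construction, each read's
   *signature* is computed: for each of $h$ hash functions (default
   $h = 48$), the minimum hash value over all canonical $k$-mers of the
   read (default $k = 20$; a $k$-mer and its reverse complement hash
   identically, so retrieval is strand-blind). Read $i$ is inserted into
   hash table $l$ under key $S_i[l]$. Querying the anchor's signature and
   taking the union over tables yields reads that very likely overlap the
   anchor's genomic locus. Two reads sharing an overlap of $m$ shared
   $k$-mers out of a union of $u$ collide in one table with probability
   about $m/u$, hence in at least one of 48 tables with probability
   $1-(1-m/u)^{48}$ — close to 1 for any overlap of a few dozen bases.

2. **Alignment and filtering.** Each candidate is aligned to the anchor by
   *shifted Hamming distance*: a gapless semi-global alignment that tries
   every shift and both orientations and keeps the placement with the
   smallest mismatches/overlap ratio (ties prefer the smaller $|$shift$|$,
   then the forward orientation). Gaps are not modeled — substitutions
   dominate Illumina data. Candidates whose best ratio is too high, or
   whose overlap is too small, are dropped. In **paired-end mode** a
   candidate whose mate is simultaneously a candidate of the anchor's mate
   passes unconditionally — both fragments almost surely come from the same
   locus — while all other candidates must pass a stricter ratio bound
   $t_{paired}$ (default 0.06, strict `<`).

3. **Weighted MSA and refinement.** Surviving candidates are stacked at
   their alignment shifts around the anchor. Per column and nucleotide the
   MSA keeps a count and a weight sum, with the weight of one base
   $\max(1 - 3r,\ 0.25)\,(1 - 10^{-Q/10})$, where $r$ is the row's mismatch
   ratio and $Q$ the base's (possibly binned) Phred score. The column
   **consensus** is the nucleotide with the greatest weight; its
   **support** is that weight over the column total. Because minhash also
   retrieves reads from inexact repeats and second haplotypes, the MSA is
   *refined*: any anchor column where a non-consensus nucleotide $X$
   reaches a count of $0.3\times$ the (user-supplied) dataset coverage
   betrays a mixed pile, and the rows on the wrong side of the anchor are
   evicted — rows *not* carrying $X$ if the anchor itself carries $X$,
   otherwise the rows carrying $X$. One column (the highest discordant
   count) is processed per iteration, the consensus is recomputed, and the
   loop stops after at most five iterations or at the first fixpoint.

4. **Correction.** MSAs are split into high and low quality by aggregating
   anchor columns: minimum support, average support, minimum coverage
   (defaults 0.75 / 0.90 / 5). *High-quality* MSAs rewrite the anchor to
   the consensus unconditionally, and also emit corrections for candidates
   lying fully inside the column window $[b-x, e+x)$ around the anchor
   region (default $x = 15$). *Low-quality* MSAs are corrected
   conservatively: classic mode changes a position only when support
   exceeds 0.90 and the anchor's own base occurs at most twice in the
   column; forest mode instead scores every position where the anchor
   disagrees with the consensus with a random-forest classifier and
   corrects when the confidence surpasses the threshold (default 0.9).

Finally the **merge phase** reconciles, per read, its single anchor
correction with all corrections it received as a candidate in other
anchors' MSAs: with fewer than three candidate corrections the anchor
correction wins; with three or more, the anchor correction is used only if
it equals every candidate correction, otherwise the read is left untouched.
This all-must-agree rule is the last line of defense against
false positives. A read with no anchor correction of its own adopts three
or more unanimous candidate corrections (our extension of the same
principle; such reads are flagged in the audit log).

## The classifiers

Two probability forests (128 trees each, fit with `ranger` at library
default hyperparameters, fixed seed) score anchor and candidate positions.
Each scored position yields 16 features (20 for candidates): local column
statistics (relative count and weight of the original and consensus base,
their Phred-derived qualities, support, coverage), the position inside the
read and inside the MSA, global aggregates over the anchor columns
(min/avg/max coverage, min/avg support), the column coverage relative to
the dataset estimate, and for candidates the alignment's overlap, mismatch
count, mismatch ratio and $|$shift$|$. The schema is versioned inside the
serialized model so drift is detected at load time.

Training runs the identical pipeline in harvest mode on simulated datasets
with error-free twins: anchor examples come from low-quality MSAs,
candidate examples from high-quality ones, at positions where the observed
base differs from the consensus; an example is *positive* iff the consensus
equals the error-free base, i.e. applying the correction would be right.
Training follows a genome-wise leave-one-out protocol: the forest used to
correct a dataset is never trained on that dataset's genome (the
`exclude_tags` argument of `train_forests()`).

The correction threshold trades sensitivity for precision: raising it can
only shrink the set of corrected positions (decisions are monotone in the
threshold), lowering it corrects more errors at the cost of more false
positives.

## The read simulator

`simulate_reads()` emulates the statistical structure the corrector
exploits, not a particular instrument: uniform fragment starts, normal
fragment lengths (300 ± 30 bp), mates reverse-complemented from fragment
ends, and per-base qualities drawn from a linearly degrading profile (mean
Phred 38 at the first cycle to 30 at the last, sd 3). Per-base substitution
probabilities are proportional to $10^{-Q/10}$ and rescaled so their mean
equals the configured error rate (default 1%); the raw profile alone would
imply a far lower rate, and the rescaling preserves both the
quality–error-rate correlation and the intended error budget. An error-free
twin and an exact error log are emitted alongside. Planted inexact repeats
(an exact number of substitutions per copy, disjoint across copies, so
pairwise copy divergence is deterministic) exercise MSA refinement.

What the simulator does *not* model — indels, PCR duplicates, adapter
read-through, position-correlated error bursts, coverage biases — bounds
what passing tests show: they validate the algorithm under its own stated
assumptions (substitution-only noise, roughly uniform coverage), not
instrument realism.

## Numerical and design choices

* **Quality binning.** The paper-level idea of 1-/2-bit lossy quality
  storage needs concrete bins: `bins2` uses boundaries 10/20/30 with
  representatives 5/15/25/37, `bins1` a single boundary at 20 with
  representatives 6/37 — conventional Illumina strata. Binning is monotone
  and idempotent. Binned values feed only the MSA weights; output files
  always carry the original qualities.
* **Hashing.** Canonical $k$-mers are 2-bit encoded; the hash is a
  splitmix64 finalizer of the code XOR a per-table seed, masked to 48 bits
  so keys are exact doubles in R. $k$-mer windows containing `N` are
  skipped; a read with no valid window is passed through uncorrected.
* **N handling.** `N` is stored as `A` in the 2-bit encoding with a
  separate mask. In alignment, positions where either base is `N` count
  toward neither mismatches nor overlap; in the MSA an `N` contributes no
  count, weight or coverage — unknown bases never fabricate evidence.
* **Exact weight arithmetic.** Per-base weights are quantized to multiples
  of $2^{-20}$ before accumulation, so column weight sums — and their
  updates when refinement subtracts evicted rows — are exact in double
  precision. Consensus tie decisions therefore cannot drift between
  incremental updates and a from-scratch rebuild; the quantization error
  (under $10^{-6}$ per base) is far below anything the consensus rule can
  resolve.
* **Ties.** Alignment ties prefer smaller $|$shift$|$, then forward
  orientation (exact rational comparison, no float equality). Consensus
  ties prefer the anchor's base (conservative toward no-op), then the
  alphabetically smaller base.
* **Refinement bookkeeping.** Eviction is implemented incrementally
  (subtracting the removed rows' contributions); tests assert equality with
  a from-scratch rebuild on the surviving member set. Only rows covering
  the triggering column are eligible; an `N` at that column "does not
  carry X". The threshold compares *counts* (the natural reading of
  frequency), not weight sums. The anchor row is never evicted.
* **Candidate cap.** A minhash query returning more than `max_candidates`
  ids (default 1000, repeat-bucket protection) admits buckets smallest
  first and drops the most populous ones.
* **Merge equality** compares full corrected sequences, not edit lists.
* **Degenerate inputs.** An anchor with no surviving candidates forms a
  single-row MSA: low quality by the coverage floor, and its conservative
  rule is a no-op, so the read passes through. A column whose total weight
  is zero (all Phred 0) falls back to count-based consensus.

## Problem sizes and defaults

The bundled tests and the acceptance script run the full method on
simulated 10 kb genomes at 30x coverage with 100 bp paired reads and 1%
errors (3 000 reads per dataset), with classifiers trained on three
disjoint genomes — one repeat-rich, one clean, one mildly repetitive — so
that both label classes are represented in training. These sizes keep every
stage (indexing, alignment, refinement, training, correction, evaluation)
exercised end to end at desk scale; the algorithm itself is
size-independent, and `coverage` is the only dataset-level parameter the
user must supply.

Under these conditions classic mode typically corrects 97–98% of the
simulated errors with zero or near-zero false positives, and forest mode
trades a few true positives for a false-positive count at or below the
classic mode's — the direction, not the magnitude, of the original tool's
reported behavior; magnitudes at genome scale are outside desk-scale reach.

## Known limitations

* Substitution-only: indels are neither simulated nor correctable
  (a gapless alignment cannot express them).
* No attempt at memory-bounded or out-of-core operation; the read set,
  index and MSAs live in RAM.
* `estimated_coverage` is taken on trust from the user; a wrong estimate
  shifts the refinement threshold proportionally.
* The candidate cap's bucket-dropping order is a heuristic; extremely
  repetitive loci may lose informative candidates along with the junk.
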