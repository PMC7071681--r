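---
title: "Barcode-free demultiplexing of pooled long reads with sample k-mer indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-free demultiplexing of pooled long reads with sample k-mer indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerplex)
```

## The problem

Long-read sequencing of many bacterial isolates on one flow cell normally
requires molecular barcoding: each sample is tagged before pooling so that
reads can be assigned back to their isolate. When accurate short-read data
already exist for every isolate — the usual situation in hybrid-assembly
projects — the barcodes are redundant: each isolate's genome content is
itself a signature. kmerplex implements this barcode-free alternative
(known as Ultraplexing in the literature): DNA from all isolates is pooled
without tags, and each long read is assigned to the sample whose
short-read-derived k-mer index explains it best.

## The assignment model

For each of the $n$ samples, a de Bruijn graph with $k = 19$ is built from
that sample's Illumina reads and cleaned by removing low-coverage
supernodes. The package realizes the cleaned graph as its node set: a
table of canonical k-mers (each k-mer stored as the lexicographic minimum
of itself and its reverse complement) with occurrence counts. Each long
read $r$ from the pool is then scored against every sample $s$ by

$$ h_s(r) \;=\; \#\{\text{k-mer windows of } r \text{ present in the
cleaned index of } s\}, $$

and assigned to $\arg\max_s h_s(r)$, with draws broken uniformly at
random. This is a deliberately simple statistic — a heuristic stand-in
for read-to-graph alignment — and it is what makes the method fast enough
to route an entire flow cell in one pass while holding all $n$ indexes in
memory.

The choice of $k$ trades specificity against error tolerance. A k-mer of
an error-prone read survives (is itself error-free) with probability

$$ (1-e)^k, $$

where $e$ is the per-base long-read error rate; `kmer_survival(0.12, 19)`
is about 0.088, so roughly one window in eleven of a 12%-error read still
matches its source genome exactly. Larger $k$ buys more sample-specific
k-mers but loses survival exponentially; $k = 19$ (odd, so that no k-mer
is its own reverse complement) is the package default.

## Index cleaning

Sequencing errors in the short reads generate spurious k-mers, almost all
of them on low-coverage paths of the graph. Cleaning operates at the
supernode (unitig) level: the k-mer set is partitioned into maximal
non-branching paths of the bidirected de Bruijn graph, and every k-mer on
a unitig whose *mean* member count falls below `min_unitig_coverage` is
removed. Two nodes chain into one unitig only when each is the unique
neighbor on the side facing the other, so the partition is independent of
table order; branch nodes become singleton or short unitigs of their own.

The threshold default is 5. At the 40–100x short-read coverage this
workflow assumes, genuine genomic unitigs have mean counts near the
coverage while error unitigs sit at 1–2, so any threshold in between
separates them; 5 leaves headroom for uneven coverage. An `"auto"` mode
instead takes the first local minimum of the k-mer multiplicity histogram
in [2, 20] — the valley between the error and the coverage peak — and
falls back to 5 when the histogram has no interior minimum there. Mean
(rather than minimum) member count is used so that a single
high-multiplicity k-mer shared with a repeat cannot rescue an error path.

Whether the original implementation cleaned on mean or minimum supernode
coverage, and at which threshold, is not documented; the rule above is
this package's own, explicit choice.

## Scoring and tie-breaking choices

* **Window vs distinct counting.** "Number of read k-mers present" can
  count every window or every distinct k-mer. The default `per_window`
  mode is the more literal reading and weights repeated k-mers by their
  multiplicity in the read; `distinct` mode is available as an option.
  Index counts are *not* used in scoring — membership only; counts are
  retained for cleaning and diagnostics.
* **Ties.** Draws (including the degenerate all-zero case of a read
  shorter than k, or a read none of whose k-mers survived) are resolved
  uniformly at random from one seeded generator consumed in read order,
  so a rerun with the same inputs and seed is byte-identical. The seed is
  a logged parameter, default 42.
* **Unassigned bin.** The reference behavior always assigns (randomly on
  a draw). That remains the default (`min_hits = 0`); `min_hits > 0`
  optionally routes hopeless reads to an `unassigned` bin and is marked
  as an extension.

## Evaluation statistics

Against a truth table, `classification_accuracy()` counts a read as
correct iff it was assigned to the sample it was simulated from. For
mis-assigned reads, `delta_edit_distance()` computes

$$ \Delta = (d_1 - d_2) / \ell, $$

where $d_1$ and $d_2$ are the ends-free edit distances of the read
(length $\ell$) to its source and to its assigned genome. Ends-free is
interpreted as infix alignment: the read aligns globally, gaps flanking
the genome are free. Both genome strands are searched and multi-contig
genomes (chromosome plus plasmids) are searched per contig, taking the
minimum — the strand and contig handling is an assumption the original
description leaves open. $\Delta = 0$ means the two genomes are locally
indistinguishable where the read maps; mis-assignments dominated by such
reads are homology-driven and harmless for downstream assembly.

The distance itself is exact, not heuristic: a bit-parallel Myers block
dynamic program (the same family of algorithm used by edlib), validated
in the test suite against a naive quadratic DP and against
`Biostrings::pairwiseAlignment(type = "global-local")` with unit costs.

`qv_score()` converts an average SNP count per genome into a Phred-scaled
consensus quality, $\mathrm{round}(-10\log_{10}(\text{SNPs}/\text{genome
size}))$, rounding half away from zero; 0 SNPs yields `Inf` rather than
an error, since perfect consensus does occur in practice.

## The synthetic-data generator

The simulator reproduces the statistical shape of the wgsim/pbsim
configurations used in the original experiments rather than wrapping
those binaries, which keeps the error process fully known for
truth-based testing:

* **Communities.** All isolates derive from one random ancestor
  chromosome by i.i.d. substitutions at the per-isolate rate
  `pairwise_divergence` (realized pairwise divergence is then about
  $2p(1-p)$), outside an optional contiguous shared segment that stays
  byte-identical across isolates. Plasmids are byte-identical across
  their carriers, and an optional repeat is inserted verbatim into both
  the chromosome and the first plasmid, emulating chromosome–plasmid
  repeat structure.
* **Short reads.** 2 x 150 bp pairs, outer distance Normal(278, 128),
  substitution errors only, at 0.005 per base, 300 Mb per isolate by
  default.
* **Long reads.** Lengths from Normal(8370, 6389) truncated to
  [230, 61011] (sampled by rejection; the upper bound is additionally
  capped at the contig length), uniform start and strand, i.i.d. errors
  at $1 - 0.88$ per base split 1:1:1 between substitutions, insertions
  and deletions, and a flow-cell yield of 5 Gb divided evenly across the
  pooled isolates.

Replicons are sampled as **circular** by default, for both short and long
reads. This is not cosmetic: with linear sampling, coverage tapers over
the last fragment-length of each artificial contig end, the end unitigs
fall below the cleaning threshold, and contiguous runs of genuine
genomic k-mers get deleted from the index — an artifact real circular
bacterial replicons do not have, which then shows up as lost hits for
long reads mapping near the origin. (We first simulated linearly on the
grounds that classification is origin-agnostic; diagnosing exactly such
missing end-of-contig k-mer runs showed that rationale to be wrong — the
linearization biases the *index*, not merely coordinates.) A
`circular = FALSE` switch restores linear sampling for genuinely linear
contigs.

What the simulator does **not** model: real Nanopore error structure
(homopolymer bias, quality-dependent and clustered errors), pbsim's
empirical quality profiles, coverage biases, chimeras, or barcode
sequences. FASTQ qualities of simulated reads are constant, derived from
the error rate, since the classifier ignores them. Passing tests on
these simulations therefore demonstrates the algorithm's behavior under
its stated error model, not performance on any particular real flow
cell.

## Problem sizes used by the test suite

The full-size experiments (multi-megabase genomes, 300 Mb of short reads
per isolate, 5 Gb pools) are not desk-scale, so the suite runs scaled
analogues chosen to keep every per-read quantity — coverage ratios, error
rates, read-length distribution — at the original operating point while
shrinking genome size and yield:

* high-divergence recovery: 10 isolates, 200 kb chromosomes, per-isolate
  divergence 0.02, 60x short-read and 30x long-read coverage
  (about 6,000 pooled reads);
* homology-driven mis-assignment: 2 isolates, 200 kb, a byte-identical
  30% segment, 0.2% divergence elsewhere, same coverages, 100 sampled
  mis-assigned reads;
* identical-genome control: 2 isolates, 50 kb, 30 Mb pool (about 3,000
  reads), where accuracy must sit at 1/2 and every sampled delta at 0;
* simulator recovery: 1 Mb of short reads and about 5,000 long reads at
  the default length model.

## Numerical and degenerate-input choices

* Ambiguous bases (N) never enter the index or the score: windows
  containing them are skipped, not substituted, so no k-mer is
  fabricated. A read shorter than k, or made entirely of ambiguous
  windows, has an all-zero hit vector and falls into the all-way draw.
* `count_kmers()` refuses inputs with no usable window, naming the
  sample; `clean_index()` refuses to return an empty index and advises a
  lower threshold.
* Index files are gzipped TSV with a versioned header (magic, version,
  k, sample id, threshold, raw/cleaned counts); loading verifies the
  magic, the version and — when the caller states one — the expected k,
  and round-trips are exact.
* All randomness in R and C++ flows through R's RNG, so one `set.seed`
  (or the `seed` argument / `--seed` flag) reproduces any run; the
  pipeline wrapper draws per-stage seeds from its master stream.

## Known limitations

* The shortest reads dominate the error budget. In the 230–500 bp tail
  of the length model only a handful of k-mers survive 12% error, and at
  SNP-only pairwise divergence of a few percent two mechanisms flip
  assignments there: surviving k-mers that happen to avoid every variant
  site of some competitor (a genuine tie), and a single read error that
  reverts a variant to the ancestral allele, making those windows match
  every other close relative but not the source. In our scaled
  simulations of 10 closely related isolates this holds demultiplexing
  accuracy just below 99.9%; multi-species pools, where competitors
  share almost no k-mers, are essentially immune.
* Scoring uses index membership only; a likelihood model over k-mer
  coverage might do better near ties but is out of scope by design.
* No read-to-graph alignment, bubble popping or tip clipping beyond the
  coverage-based supernode removal; the graph is discarded after
  assignment.
* Assignment accuracy degrades as isolates approach identity — by
  construction it reaches $1/n$ at divergence 0 — and per-read
  applications (e.g. read-based methylation calling) should not rely on
  individual assignments of closely related isolates, even though
  assembly-level results tolerate homology-driven mis-assignment well.
* The downstream hybrid assembly and the nucmer-based assembly metrics
  (SNP counts, reference recall) are external: `qv_score()` consumes SNP
  counts produced elsewhere.
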