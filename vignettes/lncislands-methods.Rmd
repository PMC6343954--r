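---
title: "Methods: reference-guided discovery of novel lncRNAs from coverage islands"
author: "lncislands"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided discovery of novel lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Long noncoding RNAs (lncRNAs) are transcripts longer than 200 nt with no
protein-coding capacity. They are expressed at roughly a tenth the level
of protein-coding genes, tend to be biexonic, and are poorly annotated
outside of well-studied tissues, so an RNA-seq experiment in a tissue
such as sensory ganglia will contain thousands of transcribed loci that
appear in no reference gene set. `lncislands` reconstructs such loci at
the *gene* level — one non-redundant model per locus, suitable for
count-based differential-expression analysis — from three pieces of
evidence produced by any splice-aware aligner on dUTP-stranded,
paired-end libraries:

1. per-base, per-strand coverage (bedGraph),
2. de-novo splice junctions with unique-read support (STAR
   `SJ.out.tab`),
3. the reference annotation (GTF) and genome (FASTA).

The procedure, per sample and strand:

* **Masking.** Every annotated gene model, extended by a 1000 bp flank
  on each side, is removed from the coverage of its own strand. The
  flank absorbs unannotated UTR extensions (rodent UTR means are a few
  hundred bp), so residual coverage cannot be an unannotated tail of a
  known gene. Masking is strand-specific: antisense transcription
  across a gene survives on the opposite strand, which is what makes
  antisense lncRNA discovery possible with stranded libraries.
* **Islands of expression.** Maximal runs of masked coverage with depth
  strictly above 2, at least 100 bp long (one read length, so
  overlapping mates cannot fake an island).
* **Junction filtering.** Junctions are kept with more than 2 unique
  reads and intron lengths strictly between 20 and 100,000 bp, dropping
  annotated junctions and any junction intersecting the same-strand
  mask.
* **Clustering.** Islands become nodes; a junction whose donor end
  falls in (or abuts, within 10 bp) one island and whose acceptor end
  falls in another adds an edge. Connected components are transcript
  clusters.
* **Consensus introns.** The union of a cluster's junction intervals is
  broken into atomic segments at every junction boundary; a segment is
  intronic when the fraction of junctions containing it, among the
  junctions overlapping its contiguous block, exceeds 1/2. Adjacent
  accepted segments merge; introns shorter than 20 bp are dropped.
* **Reconstruction.** Consensus introns are subtracted from the hull of
  the cluster's islands; pieces without island support are discarded.
* **Smoothed z-score refinement.** Exon coverage is scanned with a
  trailing 31 bp window; a position whose depth falls more than 5
  floored standard deviations below the rolling mean is a drop (peaks
  are flagged symmetrically). Flagged positions have influence 0 — they
  do not update the rolling statistics. Interior drop runs of at least
  20 bp become introns the aligner missed; a trailing drop run trims
  the transcript end.
* **Monoexonic path.** Islands touched by no junction are reconciled
  across samples: a candidate region is the intersection of
  co-overlapping junction-free islands across *all* samples, and only
  regions whose length-normalised coverage sits in the strict top
  decile of the whole monoexonic population survive
  (`Pr(>) = #{c' > c}/N < 0.1`).
* **Merging.** Per-sample candidates with overlapping same-strand
  exonic bp are unioned into one gene-level model; a gene is kept only
  if it was contributed by every replicate of at least one condition.
* **Classification.** Priority antisense > intronic > intergenic:
  antisense means at least one exonic bp overlaps an annotated exon on
  the opposite strand; intronic means containment in an annotated
  intron (either strand by default) without such overlap; intergenic
  otherwise. The closest gene (zero distance for antisense/intronic
  hosts; minimal genomic gap otherwise, ties to the lexicographically
  smaller id) also names the candidate:
  `<gene>_LNCRNA[_IG|_IN]:<chr>:<start>-<end>(<strand>)`.
* **Filters.** Length at least 200 bp; coding probability below the
  cutoff; replicate consistency; mean FPKM strictly above 0.5 in at
  least one condition, with `FPKM = count * 1e9 / (length * library size)`.

Coding potential is a CPAT-style logistic regression on four sequence
features: longest sense-strand ORF length and coverage, the Fickett
TESTCODE statistic (published position/composition lookup tables), and
mean in-frame hexamer usage log-ratio. No pre-trained model is shipped;
`train_coding_model()` fits one from labelled coding/noncoding FASTAs
supplied by the user (or by the simulator).

Downstream metrics operate on expression matrices and annotations: the
tau specificity index `tau = sum(1 - x_i/max(x))/(N - 1)` on per-subtype
means of `log2(x + 1)` expression, with subtype-specific features
requiring `tau > 0.8` and a best-subtype mean above 3; a hand-built
two-sided Fisher exact test for enrichment (odds ratio `(a d)/(b c)`
with Haldane correction, not the conditional MLE); strand-oriented TSS
proximity with 1.5 IQR outlier trimming; Pearson correlation with the
closest neighbour on `log2(x + 1)` values plus a Spearman
distance-correlation association; and the fraction of antisense/sense
pairs with opposite log2 fold changes.

# Parameters

| parameter | default | unit | why |
|---|---|---|---|
| `flank_bp` | 1000 | bp | absorbs unannotated UTR extensions |
| `depth_threshold` | 2 (strict) | reads | low floor for a complete survey of weak transcription |
| `min_island_length` | 100 | bp | one read length; shorter runs can be a single mate pair |
| `sj_min_unique_reads` | 3 (= more than 2) | reads | discards spurious alignments |
| `sj_min_length` / `sj_max_length` | 21 / 99,999 | bp | biological intron length range |
| `z_window` | 31 (odd) | bp | smoothing window of the breakpoint detector |
| `z_drop_threshold` | 5 | SD | sustained, large drops only |
| `z_min_intron` | 20 | bp | minimum intron the detector may call |
| `z_sd_floor` | 1 | depth | prevents zero-variance blowups on flat plateaus |
| `consensus_fraction` | 0.5 | — | strict majority for consensus-intron segments |
| `junction_tolerance_bp` | 10 | bp | soft-clip noise at junction/island attachment |
| `min_transcript_length` | 200 | bp | the lncRNA length definition |
| `min_fpkm` | 0.5 (strict) | FPKM | expression floor in the best condition |
| `monoexonic_pr_cutoff` | 0.1 | — | top decile of monoexonic coverage |
| `coding_cutoff` | 0.44 | probability | published mouse cutoff for CPAT-style models; override per species |

# Design choices made where the design was open

* **Coordinates.** All internal intervals are Bioconductor
  `GRanges`/`IRanges` (1-based, closed). Readers convert bedGraph
  (0-based half-open) and STAR junction coordinates on input; display
  names are 1-based inclusive with ASCII strand symbols. Delegating
  interval arithmetic to IRanges removes the off-by-one class of bugs
  that a hand-rolled half-open convention is meant to prevent.
* **Two mask modes.** Masking whole gene spans makes intronic discovery
  impossible on the same strand, yet intronic lncRNAs are a real class.
  The pipeline therefore runs a second pass with an exon-union mask,
  restricted to same-strand gene bodies, requiring at least one novel
  junction, and rejecting retained introns (candidates whose two ends
  both lie within 10 bp of an annotated intron's boundaries).
  Opposite-strand intronic transcription is already visible in the
  first pass.
* **Monoexonic `Pr(>)`.** The survival value is `#{c' > c}/N` with the
  population pooled over both strands; ties share a survival value. In
  a population of N distinct coverages this keeps the top
  `ceiling(N/10)` candidates. A rank-based reading is the only
  distribution-free one; pooling strands is used because coverage
  strength is not a strand property.
* **Merging.** The merged gene's exon set is the union of its members'
  exons. Recomputing consensus introns on pooled junctions gives the
  same answer whenever samples agree (the common case by construction
  of the per-sample step) and the union is order-independent, which
  makes the merged output deterministic under any sample order.
* **Quantification.** Candidate read-pair counts are derived from the
  coverage evidence itself (summed exonic depth over twice the read
  length), so the expression filter needs no external counting step;
  per-sample library sizes may be supplied from an existing count
  matrix instead.
* **Configuration.** The file-based driver reads a YAML configuration
  (`run_all()`), and the `ioe` script under `inst/scripts/` exposes the
  stages as subcommands (`simulate`, `find-islands`, `assemble`,
  `filter`, `run-all`, `tau`, `tss`, `antisense-report`). The
  `assemble` subcommand works from island BED files and junction tables
  alone, so it omits the coverage-based z-score refinement; `run-all`
  is the full pipeline.
* **Fisher exact.** Implemented directly (hypergeometric point
  probabilities summed with a small relative tolerance) because the
  enrichment contract wants the cross-product odds ratio with Haldane
  correction; `stats::fisher.test` serves as an independent
  cross-check in the test-suite, never as the implementation.

# The synthetic benchmark

`simulate_reference()` and `simulate_evidence()` generate a complete,
self-contained study: by default 2 chromosomes of 1 Mb tiled into 20 kb
blocks, 40 multi-exon coding genes with codon-biased ORFs written into
the genome sequence, and 30 planted novel lncRNAs — 6 antisense
(overlapping host exons on the opposite strand), 15 intergenic, 6
intronic (deep inside a long host intron, same strand), 3 monoexonic —
plus 10 coding-like biexonic decoys, profiled in 2 conditions times 3
replicates. Planted intergenic features are placed over 1000 bp from
any gene span by construction, so they cannot be masked away. The
monoexonic class is held at 10% of planted features: the top-decile
`Pr(>)` filter retains about one in ten monoexonic candidates by
design, so a benchmark in which a much larger share of the truth is
monoexonic could not be recovered by *any* faithful implementation of
the procedure; the biexonic-skewed exon distribution
(2 exons : 55%-like weight) is kept among the multiexonic features.

Evidence generation: each expressed feature gets a per-feature target
depth drawn uniformly from 8–20; each exon's plateau is
`max(3, Poisson(target))` per sample — the truncation guarantees that an
expressed feature clears the island floor, emulating consistent
expression across replicates. Junction support is uniform on 5–15
unique reads per sample. Background noise is planted as sparse 20–80 bp
runs of depth 3–6, above the depth threshold but below the island
length, so it stresses the length filter rather than the depth filter.
Counts are negative binomial (dispersion 0.1) around a programme in
which lncRNAs sit tenfold below coding genes; a configurable fraction
(default 0.4) of antisense lncRNAs receives a condition effect with the
opposite sign to its host gene. A CAGE-like TSS track is emitted at
feature 5' ends with 30 bp Gaussian jitter (90% of features).

The simulated codon usage is deliberately asymmetric under reverse
complement (A-rich, T-poor codons): real coding sequence is
strand-asymmetric, and this is exactly the property that lets hexamer
usage separate an antisense lncRNA — whose sequence is the reverse
complement of coding exons — from genuinely coding sequence. A
symmetric toy bias would make every antisense candidate look coding and
would misrepresent how the coding filter behaves on real data.

What the generator does *not* emulate: mappability and GC biases,
soft-clipped or multi-mapped reads, overlapping genes on the same
strand, alternative isoforms (the pipeline is gene-level by design),
library-size scales of real experiments (library sizes here are small;
all FPKM comparisons are threshold-based, not scale-calibrated), and
positionally correlated noise. Passing the synthetic benchmark
therefore demonstrates the correctness of the algorithmic chain under
the stated noise model, not performance on a real aligner's output.

# Numerical and degeneracy conventions

* Rolling mean/variance in the z-score detector are maintained by an
  O(1) update of sums over the filtered series; the standard deviation
  is floored at `z_sd_floor` before thresholding.
* A cluster whose consensus subtraction consumes the whole hull yields
  no candidate rather than an error; junction-free multi-island
  clusters cannot arise within one sample (islands are disjoint).
* `tau` rejects all-zero and negative profiles; Fisher enrichment
  rejects degenerate margins; FPKM rejects non-positive lengths and
  library sizes.
* Distances are gap widths in bp (0 for touching or overlapping
  features). Closest-gene ties break to the lexicographically smaller
  gene id.
* Candidate ids are assigned after sorting merged models by genomic
  position, so outputs are independent of sample order and re-runs are
  byte-identical.

# Problem sizes used by the test-suite

Unit tests run on toy tracks (hundreds of bp to 10 kb) against
position-scan, transitive-closure, exhaustive-ORF, table-lookup and
enumeration oracles. The end-to-end benchmark uses the default
configuration above (2 x 1 Mb, 30 planted lncRNAs, 6 samples), which
completes in about two minutes on one core; the determinism check uses
a 1 x 400 kb configuration. These sizes were chosen so that the whole
suite exercises every stage, including the full pipeline twice, in a
few minutes.

# Known limitations

* Coverage-level masking is a conservative approximation of read-level
  filtering: a read pair straddling a mask boundary contributes its
  unmasked bases. A strict read-level filter would require BAM input,
  which the bedGraph contract intentionally avoids.
* The monoexonic filter is rank-based within one run, so its outcome
  depends on the composition of the monoexonic population in that run.
* The coding model is only as good as its training sets; with the
  synthetic trainer it separates codon-biased ORFs from random
  sequence, which is an easier task than real coding/noncoding
  discrimination.
* Isoform structure within a locus is deliberately collapsed to one
  gene-level model.
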