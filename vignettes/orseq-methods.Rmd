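---
title: "orseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `orseq`, the parameter
choices that matter, and the design decisions that were genuinely open.
The package addresses one question: across a panel of bulk RNA-seq tissue
libraries, which olfactory receptor (OR) genes and pseudogenes are
expressed above technical background, and which apparent OR signals are
by-products of transcription of neighbouring genes?

## Quantification model

Expression is quantified by union-exon counting. All exons annotated for a
locus are merged into a set of disjoint intervals, and a fragment (a read,
or a read pair counted once) is assigned to the locus if any aligned base
of any of its blocks overlaps that union. Abundance is reported in FPKM,

$$\mathrm{FPKM} = \frac{c \cdot 10^9}{L \cdot N},$$

where $c$ is the fragment count, $L$ the union-exon length in bp, and $N$
the library's total number of fragments with at least one reported
alignment. Three consequences of this model are worth keeping in mind.

* It is deterministic and exactly testable against a base-by-base overlap
  oracle, which the test suite does on a 50-kb toy genome. Transcript-level
  EM estimators assign multi-gene reads probabilistically; union-exon
  counting instead **double-counts** fragments where loci overlap. This is
  deliberate: overlapping OR/host-gene pairs are reported separately, each
  with its own count, and the overlap itself is analysed by the chimera
  module rather than hidden in an assignment heuristic.
* $N$ is the mapped-fragment total of the library, not the sum of assigned
  fragments; intergenic and intronic fragments dilute all FPKMs equally.
* FPKM is quantised: one fragment on a locus of length $L$ contributes
  $10^9/(LN)$ FPKM. At $N = 2\times10^6$ and $L = 1$ kb the quantum is
  0.5 FPKM; at the depths of real body-map libraries
  ($N \approx 7\times10^7$) it is ~0.013. Desk-scale studies that must
  resolve the 0.01–0.1 FPKM band therefore use 10-kb single-exon loci
  (quantum 0.05), keeping every simulation small while preserving the
  statistical geometry of the threshold problem.

## The intergenic background null

The detection threshold is calibrated from regions that should contain no
signal. `intergenic_space()` removes every locus span (first exon start to
last exon end, so introns are masked too) plus a flank from the genome;
`sample_background_regions()` then places regions uniformly at random in
the remaining space, one per annotated gene, length-matched to the gene's
union-exon length, rejecting overlaps among placed regions (larger regions
are placed first to reduce infeasibility). Quantifying these regions with
the same denominator yields the null FPKM distribution.

Genes and background regions are binned by FPKM. Within bin $b$ the false
discovery rate is $\mathrm{fdr}_b = \min(1, I_b/G_b)$ (defined as 0 when
$G_b = 0$: no detections, nothing to be false), and the estimated true
count is $G_b(1-\mathrm{fdr}_b)$. Cumulating intergenic and gene counts
from above gives $\mathrm{FDR}(\theta)$; cumulating the estimated-true
mass from below and normalising gives $\mathrm{FNR}(\theta)$. The
detection threshold is the smallest bin edge with
$\mathrm{FDR} \le \mathrm{FNR}$; the analysis convention is to set the
working threshold slightly above this crossing, and the default calls are
`expressed` above 0.1 FPKM, `potential` in the closed band [0.01, 0.1]
(ties at 0.1 fall in the band, since "expressed" is a strict inequality),
and `not_detected` below.

The quality of the sub-threshold band is summarised by the window
true-positive fraction $1 - I_w/G_w$ over a closed FPKM window, floored at
zero.

Parameters that matter:

* `flank` (bp, default 10 000) — exclusion margin around gene spans. The
  default reflects the convention that suitable intergenic regions keep
  well clear of genes; desk-scale toy genomes use 2 000 bp because their
  intergenic gaps are only 10–30 kb wide and a 10-kb flank would mask them
  entirely. The flank changes which space is sampled, not the statistics
  computed on it.
* `bin_edges` — default log10-spaced, 5 per decade, $10^{-3}$–$10^3$ FPKM.
  The grid density is a presentation choice; tests that compare counts at
  exact fragment thresholds use half-count edges $(k - 0.5)\cdot q$ so
  that floating-point rounding of the quantum $q$ cannot move a value
  across a bin boundary.
* FNR estimation — only the *shape* of the estimated-true histogram enters
  the FNR; it is implemented as the estimated-true mass below $\theta$
  over the total estimated-true mass, matching the cumulative construction
  of the FDR.

## Reproducibility and neighbourhood statistics

`replicate_overlap()` takes the targets of one data set inside a weak
window (default [0.01, 0.1] FPKM) and reports the fraction detected (at
least 0.01 FPKM — "detected" is deliberately the weakest call) in a second
data set. Between replicates of one tissue this fraction is high; against
an unrelated tissue it collapses to the background rate, which is the
evidence that the weak window carries real signal. `correlation_r2()`
computes squared Pearson correlation of $\log_{10}$ FPKM over targets
passing a floor in both sets (expression spans orders of magnitude, so raw
correlation would be dominated by the top gene; a raw-space option is
retained). `neighbor_dependence()` reports, among ORs expressed anywhere,
the share with at least one non-OR adjacent locus, and among ORs whose
neighbours are all OR-type, the share expressed; neighbours are the
nearest non-overlapping annotated loci on each side, any strand, with an
optional maximum distance (default unlimited; 0.5 Mb reproduces the
convention of earlier neighbourhood analyses).

## Chimeric transcripts and reading frames

Chimera detection works purely from spliced-alignment junctions; there is
no discordant-pair or assembly step. A junction is recorded as
(chrom, donor, acceptor, strand, support), with donor the exclusive end of
the left block and acceptor the start of the right block, and support the
number of distinct fragments spanning the gap. A call requires the
transcription-sense donor inside an exon of a non-OR locus and the final
acceptor inside the span of an OR gene or pseudogene on the same
chromosome, following the upstream gene's strand; junctions of known
antisense strand are ignored, and unstranded junctions are accepted for
either orientation. Chains are followed when one junction's acceptor and
the next junction's donor share an annotated exon, to a depth of five
junctions — multi-exon 5' structures occur in read-through transcripts but
unlimited chaining would invite combinatorial artefacts. Chain support is
the minimum along the chain. The default minimum support of 2 is a
documented choice: single-fragment junctions are treated as noise.

Frame classification: if the transcript enters the OR upstream (in
transcription direction) of the OR start codon, the OR ORF is intact
regardless of the upstream gene's frame. Otherwise, with $c_u$ the coding
bases of the upstream ORF retained by the transcript (including retained
intermediate exons of a chain) and $c_a$ the OR coding bases lost 5' of
the entry point, the fusion preserves the OR frame iff
$c_u \equiv c_a \pmod 3$. An entry point beyond the OR stop codon is a
malformed call and raises an error. The test suite validates the mod-3
rule against an oracle that builds actual nucleotide sequences, fuses
them, translates, and compares C-terminal peptides — for all nine
$(c_u \bmod 3)\times(c_a \bmod 3)$ combinations and on both strands.
Protein-level consequences beyond the frame class (premature stops in the
shifted frame) would require genomic sequence and are not computed.

Internal splicing inside an OR ORF removes `acceptor - donor` coding
bases: an in-frame deletion when divisible by 3, otherwise a frameshift.
Junction endpoints that neither fall inside any annotated exon nor match
an exon boundary (tolerance 0 bp by default — synthetic data is exact;
real data would need slack) are reported as evidence for unannotated
exons, e.g. novel OR 5'UTRs.

## The synthetic-data generator

`build_toy_annotation()` lays out a deterministic (per seed) toy genome:
by default two 500-kb chromosomes carrying 60 loci — 30 multi-exon non-OR
genes with spliced ORFs, 20 single-exon OR genes with 939-bp intron-free
ORFs, 10 OR pseudogenes without ORFs — an OR cluster block, intergenic
gaps of 10–14 kb, and one non-OR gene placed 2 kb upstream of an OR as the
read-through pair. `simulate_tissue()` draws per-locus fragment counts
from a Poisson with mean
$\lambda = f \cdot (L/1000) \cdot (N/10^6)$ for true FPKM $f$, places
fragment starts uniformly in exon space (splicing blocks across introns),
adds `noise_rate` $\cdot N$ single-block fragments uniformly over the
genome, realises planted chimeric and internal-splice junctions as spliced
fragments, and declares `total_mapped = N` (the fragments not materialised
stand for the unmodelled remainder of the transcriptome).

What the generator emulates: Poisson counting noise, uniform intergenic
background, FPKM quantisation at realistic relative depth, spliced
alignment structure, read-through junctions with controllable frame
consequences. What it does not: overdispersion between biological
replicates, mappability and GC bias, sequencing error, multi-mapping
ambiguity between near-identical OR paralogs (the similarity-merge
machinery is exercised with configured groups instead), and
transcript-level isoform mixtures. Passing desk-scale tests therefore
demonstrates correctness of the *computational* chain under its own
statistical assumptions, not robustness to the biases of real libraries —
full-scale reproduction would feed alignments from a spliced aligner
directly into `read_alignments()`.

`noise_rate` is the fraction of fragments that are intergenic noise. On a
toy genome the analysis-relevant quantity is the background FPKM,
`noise_rate * 1e9 / genome_length`, so realistic values are far smaller
than on a 3-Gb genome; the default `2e-5` puts the toy background at
~0.02 FPKM, inside the "potentially expressed" band.

## Study designs used by tests and the acceptance script

All designs were fixed from Poisson expectations before the tests were
run; the problem sizes keep every study inside a few minutes on one CPU.

* **Oracle equivalence**: 50-kb genome, 20 loci, ~5 000 fragments;
  union-exon counts must equal a prefix-sum membership oracle exactly.
* **Recovery**: default 60-locus genome at $2\times10^6$ fragments, truth
  log-uniform on [1, 100] FPKM; estimates for loci with
  $\lambda \ge 25$ regress through the origin with slope in [0.95, 1.05]
  (3 seeds averaged), and ≥99% of loci stay within $3\sqrt\lambda/\lambda$
  relative error (5 seeds pooled, because the exact Poisson two-sided
  3-sigma exceedance is ~0.3% per locus and a single-seed check at 60
  loci could not distinguish that from failure).
* **FDR calibration**: 500 truly-zero + 20 expressed 10-kb loci,
  `noise_rate` 0.02, $4.25\times10^6$ fragments. The FDR curve is pooled
  over 12 simulated tissues — exactly as the calibration pools every
  data set of a study into one curve — and validated against the
  truth-computed false-discovery proportion of a single tissue on a
  13-point grid in the background's upper tail. Pooling is essential, not
  cosmetic: a curve estimated from a single tissue has the same sampling
  variance as the quantity it is checked against, and two independent
  binomial draws cannot sit inside a one-sample 95% interval 90% of the
  time.
* **Threshold crossing**: 1 200 zero + 400 expressed (log-uniform
  [0.08, 3] FPKM) 10-kb loci with background mean 0.3 fragments per locus
  place the expected FDR/FNR crossing at ~0.13 FPKM;
  `find_threshold()` must land within one log-grid bin of the closed-form
  crossing for three seeds.
* **Window true positives**: 800 loci at 0.015 FPKM over background mean
  0.043 put ~230 genes and ~34 background regions in the 0.01–0.1 window
  (designed TP fraction ~0.85); the measured fraction must match the
  closed-form design within ±0.10.
* **Replicate overlap**: 400 loci at 0.05 FPKM; weak-window targets of
  one replicate must be detected in a second replicate more than 50% of
  the time but in a zero-truth tissue less than 15%.
* **Chimeras**: planted junctions at support ≥ 5 against 30 support-1
  noise junctions must be recovered at `min_support = 2` with precision
  and recall 1.

## Numerical and edge-case conventions

* Coordinates are 0-based half-open internally; GTF I/O converts from the
  1-based inclusive convention, BED is native.
* Degenerate inputs raise informative errors rather than returning
  defaults: zero-length regions, empty detection windows, fewer than three
  targets for a correlation, an FDR curve that never crosses the FNR, a
  background length that cannot be placed, a fragment length exceeding a
  locus's exon union.
* `fdr_b` caps at 1; `FNR` is 0 when there is no estimated-true mass;
  values outside the bin grid are excluded from binning (cumulative counts
  are taken within the grid, so the top edge should cover the data).
* Seeded operations (`sample_background_regions`, the simulator, the
  annotation builder) restore the caller's RNG state on exit.

## Known limitations

* Union-exon counting double-counts fragments shared by overlapping loci;
  FPKMs of overlapping gene pairs are not additive.
* The library is treated as unstranded; junction orientation is resolved
  against the annotation, so antisense transcription through an OR is
  indistinguishable from sense read-through without strand information.
* Paired-end mates are expected under one fragment name; chimeric
  evidence from discordant pairs (as opposed to spliced junctions) is out
  of scope.
* The chimera caller requires the upstream partner to be annotated; a
  read-through from an unannotated promoter appears only in the
  unannotated-exon evidence table.
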