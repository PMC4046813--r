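---
title: "Methods: TSS sharpness, splicing and promoter analytics in tsskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS sharpness, splicing and promoter analytics in tsskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: what each
stage assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## Coordinates and containers

All internal coordinates are 0-based half-open (BED-native); GFF3/GTF
(1-based inclusive) is converted only at the I/O boundary, by
`read_annotation()` / `write_annotation()` / `write_regions()`. A single
convention across eight modules prevents off-by-one drift, and the
round-trip identity is property-tested. Alignments enter as BED12 (blocks =
spliced segments); BAM is deliberately not parsed — converting upstream
with standard tools keeps every fixture a small text file.

## Expression summaries

A read counts toward a locus when any aligned block overlaps it by one base
or more; same-strand overlap is sense, opposite antisense. Reads touching
several loci count once per locus and are flagged ambiguous (naive per-locus
counting, matching how per-locus RPKM tables are normally built). RPKM uses
the annotated locus span, not the exon sum, and the expressed-locus
threshold `RPKM > 1` is strict. Genome coverage is the fraction of bases
with depth >= 1 combined over both strands.

## Transcribed fragments and gene-count extrapolation

The transfrag caller is a coverage merge: maximal per-strand runs with
depth >= `min_depth` (default 1), bridging internal gaps up to `max_gap`
(default 0) and keeping runs >= `min_length` (default 1). This is the
simplest rule consistent with "covered by at least one read"; full isoform
assembly is out of scope. Novelty of a transfrag is tested strand-blind
(overlap with any annotated locus in either direction); a strand-aware
variant exists but is not the default, matching how novel fractions are
conventionally denominated. If a fraction *f* of transcribed bases falls in novel
fragments and annotated/unannotated genes share a length distribution, the
annotated count *N* extrapolates to *N*/(1 − *f*) total genes; the
inverse-consistency of this map is property-tested.

ORFs are scanned in all six frames from ATG to the next stop (or the
sequence end, kept and flagged partial); the length threshold (default
300 nt = 100 aa) applies to the coding part excluding the stop. Nested ATGs
within an open stretch are not reported separately.

## Splicing

Introns are the inter-block gaps of spliced reads, keyed exactly by
(chromosome, strand, interval); support is the number of distinct reads.
Accepted lengths default to 10–4000 nt, echoing common short-read mapping
bounds. Splice classes (GT-AG, AT-AC, GC-AG, other) are read from the
strand-corrected intron sequence. Junction matching against annotation is
exact (no fuzz window — junctions are base-precise in spliced alignments)
and strand-aware: the donor is the 5' junction. Transcript sets are
single-linkage groups of same-strand transcripts whose spans overlap by at
least one base; a set with more than one member counts as alternatively
spliced (requiring distinct intron chains would be stricter and is not
implemented). Exon skipping is the pattern of one long
intron sharing its two boundaries with two non-overlapping strictly shorter
introns; "short" has no absolute threshold. The detector is verified
against a brute-force triple enumeration. Intron retention is an exon of
one member fully containing an intron of another; when the genome and CDS
are supplied, the retained coding sequence is translated in the frame at
the insertion point and a premature stop is called if a stop codon appears
before the annotated terminal codon.

## Antisense bias

Each locus splits into strand-oriented thirds (the remainder base of
lengths not divisible by 3 goes to the central third; on the minus strand
the left genomic third is the 3' end). A read is assigned to the third
holding its strand-oriented 5'-most base — deterministic and
orientation-symmetric (the symmetry is property-tested). Label thresholds are
strict: 5'-biased iff >40% of antisense reads in
the 5' third and <10% in the 3' third; 3'-biased symmetrically; central
iff >75% central; otherwise unbiased. The two end-bias conditions are
mutually exclusive by construction. A floor of `min_reads = 10` avoids labelling
sampling noise; set `min_reads = 1` to label every locus with reads.

## TSS calling and the mirror-bootstrap CIL

Read heads are shifted 1 nt 5' of the mapped read start (the offset
compensates a base trimmed in mapping); the shift is a signed parameter.
Region calling is greedy: highest remaining head with depth >= `min_peak`
(10), 121-nt window centred there, accepted iff >= `min_total` (50) heads
remain in the window, then the window is masked whether or not accepted.
Ties go to the smaller coordinate; windows at contig edges are truncated,
not discarded; accepted regions are pairwise disjoint (property-tested).

The sharpness statistic mirrors the window counts about the peak and
bootstraps the mean position: `n_boot` (2000) resamples of size `n` (the
original, unmirrored head count — mirroring changes shape, not sample
size), percentile interval at `level` (0.95), CIL = interval length. The
statistic is the resample mean; a mode variant is exposed as an exploratory
flag. CIL = 0 exactly when all heads sit on one base. Class boundaries are
inclusive downward: tight (<= 2 nt), intermediate (2, 4], diffuse (> 4).
For discretized-normal profiles the bootstrap tracks
`2 * 1.96 * sigma / sqrt(n)`; discretization adds variance 1/12, visible at
`sigma = 1` (about +4%), and the suite allows 20% relative error on a
`sigma x n` grid. Note the strong `n`-dependence: the same positional
spread is "tight" at high coverage and "diffuse" at low coverage — class
labels are statements about the evidence, not only about the promoter.

TSS link to genes when the peak lies 1–500 nt upstream of a same-strand
locus 5' end (nearest eligible locus wins); peaks inside a locus body are
internal. UTR length is the peak-to-locus-start distance, which equals the
peak-to-ATG distance when loci are annotated by their CDS (as the generator
does).

## Promoters and motifs

Promoters cover −200..+24 relative to the peak (position 0 = peak), 225 nt,
strand-corrected; truncated promoters are excluded from positional
statistics. Scanning is sense-strand IUPAC matching via
`Biostrings::vmatchPattern(fixed = "subject")`, overlapping matches
included.

The background is an order-3 Markov model with pseudocount smoothing,
trained by default on sequences upstream of translation starts. Expected
motif counts sum, over sequences and start offsets, the probability that
the model emits any word matching the motif given the position-specific
left context; scanning for enrichment starts at offset `order` within each
sequence so a full context always exists, and observed counts cover the
same positions. The Z-score uses a Poisson variance approximation
(`var = expected`) — simpler than an exact word-count variance and
conservative for rare motifs; it overstates significance for very common,
self-overlapping words. Exhaustive enumeration scores every concrete word
occurring at least `min_count` times, then generates degenerate variants
(<= 2 ambiguity symbols from {R, Y, S, W, N} by default) around the
`expand_top` best words; redundancy is reduced greedily by Jaccard overlap
(> 0.5) of promoter hit sets, at most 20 motifs per length — a deliberate
simplification of specialised motif-explanation tools, not claimed
equivalent.

Positional uniformity is a chi-squared goodness-of-fit over 10-nt bins
tiling the promoter (the last bin is short; expectations scale with bin
width). Counts below 5 per bin on average are flagged low-power. One
caveat established during calibration: hits of *self-overlapping* motifs
(e.g. TATA) cluster, which overdisperses the statistic and inflates the
type-I error; the null-calibration test therefore probes with a
non-self-overlapping word, and users should interpret uniformity p-values
for self-overlapping motifs cautiously. Conservation across orthologue
pairs uses presence/absence in each species' 300-nt upstream region and a
2x2 chi-squared test; because it is unstated whether a continuity
correction applies, both the uncorrected and Yates-corrected statistics are
reported.

## The synthetic-data generator

The generator emulates, with one fixed seed giving byte-identical output:

* non-overlapping genes on both strands, exon/intron chains with junction
  dinucleotides written into the genome (strand-corrected) according to the
  class weights 21794 : 428 : 414 (GT-AG : AT-AC : GC-AG);
* intron lengths from a shifted lognormal, `44 + Lognormal(log 15, 1.28)`
  truncated to [10, 4000] nt — the shift gives the hard left edge of real
  intron lengths; moment matching reproduces a median of 59 nt with central
  95% near [46, 228];
* long-tailed expression (lognormal; the draw is the expected sense read
  count), reads placed uniformly on the mature transcript so junction reads
  arise naturally;
* antisense reads at a configurable fraction with none/5'/central/3' bias:
  the biased third receives probability `strength`, the remainder splits
  3:1 toward the central third;
* 5' UTR lengths lognormal with median 93 nt, truncated to [5, 480];
* read heads per TSS from class-specific mixtures of sharp sub-peaks
  (sub-peak spread 1.5 nt): tight {0}, intermediate {−8, +8}, diffuse
  {−25, 0, +25}, 200 heads per TSS, plus a uniform per-base background
  emulating degradation;
* promoter motif planting at configurable offsets (normal or uniform law)
  with strand-corrected insertion.

Why sub-peak mixtures and not one wide normal per class: the calling
thresholds (peak >= 10, window >= 50) and the CIL jointly constrain a
unimodal profile — a normal wide enough to be "diffuse" cannot reach peak
depth 10 at any coverage where its CIL stays above 4 (peak height scales as
`n / (sigma * sqrt(2*pi))` while CIL scales as `sigma / sqrt(n)`; the
121-bp window also caps the attainable positional spread near 35 nt). Real
diffuse regions are described as multiple lower peaks, and a mixture of
sharp alternative starts reproduces exactly that: every sub-peak clears the
depth filter while the region-level spread is set by the sub-peak offsets.
Because the statistic mirrors about the peak, the effective spread is the
RMS deviation about the tallest sub-peak; the offsets above give analytic
CILs of about 0.4, 3.2 and 5.7–9.0 nt at 200 heads — inside the three
bands for every possible winning sub-peak.

What the generator does **not** emulate: sequencing error, colour-space
artefacts, mappability variation, polyA sites, overlapping genes, UTR
introns, nucleotide composition of real promoters (background genome is
i.i.d. uniform), and expression correlation between sense and antisense.
Passing recovery tests therefore demonstrates the correctness of the
inference machinery under the stated laws, not robustness to every real
artefact.

## Problem sizes and numerical choices in the shipped tests

The suite runs in a few minutes on one CPU: the analytic-limit grid uses
`sigma` in {1, 5, 20} by `n` in {100, 400, 1600} with 2000 bootstrap
replicates; generator round-trips use a 2000-gene, 5.6-Mb genome (about
4600 planted introns, 140k reads) and recover the intron-length median
within 2 nt, splice-class weights within 3 percentage points and the UTR
median within 3 nt of truth; the uniformity null calibration uses 1000 sets
of 400 background promoters; motif power uses CACGTG planted at −70 ± 5 in
half of 500 promoters. Bootstrap seeds are fixed and recorded in every
`cil_estimate`; `z = 1.959964` is used wherever the analytic 95% limit is
cross-checked.

## Known limitations

* The choice of bootstrap statistic (mean vs mode of the resample) is
  genuinely open; the mean is implemented and the mode exposed without any
  fidelity claim.
* The Poisson variance in motif Z-scores and the greedy Jaccard redundancy
  reduction are simplifications of YMF-class tooling.
* Genome-scale survey counts (tens of thousands of TSS regions and
  introns) depend on the original sequencing libraries and are not
  reproducible from synthetic data; the package targets the methods, their
  internal identities and their worked-example arithmetic instead.
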