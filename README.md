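# tsskit

Analytics for strand-specific RNA-seq annotation of compact (fungal)
genomes, centred on transcription start site (TSS) discovery from
5'-enriched libraries. The package implements the full downstream stack of
a transcriptome re-annotation study — expression summaries, transcribed
fragment discovery, splicing analysis, antisense classification, TSS calling
with a bootstrap sharpness metric, and promoter motif statistics — together
with a synthetic-data generator so that every stage can be exercised and
validated without any external download.

## Who this is for

Bioinformaticians annotating a genome from stranded RNA-seq plus a
5'-end-enriched library (CAGE-like / 5' RATE-like data): the input is a
genome FASTA, a GFF3/GTF annotation, spliced alignments as BED12 and/or a
per-base read-head table; the outputs are per-locus expression tables,
transfrags, intron calls, antisense bias labels, classified TSS regions,
UTR lengths and promoter motif statistics.

## The core method: mirror-bootstrap CIL

Read heads (RH) are the inferred 5'-most transcript bases, one per read,
offset 1 nt from the mapped read start. A TSS region is a 121-bp window
centred on a major RH peak (peak depth >= 10 RH, window total >= 50 RH);
windows are chosen greedily by descending peak height and never share a
base. RH profiles in a window are usually not normal, so the profile is
**mirrored** about its peak,

    out[p] = in[p] + in[2 * peak - p],

yielding an exactly symmetric distribution with the original spread. The
sharpness of the TSS is then the **confidence-interval length (CIL)**: the
length of the central 95% percentile interval of bootstrap resample means
(resample size = the original RH count `n`) drawn from the mirrored
profile. For a near-normal spread `sigma` this approaches the analytic
limit

    CIL = 2 * z * sigma / sqrt(n),   z = 1.959964 at 95%,

which the test suite verifies to within 20% over a `sigma x n` grid.
Regions are classed `tight` (CIL <= 2 nt), `intermediate` (2 < CIL <= 4) or
`diffuse` (CIL > 4).

Promoters (positions -200..+24 relative to the TSS peak, strand-corrected)
are profiled for base/dinucleotide composition and scanned for IUPAC
motifs; enrichment is a Z-score of observed counts against expectations
under a third-order Markov background trained on upstream sequence, with
positional chi-squared uniformity tests and an orthologue-pair conservation
test.

## Worked example

Simulate a 60-gene genome with the default study-like laws, run the whole
pipeline, and compare against the planted truth:

```r
library(tsskit)

cfg   <- simulation_config(seed = 42, n_genes = 60, n_chroms = 2)
sim   <- simulate_genome_and_annotation(cfg)
reads <- simulate_reads(sim$bundle, sim$truth, cfg)

# expression
s <- expression_summary(expression_table(reads, sim$bundle$loci))

# splicing
intr <- extract_introns(reads)
cls  <- classify_splice_sites(intr, sim$bundle$sequences)

# TSS calling
rh    <- simulate_readheads(sim$bundle, sim$truth, cfg)
tss   <- call_and_classify_tss(rh, chrom_lengths = sim$bundle$chrom_lengths,
                               seed = 1)
links <- link_tss_to_genes(tss, sim$bundle$loci)
```

This prints (seed 42):

```
loci: 60 | sense detected: 98% | sense RPKM>1: 98%
introns: 99 | median length: 55 nt | classes: AT_AC 1, GC_AG 4, GT_AG 94
TSS regions: 60 | classes: diffuse 33, intermediate 11, tight 16
linked upstream: 59 | UTR median: 83 nt (planted law median 93)
extrapolation: +980 unannotated, 11800 total
```

All 60 planted TSS are called; class proportions track the configured
weights; the intron median (55 nt here, 59 at larger n) and the UTR median
track the generating laws. The last line is the gene-count extrapolation
from reported annotation inputs: with 10,827 annotated loci and a novel
transcribed-base fraction of 0.083, `extrapolate_gene_count()` estimates
about 980 unannotated transcripts and a total of about 11,800 genes.

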