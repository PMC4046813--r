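#' Count sense and antisense reads per locus
#'
#' A read is assigned to a locus if any aligned block overlaps it by at least
#' one base; same-strand overlap is sense, opposite-strand antisense. A read
#' overlapping several loci is counted once per overlapped locus and flagged
#' ambiguous.
#'
#' @param reads block-level read data frame (see [read_alignments()]).
#' @param loci locus data frame (`locus_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return data frame `locus_id`, `sense_count`, `antisense_count`,
#'   `ambiguous_count` (reads touching more than one locus).
#' @export
count_reads_per_locus <- function(reads, loci) {
  out <- data.frame(locus_id = loci$locus_id,
                    sense_count = 0L, antisense_count = 0L,
                    ambiguous_count = 0L, stringsAsFactors = FALSE)
  if (!nrow(reads) || !nrow(loci)) return(out)
  rgr <- GenomicRanges::GRanges(reads$chrom,
    IRanges::IRanges(reads$start + 1L, reads$end))
  lgr <- GenomicRanges::GRanges(loci$chrom,
    IRanges::IRanges(loci$start + 1L, loci$end))
  ov <- GenomicRanges::findOverlaps(rgr, lgr, ignore.strand = TRUE)
  if (!length(ov)) return(out)
  hit <- unique(data.frame(read = reads$read_id[S4Vectors::queryHits(ov)],
                           rstrand = reads$strand[S4Vectors::queryHits(ov)],
                           locus = S4Vectors::subjectHits(ov)))
  n_loci_per_read <- table(hit$read)
  hit$ambig <- n_loci_per_read[hit$read] > 1
  sense <- hit$rstrand == loci$strand[hit$locus]
  add <- function(col, idx) {
    t <- table(idx)
    out[[col]][as.integer(names(t))] <<- as.integer(t)
  }
  add("sense_count", hit$locus[sense])
  add("antisense_count", hit$locus[!sense])
  add("ambiguous_count", hit$locus[hit$ambig])
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (locus_length/1000) / (library_mapped/1e6)`. Vectorized.
#'
#' @param count read count(s), >= 0.
#' @param locus_length locus span in nt (> 0).
#' @param library_mapped total mapped reads in the library (> 0).
#' @return numeric RPKM.
#' @export
compute_rpkm <- function(count, locus_length, library_mapped) {
  if (any(locus_length <= 0)) stop("locus_length must be positive")
  if (any(library_mapped <= 0)) stop("library_mapped must be positive")
  count / (locus_length / 1000) / (library_mapped / 1e6)
}

#' Build a per-locus expression table
#'
#' Convenience wrapper combining [count_reads_per_locus()] and
#' [compute_rpkm()] for one library. Locus length is the annotated span
#' (start to end), not the exon sum.
#'
#' @param reads block-level read data frame.
#' @param loci locus data frame.
#' @param library_mapped library size; defaults to the number of distinct
#'   reads supplied.
#' @param library_id label stored in the output.
#' @return data frame with counts and sense/antisense RPKM per locus.
#' @export
expression_table <- function(reads, loci,
                             library_mapped = length(unique(reads$read_id)),
                             library_id = "lib1") {
  cnt <- count_reads_per_locus(reads, loci)
  len <- loci$end - loci$start
  cnt$rpkm_sense <- compute_rpkm(cnt$sense_count, len, library_mapped)
  cnt$rpkm_antisense <- compute_rpkm(cnt$antisense_count, len, library_mapped)
  cnt$library_id <- library_id
  cnt
}

#' Expressed-gene summary fractions
#'
#' Per orientation: the fraction of loci with at least one read in any
#' library and the fraction with RPKM strictly greater than 1 (in any
#' library).
#'
#' @param table per-locus expression table (rows may repeat a locus across
#'   libraries) with columns `locus_id`, `sense_count`, `antisense_count`,
#'   `rpkm_sense`, `rpkm_antisense`.
#' @return list with `n_loci` and, per orientation, `frac_detected`
#'   (>= 1 read) and `frac_rpkm_gt1` (RPKM > 1, strict).
#' @export
expression_summary <- function(table) {
  if (!nrow(table)) stop("empty expression table")
  agg <- function(col) tapply(table[[col]], table$locus_id, max)
  s_cnt <- agg("sense_count"); a_cnt <- agg("antisense_count")
  s_rpkm <- agg("rpkm_sense"); a_rpkm <- agg("rpkm_antisense")
  list(n_loci = length(s_cnt),
       sense = list(frac_detected = mean(s_cnt >= 1),
                    frac_rpkm_gt1 = mean(s_rpkm > 1)),
       antisense = list(frac_detected = mean(a_cnt >= 1),
                        frac_rpkm_gt1 = mean(a_rpkm > 1)))
}

#' Per-base coverage track from reads
#'
#' Depth per strand per chromosome as run-length encodings; base `i`
#' (0-based) corresponds to run position `i + 1`.
#'
#' @param reads block-level read data frame.
#' @param chrom_lengths named chromosome lengths.
#' @return object of class `coverage_track`: list of strands `+`/`-`, each a
#'   named list of [S4Vectors::Rle] depth vectors.
#' @export
coverage_track <- function(reads, chrom_lengths) {
  mk <- function(st) {
    r <- reads[reads$strand == st, , drop = FALSE]
    lapply(setNames(names(chrom_lengths), names(chrom_lengths)),
           function(ch) {
             b <- r[r$chrom == ch, , drop = FALSE]
             IRanges::coverage(IRanges::IRanges(b$start + 1L, b$end),
                               width = chrom_lengths[[ch]])
           })
  }
  structure(list(`+` = mk("+"), `-` = mk("-"),
                 chrom_lengths = chrom_lengths),
            class = "coverage_track")
}

#' Fraction of the genome covered by at least one read
#'
#' Combined over both strands; overlapping reads count once per base.
#'
#' @param coverage a [coverage_track()].
#' @return fraction in `[0, 1]`.
#' @export
genome_coverage_fraction <- function(coverage) {
  stopifnot(inherits(coverage, "coverage_track"))
  lens <- coverage$chrom_lengths
  covered <- sum(vapply(names(lens), function(ch) {
    both <- coverage$`+`[[ch]] + coverage$`-`[[ch]]
    sum(S4Vectors::runLength(both)[S4Vectors::runValue(both) >= 1])
  }, numeric(1)))
  covered / sum(lens)
}
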