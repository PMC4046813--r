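#' Call transcribed fragments from coverage
#'
#' Maximal runs of bases with depth at least `min_depth`, per strand,
#' bridging internal gaps up to `max_gap` bases and keeping runs of at least
#' `min_length` nt. The defaults implement the simplest rule consistent with
#' "covered by at least one read".
#'
#' @param coverage a [coverage_track()].
#' @param min_depth minimum per-base depth (reads).
#' @param max_gap longest internal sub-threshold gap bridged (nt).
#' @param min_length minimum transfrag length (nt).
#' @return data frame `chrom`, `strand`, `start`, `end`, `length`,
#'   `mean_depth` (mean depth over the final interval).
#' @export
call_transfrags <- function(coverage, min_depth = 1L, max_gap = 0L,
                            min_length = 1L) {
  stopifnot(inherits(coverage, "coverage_track"),
            min_depth >= 1, max_gap >= 0, min_length >= 1)
  out <- list()
  for (st in c("+", "-")) {
    for (ch in names(coverage$chrom_lengths)) {
      rle <- coverage[[st]][[ch]]
      ir <- IRanges::reduce(
        methods::as(S4Vectors::Rle(S4Vectors::runValue(rle) >= min_depth,
                                   S4Vectors::runLength(rle)), "IRanges"),
        min.gapwidth = max_gap + 1L)
      ir <- ir[IRanges::width(ir) >= min_length]
      if (!length(ir)) next
      md <- IRanges::viewMeans(IRanges::Views(rle, ir))
      out[[paste0(ch, st)]] <- data.frame(
        chrom = ch, strand = st,
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
        length = IRanges::width(ir), mean_depth = as.numeric(md),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      length = integer(), mean_depth = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Classify transfrags as annotated-overlapping or novel
#'
#' Overlap with annotated loci is tested strand-blind ("in either
#' direction"). Also reports the fraction of all transfrag bases lying in
#' novel fragments, the input to [extrapolate_gene_count()]. A strand-aware
#' variant is available via `strand_blind = FALSE`.
#'
#' @param transfrags output of [call_transfrags()].
#' @param loci locus data frame.
#' @param strand_blind test overlap irrespective of strand (default TRUE).
#' @return list with `calls` (transfrag table plus `status` and
#'   `overlapped_locus_ids`), `novel_count`, `total_count`,
#'   `novel_base_fraction`.
#' @export
classify_novelty <- function(transfrags, loci, strand_blind = TRUE) {
  n <- nrow(transfrags)
  status <- rep("novel", n)
  ids <- vector("list", n)
  if (n && nrow(loci)) {
    tgr <- GenomicRanges::GRanges(transfrags$chrom,
      IRanges::IRanges(transfrags$start + 1L, transfrags$end),
      strand = transfrags$strand)
    lgr <- GenomicRanges::GRanges(loci$chrom,
      IRanges::IRanges(loci$start + 1L, loci$end), strand = loci$strand)
    ov <- GenomicRanges::findOverlaps(tgr, lgr,
                                      ignore.strand = strand_blind)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      status[unique(q)] <- "overlaps_annotated"
      ids_hit <- split(loci$locus_id[S4Vectors::subjectHits(ov)], q)
      ids[as.integer(names(ids_hit))] <- ids_hit
    }
  }
  calls <- transfrags
  calls$status <- status
  calls$overlapped_locus_ids <- vapply(ids, function(v)
    paste(v, collapse = ","), character(1))
  novel <- status == "novel"
  list(calls = calls,
       novel_count = sum(novel), total_count = n,
       novel_base_fraction = if (n) sum(transfrags$length[novel]) /
         sum(transfrags$length) else 0)
}

#' Extrapolate the total gene count from the novel transcribed fraction
#'
#' Assuming annotated and unannotated genes share a length distribution, a
#' fraction `f` of transcribed bases in novel fragments implies
#' `total = annotated_n / (1 - f)` loci and
#' `additional = annotated_n * f / (1 - f)` unannotated ones.
#'
#' @param annotated_n number of annotated loci.
#' @param novel_base_fraction fraction `f` in `[0, 1)`.
#' @return list with `estimated_total` and `estimated_additional`.
#' @export
extrapolate_gene_count <- function(annotated_n, novel_base_fraction) {
  if (novel_base_fraction < 0 || novel_base_fraction >= 1)
    stop("novel_base_fraction must be in [0, 1)")
  total <- annotated_n / (1 - novel_base_fraction)
  list(estimated_total = total,
       estimated_additional = total - annotated_n)
}

#' Extract open reading frames from a sequence
#'
#' Scans all six frames (both strands) for ORFs starting at ATG and ending at
#' a stop codon or the sequence end; ORFs reaching the end without a stop are
#' kept and flagged `partial`. The length threshold applies to the coding
#' part in nucleotides, excluding the stop codon (300 nt = 100 aa). `N` bases
#' translate to `X`.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param min_orf minimum ORF length in nt (default 300).
#' @return data frame `strand`, `frame` (0-2), `start`, `end` (0-based
#'   half-open in the input sequence, coding part only), `length_nt`,
#'   `partial`, `peptide`.
#' @export
extract_orfs <- function(sequence, min_orf = 300L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  res <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (st in c("+", "-")) {
    s <- if (st == "+") sequence else revcomp(sequence)
    for (fr in 0:2) {
      ncod <- (n - fr) %/% 3
      if (ncod < 1) next
      codons <- substring(s, fr + 1 + 3 * (seq_len(ncod) - 1),
                          fr + 3 * seq_len(ncod))
      is_start <- codons == "ATG"
      is_stop <- codons %in% stops
      i <- 1L
      while (i <= ncod) {
        if (is_start[i]) {
          j <- i
          while (j <= ncod && !is_stop[j]) j <- j + 1L
          partial <- j > ncod
          len_nt <- 3L * ((if (partial) ncod else j - 1L) - i + 1L)
          if (len_nt >= min_orf) {
            cod_end <- if (partial) ncod else j - 1L
            a <- fr + 3L * (i - 1L)            # 0-based in strand s
            b <- fr + 3L * cod_end             # half-open
            orf_seq <- substr(s, a + 1, b)
            pep <- as.character(Biostrings::translate(
              Biostrings::DNAString(chartr("N", "N", orf_seq)),
              if.fuzzy.codon = "X"))
            res[[length(res) + 1]] <- data.frame(
              strand = st, frame = fr,
              start = if (st == "+") a else n - b,
              end = if (st == "+") b else n - a,
              length_nt = len_nt, partial = partial, peptide = pep,
              stringsAsFactors = FALSE)
          }
          i <- if (partial) ncod + 1L else j + 1L
        } else i <- i + 1L
      }
    }
  }
  if (!length(res))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      length_nt = integer(), partial = logical(),
                      peptide = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
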