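#' Extract introns from spliced reads
#'
#' Every gap between consecutive blocks of a read is a candidate intron,
#' keyed exactly by (chrom, strand, interval); support is the number of
#' distinct reads sharing the gap. Gaps outside the accepted length bounds
#' (defaults mirror typical short-read mapping limits) are dropped.
#'
#' @param reads block-level read data frame.
#' @param min_length,max_length accepted intron length bounds (nt).
#' @return data frame `chrom`, `strand`, `start`, `end`, `length`, `support`.
#' @export
extract_introns <- function(reads, min_length = 10L, max_length = 4000L) {
  empty <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      support = integer(), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  r <- reads[order(reads$read_id, reads$start), ]
  same <- r$read_id[-1] == r$read_id[-nrow(r)]
  if (!any(same)) return(empty)
  gs <- r$end[-nrow(r)][same]    # gap start (end of previous block)
  ge <- r$start[-1][same]        # gap end (start of next block)
  d <- data.frame(chrom = r$chrom[-1][same], strand = r$strand[-1][same],
                  start = gs, end = ge, read = r$read_id[-1][same],
                  stringsAsFactors = FALSE)
  d <- d[d$end - d$start >= min_length & d$end - d$start <= max_length, ,
         drop = FALSE]
  if (!nrow(d)) return(empty)
  d <- unique(d)   # one vote per read per junction
  key <- paste(d$chrom, d$strand, d$start, d$end)
  t <- table(key)
  first <- d[!duplicated(key), , drop = FALSE]
  first$support <- as.integer(t[paste(first$chrom, first$strand,
                                      first$start, first$end)])
  first$length <- first$end - first$start
  out <- first[order(first$chrom, first$start, first$end, first$strand),
               c("chrom", "strand", "start", "end", "length", "support")]
  rownames(out) <- NULL
  out
}

#' Classify splice-site dinucleotides
#'
#' Reads the first and last two intron bases from the transcribed
#' (strand-corrected) sequence and assigns GT_AG, AT_AC, GC_AG or other.
#' Introns at contig edges are classed `other` with a warning.
#'
#' @param introns intron data frame (see [extract_introns()]).
#' @param genome named character vector of chromosome sequences.
#' @return the intron table with `splice_class`, `donor2`, `acceptor2`
#'   columns added.
#' @export
classify_splice_sites <- function(introns, genome) {
  n <- nrow(introns)
  cls <- rep("other", n)
  don <- acc <- rep(NA_character_, n)
  lens <- nchar(genome)
  for (i in seq_len(n)) {
    ch <- introns$chrom[i]
    s <- introns$start[i]; e <- introns$end[i]
    if (s < 0 || e > lens[[ch]]) {
      warning("intron at contig edge classed 'other'")
      next
    }
    seq <- substr(genome[[ch]], s + 1, e)
    if (introns$strand[i] == "-") seq <- revcomp(seq)
    don[i] <- substr(seq, 1, 2)
    acc[i] <- substr(seq, nchar(seq) - 1, nchar(seq))
    cls[i] <- if (don[i] == "GT" && acc[i] == "AG") "GT_AG"
      else if (don[i] == "AT" && acc[i] == "AC") "AT_AC"
      else if (don[i] == "GC" && acc[i] == "AG") "GC_AG"
      else "other"
  }
  introns$splice_class <- cls
  introns$donor2 <- don
  introns$acceptor2 <- acc
  introns
}

#' Positional base frequencies at splice junctions
#'
#' For a set of introns (typically the GT-AG class), tallies per-position
#' base frequencies over the first `k` donor bases, the last 3 acceptor
#' bases, and the 2 exonic bases immediately upstream of the donor, all on
#' the transcribed strand. Columns sum to 100.
#'
#' @param introns intron data frame.
#' @param genome named character vector of sequences.
#' @param k donor positions to profile (default 7, e.g. GTRAAGT).
#' @return list of 4 x positions percentage matrices `donor`, `acceptor`,
#'   `exon_upstream`, and `n` introns used.
#' @export
splice_consensus <- function(introns, genome, k = 7L) {
  stopifnot(nrow(introns) >= 1)
  don <- character(0); acc <- character(0); exu <- character(0)
  lens <- nchar(genome)
  for (i in seq_len(nrow(introns))) {
    ch <- introns$chrom[i]
    s <- introns$start[i]; e <- introns$end[i]
    if (introns$strand[i] == "+") {
      if (s - 2 < 0 || e > lens[[ch]]) next
      don <- c(don, substr(genome[[ch]], s + 1, s + k))
      acc <- c(acc, substr(genome[[ch]], e - 2, e))
      exu <- c(exu, substr(genome[[ch]], s - 1, s))
    } else {
      if (e + 2 > lens[[ch]] || s < 0) next
      don <- c(don, revcomp(substr(genome[[ch]], e - k + 1, e)))
      acc <- c(acc, revcomp(substr(genome[[ch]], s + 1, s + 3)))
      exu <- c(exu, revcomp(substr(genome[[ch]], e + 1, e + 2)))
    }
  }
  freq <- function(x) {
    m <- do.call(rbind, strsplit(x, ""))
    apply(m, 2, function(col)
      100 * table(factor(col, levels = c("A", "C", "G", "T"))) / length(col))
  }
  list(donor = freq(don), acceptor = freq(acc), exon_upstream = freq(exu),
       n = length(don))
}

# annotated introns = gaps between consecutive exons of each locus
#' Derive annotated introns from exon chains
#' @param exons exon data frame (`locus_id`, `chrom`, `start`, `end`,
#'   `strand`), exons disjoint per locus.
#' @return intron-style data frame with `locus_id`.
#' @export
annotated_introns <- function(exons) {
  e <- exons[order(exons$locus_id, exons$start), ]
  same <- e$locus_id[-1] == e$locus_id[-nrow(e)]
  if (!nrow(e) || !any(same))
    return(data.frame(locus_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(locus_id = e$locus_id[-1][same], chrom = e$chrom[-1][same],
             strand = e$strand[-1][same],
             start = e$end[-nrow(e)][same], end = e$start[-1][same],
             stringsAsFactors = FALSE)
}

#' Match observed introns to annotated introns
#'
#' Junction equality is exact and strand-aware: the donor is the 5' junction
#' (interval start on `+`, interval end on `-`). Categories are mutually
#' exclusive, assigned in precedence order: both junctions equal an annotated
#' intron; donor only; acceptor only; overlap without a shared junction; no
#' overlap.
#'
#' @param introns observed intron data frame.
#' @param annotated annotated intron data frame (same columns).
#' @return list with `matches` (introns plus `category`) and `counts`.
#' @export
match_to_annotation <- function(introns, annotated) {
  key <- function(d) paste(d$chrom, d$strand, d$start, d$end)
  donor_key <- function(d)
    paste(d$chrom, d$strand, ifelse(d$strand == "+", d$start, d$end))
  acc_key <- function(d)
    paste(d$chrom, d$strand, ifelse(d$strand == "+", d$end, d$start))
  both <- key(introns) %in% key(annotated)
  d5 <- donor_key(introns) %in% donor_key(annotated)
  d3 <- acc_key(introns) %in% acc_key(annotated)
  ovl <- rep(FALSE, nrow(introns))
  if (nrow(introns) && nrow(annotated)) {
    igr <- GenomicRanges::GRanges(introns$chrom,
      IRanges::IRanges(introns$start + 1L, introns$end),
      strand = introns$strand)
    agr <- GenomicRanges::GRanges(annotated$chrom,
      IRanges::IRanges(annotated$start + 1L, annotated$end),
      strand = annotated$strand)
    ovl[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(igr, agr)))] <- TRUE
  }
  category <- ifelse(both, "both_junctions",
               ifelse(d5, "five_prime_only",
                ifelse(d3, "three_prime_only",
                 ifelse(ovl, "overlap_no_junction", "no_overlap"))))
  introns$category <- category
  counts <- table(factor(category,
    levels = c("both_junctions", "five_prime_only", "three_prime_only",
               "overlap_no_junction", "no_overlap")))
  list(matches = introns, counts = counts)
}

#' Classify an intron's relation to annotated loci
#'
#' Same-strand comparison. `contained`: intron within a locus;
#' `extends_5prime`/`extends_3prime`: one junction inside a locus, the other
#' beyond its 5'/3' edge (strand-aware); `spans_locus`: a locus entirely
#' inside the intron; `intergenic`: no same-strand overlap. One category per
#' intron, precedence contained > spans_locus > extends.
#'
#' @param introns intron data frame.
#' @param loci locus data frame.
#' @return character vector of categories, one per intron.
#' @export
classify_intron_vs_locus <- function(introns, loci) {
  n <- nrow(introns)
  out <- rep("intergenic", n)
  if (!n || !nrow(loci)) return(out)
  igr <- GenomicRanges::GRanges(introns$chrom,
    IRanges::IRanges(introns$start + 1L, introns$end),
    strand = introns$strand)
  lgr <- GenomicRanges::GRanges(loci$chrom,
    IRanges::IRanges(loci$start + 1L, loci$end), strand = loci$strand)
  ov <- GenomicRanges::findOverlaps(igr, lgr)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  rank <- c(contained = 1, spans_locus = 2, extends_5prime = 3,
            extends_3prime = 4, intergenic = 5)
  for (k in seq_along(q)) {
    i <- q[k]; l <- s[k]
    is0 <- introns$start[i]; ie <- introns$end[i]
    ls <- loci$start[l]; le <- loci$end[l]
    cat <- if (is0 >= ls && ie <= le) "contained"
      else if (is0 <= ls && ie >= le) "spans_locus"
      else {
        past_left <- is0 < ls            # extends past the genomic left edge
        if (introns$strand[i] == "+")
          if (past_left) "extends_5prime" else "extends_3prime"
        else
          if (past_left) "extends_3prime" else "extends_5prime"
      }
    if (rank[cat] < rank[out[i]]) out[i] <- cat
  }
  out
}

#' Group transcripts into transcript sets
#'
#' Single-linkage grouping of same-strand transcripts whose genomic spans
#' overlap by at least one base ("a common genomic locus"). A set is counted
#' as alternatively spliced iff it has more than one member.
#'
#' @param transcripts data frame `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @return list with `sets` (transcripts plus `set_id`), `n_sets`,
#'   `n_multi` and `frac_multi` (alternatively spliced transcript sets as a
#'   fraction of all sets).
#' @export
group_transcript_sets <- function(transcripts) {
  d <- transcripts[order(transcripts$chrom, transcripts$strand,
                         transcripts$start, transcripts$end), ]
  n <- nrow(d)
  if (!n) return(list(sets = d, n_sets = 0L, n_multi = 0L,
                      frac_multi = NaN))
  set <- integer(n)
  set[1] <- 1L
  maxend <- d$end[1]
  for (i in seq_len(n)[-1]) {
    new_group <- d$chrom[i] != d$chrom[i - 1] ||
      d$strand[i] != d$strand[i - 1] || d$start[i] >= maxend
    set[i] <- set[i - 1] + new_group
    maxend <- if (new_group) d$end[i] else max(maxend, d$end[i])
  }
  d$set_id <- set
  sizes <- table(set)
  list(sets = d[order(match(d$transcript_id, transcripts$transcript_id)), ],
       n_sets = length(sizes), n_multi = sum(sizes > 1),
       frac_multi = sum(sizes > 1) / length(sizes))
}

#' Detect exon-skipping patterns among the introns of a locus
#'
#' Reports every triple (L, s1, s2) in which two non-overlapping introns,
#' each strictly shorter than a longer intron L, share exactly one of L's
#' boundaries each (one the donor side, one the acceptor side). The genomic
#' region between s1 and s2 is the skipped exon.
#'
#' @param introns intron data frame for one chromosome/strand group (or any
#'   mixture; grouping is handled internally).
#' @return data frame of events: long/short intron coordinates and the
#'   skipped exon interval.
#' @export
detect_exon_skipping <- function(introns) {
  empty <- data.frame(chrom = character(), strand = character(),
                      long_start = integer(), long_end = integer(),
                      s1_start = integer(), s1_end = integer(),
                      s2_start = integer(), s2_end = integer(),
                      exon_start = integer(), exon_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(introns) < 3) return(empty)
  res <- list()
  grp <- split(introns, paste(introns$chrom, introns$strand))
  for (g in grp) {
    for (i in seq_len(nrow(g))) {
      L <- g[i, ]
      llen <- L$end - L$start
      left <- g[g$start == L$start & g$end < L$end &
                  (g$end - g$start) < llen, , drop = FALSE]
      right <- g[g$end == L$end & g$start > L$start &
                   (g$end - g$start) < llen, , drop = FALSE]
      if (!nrow(left) || !nrow(right)) next
      for (a in seq_len(nrow(left))) for (b in seq_len(nrow(right))) {
        if (left$end[a] < right$start[b]) {  # non-overlapping, exon >= 1 nt
          res[[length(res) + 1]] <- data.frame(
            chrom = L$chrom, strand = L$strand,
            long_start = L$start, long_end = L$end,
            s1_start = left$start[a], s1_end = left$end[a],
            s2_start = right$start[b], s2_end = right$end[b],
            exon_start = left$end[a], exon_end = right$start[b],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect intron retention within a transcript set
#'
#' Retention occurs when one member's exon fully contains another member's
#' intron. If the genome and the locus CDS are supplied, the retained coding
#' sequence is translated in the reading frame at the insertion point and
#' `premature_stop` reports whether a stop codon appears before the annotated
#' terminal codon; otherwise `premature_stop` is `NA`.
#'
#' @param exons exon data frame with a `transcript_id` column (one chain per
#'   transcript, same locus/strand).
#' @param genome optional named character vector of sequences.
#' @param cds optional CDS interval `c(start, end)` (0-based half-open,
#'   genomic) shared by the set.
#' @return data frame of events: retaining transcript, spliced transcript,
#'   retained intron coordinates, `premature_stop`.
#' @export
detect_intron_retention <- function(exons, genome = NULL, cds = NULL) {
  stopifnot("transcript_id" %in% names(exons))
  txs <- unique(exons$transcript_id)
  empty <- data.frame(retaining = character(), spliced = character(),
                      intron_start = integer(), intron_end = integer(),
                      premature_stop = logical(), stringsAsFactors = FALSE)
  if (length(txs) < 2) return(empty)
  intr <- annotated_introns(
    data.frame(locus_id = exons$transcript_id, chrom = exons$chrom,
               start = exons$start, end = exons$end, strand = exons$strand,
               stringsAsFactors = FALSE))
  if (!nrow(intr)) return(empty)
  res <- list()
  for (tx in txs) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    other <- intr[intr$locus_id != tx, , drop = FALSE]
    if (!nrow(other)) next
    for (k in seq_len(nrow(other))) {
      hit <- ex$start <= other$start[k] & ex$end >= other$end[k] &
        ex$chrom == other$chrom[k]
      if (any(hit)) {
        ps <- retention_premature_stop(
          exons[exons$transcript_id == other$locus_id[k], , drop = FALSE],
          other$start[k], other$end[k], genome, cds)
        res[[length(res) + 1]] <- data.frame(
          retaining = tx, spliced = other$locus_id[k],
          intron_start = other$start[k], intron_end = other$end[k],
          premature_stop = ps, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- unique(do.call(rbind, res))
  rownames(out) <- NULL
  out
}

# Translate the spliced CDS of `ex` (the transcript that removes the intron)
# with the intron re-inserted; premature iff an in-frame stop appears before
# the annotated terminal codon of the spliced form.
retention_premature_stop <- function(ex, int_start, int_end, genome, cds) {
  if (is.null(genome) || is.null(cds)) return(NA)
  ex <- ex[order(ex$start), , drop = FALSE]
  strand <- ex$strand[1]; ch <- ex$chrom[1]
  cs <- max(cds[1], min(ex$start)); ce <- min(cds[2], max(ex$end))
  piece <- function(s, e) substr(genome[[ch]], s + 1, e)
  coding <- function(with_intron) {
    segs <- character(0)
    for (i in seq_len(nrow(ex))) {
      s <- max(ex$start[i], cs); e <- min(ex$end[i], ce)
      if (e > s) segs <- c(segs, piece(s, e))
      # append the retained intron where it sits between exons i and i+1
      if (with_intron && i < nrow(ex) && ex$end[i] == int_start &&
          ex$start[i + 1] == int_end)
        segs <- c(segs, piece(int_start, int_end))
    }
    seq <- paste0(segs, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    seq
  }
  first_stop <- function(seq) {
    ncod <- nchar(seq) %/% 3
    if (ncod < 1) return(Inf)
    codons <- substring(seq, 3 * (seq_len(ncod) - 1) + 1, 3 * seq_len(ncod))
    w <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(w)) w[1] else Inf
  }
  spliced <- coding(FALSE)
  retained <- coding(TRUE)
  stop_spliced <- first_stop(spliced)      # annotated terminal codon index
  stop_retained <- first_stop(retained)
  if (!is.finite(stop_retained)) return(FALSE)
  # premature iff the retained form stops before reaching the position of
  # the annotated stop (which sits (intron length) nt later in the retained
  # sequence when the intron precedes it)
  annotated_nt <- if (is.finite(stop_spliced)) 3 * stop_spliced else
    nchar(spliced)
  intron_before <- if (strand == "+") {
    spliced5 <- sum(pmax(0, pmin(ex$end, int_start) -
                           pmax(ex$start, cs)))
    spliced5 < annotated_nt
  } else {
    spliced5 <- sum(pmax(0, pmin(ex$end, ce) - pmax(ex$start, int_end)))
    spliced5 < annotated_nt
  }
  expected_nt <- annotated_nt + if (intron_before) int_end - int_start else 0
  3 * stop_retained < expected_nt
}

#' Intron length summary
#'
#' Median and central 95% interval (linear-interpolation percentiles).
#'
#' @param lengths integer vector of intron lengths (>= 1 value).
#' @return list `median`, `ci95` (2.5 and 97.5 percentiles), `n`.
#' @export
intron_length_stats <- function(lengths) {
  stopifnot(length(lengths) >= 1)
  list(median = unname(median(lengths)),
       ci95 = unname(quantile(lengths, c(0.025, 0.975), type = 7)),
       n = length(lengths))
}
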