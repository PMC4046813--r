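#' Split a locus into strand-oriented thirds
#'
#' The genomic left/middle/right thirds map to the 5'/central/3' thirds
#' according to the locus strand (on `-` the left genomic third is the 3'
#' end). When the length is not divisible by 3 the remainder base(s) go to
#' the central third.
#'
#' @param locus one-row data frame (or list) with `start`, `end`, `strand`.
#' @return named list `five_prime`, `central`, `three_prime`, each
#'   `c(start =, end =)` 0-based half-open, or `NULL` (with attribute) when
#'   the locus is shorter than 3 nt.
#' @export
split_locus_thirds <- function(locus) {
  len <- locus$end - locus$start
  if (len < 3) return(structure(list(), insufficient = TRUE))
  side <- len %/% 3
  left <- c(start = locus$start, end = locus$start + side)
  mid <- c(start = locus$start + side, end = locus$end - side)
  right <- c(start = locus$end - side, end = locus$end)
  if (locus$strand == "+")
    list(five_prime = left, central = mid, three_prime = right)
  else
    list(five_prime = right, central = mid, three_prime = left)
}

#' Classify the positional bias of antisense counts
#'
#' Labels (thresholds strict): `five_prime` iff >40% of reads in the 5'
#' third and <10% in the 3' third; `three_prime` symmetric; `central` iff
#' >75% central; otherwise `unbiased`. Totals below `min_reads` are
#' `insufficient`.
#'
#' @param c5,cc,c3 antisense read counts in the 5', central and 3' thirds.
#' @param min_reads minimum total for a label (default 10; set 1 to label
#'   any locus with reads).
#' @return character label.
#' @export
classify_bias <- function(c5, cc, c3, min_reads = 10L) {
  total <- c5 + cc + c3
  if (total < min_reads || total == 0) return("insufficient")
  f5 <- c5 / total; fc <- cc / total; f3 <- c3 / total
  if (f5 > 0.40 && f3 < 0.10) "five_prime"
  else if (f3 > 0.40 && f5 < 0.10) "three_prime"
  else if (fc > 0.75) "central"
  else "unbiased"
}

#' Antisense positional profiles per locus
#'
#' Counts antisense reads in the strand-oriented thirds of each locus; a
#' read is assigned to the third containing its strand-oriented 5'-most base
#' within the locus, and classified with [classify_bias()].
#'
#' @param reads block-level read data frame.
#' @param loci locus data frame.
#' @param min_reads label floor passed to [classify_bias()].
#' @return data frame `locus_id`, `counts_5prime`, `counts_central`,
#'   `counts_3prime`, `total`, `bias`.
#' @export
antisense_profiles <- function(reads, loci, min_reads = 10L) {
  out <- data.frame(locus_id = loci$locus_id,
                    counts_5prime = 0L, counts_central = 0L,
                    counts_3prime = 0L, total = 0L,
                    bias = "insufficient", stringsAsFactors = FALSE)
  if (!nrow(loci)) return(out)
  if (nrow(reads)) {
    # collapse blocks to whole-read spans
    sp <- reads[order(reads$read_id, reads$start), ]
    firsts <- !duplicated(sp$read_id)
    span <- data.frame(read_id = sp$read_id[firsts],
                       chrom = sp$chrom[firsts], strand = sp$strand[firsts],
                       start = tapply(sp$start, sp$read_id, min)[
                         sp$read_id[firsts]],
                       end = tapply(sp$end, sp$read_id, max)[
                         sp$read_id[firsts]], stringsAsFactors = FALSE)
    rgr <- GenomicRanges::GRanges(span$chrom,
      IRanges::IRanges(span$start + 1L, span$end))
    lgr <- GenomicRanges::GRanges(loci$chrom,
      IRanges::IRanges(loci$start + 1L, loci$end))
    ov <- GenomicRanges::findOverlaps(rgr, lgr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    anti <- span$strand[q] != loci$strand[s]
    q <- q[anti]; s <- s[anti]
    if (length(q)) {
      for (k in seq_along(q)) {
        locus <- loci[s[k], ]
        thirds <- split_locus_thirds(locus)
        if (!length(thirds)) next
        # strand-oriented 5'-most base of the read, clamped into the locus
        p <- if (span$strand[q[k]] == "+") span$start[q[k]]
             else span$end[q[k]] - 1L
        p <- min(max(p, locus$start), locus$end - 1L)
        third <- names(thirds)[vapply(thirds, function(t)
          p >= t["start"] && p < t["end"], logical(1))][1]
        col <- c(five_prime = "counts_5prime", central = "counts_central",
                 three_prime = "counts_3prime")[third]
        out[[col]][s[k]] <- out[[col]][s[k]] + 1L
      }
    }
  }
  out$total <- out$counts_5prime + out$counts_central + out$counts_3prime
  short <- (loci$end - loci$start) < 3
  out$bias <- vapply(seq_len(nrow(out)), function(i)
    if (short[i]) "insufficient" else
      classify_bias(out$counts_5prime[i], out$counts_central[i],
                    out$counts_3prime[i], min_reads), character(1))
  out
}

#' Antisense summary across loci
#'
#' Counts per bias class plus the fraction of loci with at least one
#' antisense read and (if an expression table is given) the fraction with
#' antisense RPKM > 1.
#'
#' @param profiles output of [antisense_profiles()].
#' @param expression optional per-locus expression table with
#'   `rpkm_antisense`.
#' @return list `class_counts`, `frac_detected`, `frac_rpkm_gt1` (NA if no
#'   expression table).
#' @export
antisense_summary <- function(profiles, expression = NULL) {
  cc <- table(factor(profiles$bias,
    levels = c("five_prime", "central", "three_prime", "unbiased",
               "insufficient")))
  frac_rpkm <- if (!is.null(expression)) {
    r <- tapply(expression$rpkm_antisense, expression$locus_id, max)
    mean(r > 1)
  } else NA_real_
  list(class_counts = cc,
       frac_detected = mean(profiles$total >= 1),
       frac_rpkm_gt1 = frac_rpkm)
}
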