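#' Simulation configuration
#'
#' Parameters of the synthetic genome/read generator. Defaults emulate the
#' statistical structure of a compact fungal transcriptome as reported for
#' strand-specific and 5'-enriched libraries:
#'
#' * intron lengths: shifted lognormal `44 + Lognormal(log 15, 1.28)`
#'   truncated to `[10, 4000]` nt, matching a median of 59 nt with central
#'   95% approximately `[46, 228]`;
#' * splice-site class weights proportional to 21794 GT-AG : 428 AT-AC :
#'   414 GC-AG;
#' * long-tailed expression law (lognormal), the draw being the expected
#'   sense read count of a locus;
#' * 5' UTR lengths lognormal with median 93 nt, capped at 480 nt;
#' * TSS classes drawn with weights 4557:4637:8798 (tight, intermediate,
#'   diffuse); each class emits read heads from a mixture of sharp sub-peaks
#'   (individual spread `tss_subpeak_sigma`) at fixed offsets from the true
#'   TSS -- a single start for tight promoters, alternative starts 16 nt
#'   (intermediate) or 25 nt (diffuse) apart, mirroring the multi-peak shape
#'   of real diffuse TSS regions. Because the sharpness statistic mirrors
#'   the profile about its peak, the effective spread is the RMS deviation
#'   about the tallest sub-peak; at the default 200 read heads per TSS the
#'   analytic interval length `2 * 1.96 * rms / sqrt(n)` of the three classes
#'   (~0.4, ~3.2, 5.7-9.0 nt) falls inside the tight / intermediate /
#'   diffuse bands for every possible winning sub-peak, while each sub-peak
#'   still clears the 10-RH peak-depth filter;
#' * uniform per-base read-head background emulating partially degraded
#'   transcripts.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param n_chroms,chrom_length number and length (nt) of chromosomes.
#' @param n_genes number of genes to place (non-overlapping).
#' @param intron_shift,intron_meanlog,intron_sdlog,intron_min,intron_max
#'   shifted-lognormal intron length law and truncation bounds (nt).
#' @param introns_per_gene_mean Poisson mean of introns per gene.
#' @param exon_length_range uniform range of exon lengths (nt).
#' @param splice_class_weights probabilities over GT_AG, AT_AC, GC_AG.
#' @param expression_meanlog,expression_sdlog lognormal expression law;
#'   the per-locus draw is its expected sense read count.
#' @param read_length simulated read length (nt).
#' @param antisense_fraction expected antisense reads as a fraction of the
#'   locus expression draw.
#' @param antisense_bias one of `"none"`, `"5prime"`, `"central"`, `"3prime"`.
#' @param antisense_bias_strength probability mass placed on the biased third.
#' @param tss_class_weights probabilities over tight/intermediate/diffuse.
#' @param tss_offsets_by_class named list of sub-peak offsets (nt, relative
#'   to the true TSS) per class.
#' @param tss_subpeak_sigma spread (nt) of read heads around each sub-peak.
#' @param rh_per_tss read heads drawn per true TSS.
#' @param rh_background_rate per-base, per-strand uniform background
#'   read-head rate (degradation noise).
#' @param utr_meanlog,utr_sdlog,utr_min,utr_max lognormal 5' UTR length law
#'   and truncation (nt).
#' @param min_intergenic minimum gap between placed genes (nt); leaves room
#'   for the upstream TSS and promoter window.
#' @param motif,motif_plant_prob,motif_offset_law,motif_offset_mean,
#'   motif_offset_sd,motif_offset_range promoter-motif planting law; offsets
#'   are promoter coordinates relative to the TSS (position 0).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chroms = 2L, chrom_length = 300000L, n_genes = 60L,
    intron_shift = 44, intron_meanlog = log(15), intron_sdlog = 1.28,
    intron_min = 10L, intron_max = 4000L,
    introns_per_gene_mean = 2.3,
    exon_length_range = c(120L, 400L),
    splice_class_weights = c(GT_AG = 21794, AT_AC = 428, GC_AG = 414) / 22636,
    expression_meanlog = log(30), expression_sdlog = 1.2,
    read_length = 50L,
    antisense_fraction = 0.1,
    antisense_bias = c("3prime", "none", "5prime", "central"),
    antisense_bias_strength = 0.8,
    tss_class_weights = c(tight = 4557, intermediate = 4637,
                          diffuse = 8798) / 17992,
    tss_offsets_by_class = list(tight = 0L,
                                intermediate = c(-8L, 8L),
                                diffuse = c(-25L, 0L, 25L)),
    tss_subpeak_sigma = 1.5,
    rh_per_tss = 200L,
    rh_background_rate = 2e-05,
    utr_meanlog = log(93), utr_sdlog = 0.8, utr_min = 5L, utr_max = 480L,
    min_intergenic = 700L,
    motif = "CACGTG", motif_plant_prob = 0.5,
    motif_offset_law = c("normal", "uniform"),
    motif_offset_mean = -70, motif_offset_sd = 5,
    motif_offset_range = c(-120, -70)) {
  antisense_bias <- match.arg(antisense_bias)
  motif_offset_law <- match.arg(motif_offset_law)
  stopifnot(seed == as.integer(seed), n_chroms >= 1, chrom_length >= 1000,
            n_genes >= 0, intron_min >= 1, intron_max >= intron_min,
            length(splice_class_weights) == 3,
            all(splice_class_weights >= 0),
            antisense_fraction >= 0, antisense_bias_strength >= 0,
            antisense_bias_strength <= 1,
            tss_subpeak_sigma >= 0, rh_per_tss >= 1,
            rh_background_rate >= 0, min_intergenic >= 300)
  if (abs(sum(splice_class_weights) - 1) > 1e-8)
    stop("splice_class_weights must sum to 1")
  if (abs(sum(tss_class_weights) - 1) > 1e-8)
    stop("tss_class_weights must sum to 1")
  if (!setequal(names(tss_offsets_by_class),
                c("tight", "intermediate", "diffuse")))
    stop("tss_offsets_by_class must name tight, intermediate, diffuse")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

draw_intron_lengths <- function(n, cfg) {
  len <- round(cfg$intron_shift +
                 rlnorm(n, cfg$intron_meanlog, cfg$intron_sdlog))
  pmin(pmax(len, cfg$intron_min), cfg$intron_max)
}

draw_utr_lengths <- function(n, cfg) {
  len <- round(rlnorm(n, cfg$utr_meanlog, cfg$utr_sdlog))
  pmin(pmax(len, cfg$utr_min), cfg$utr_max)
}

splice_dinucs <- list(
  GT_AG = c(donor = "GT", acceptor = "AG"),
  AT_AC = c(donor = "AT", acceptor = "AC"),
  GC_AG = c(donor = "GC", acceptor = "AG"))

#' Simulate a genome with annotation and ground truth
#'
#' Places non-overlapping genes on both strands, draws intron lengths from
#' the configured law and writes junction dinucleotides (strand-corrected)
#' into the genome. Every planted entity is recorded in a truth table.
#'
#' @param config a [simulation_config()].
#' @return list with `bundle` (a [genome_bundle()]) and `truth`: a list of
#'   data frames `genes` (with true TSS position, class, sigma, UTR length
#'   and expression draw) and `introns` (with splice class).
#' @export
simulate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 11L, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    seqs <- lapply(chroms, function(ch)
      sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
    names(seqs) <- chroms
    genes <- list(); exons <- list(); introns <- list(); cds <- list()
    gid <- 0L
    margin <- 600L   # room upstream of the first gene for TSS + promoter
    ci <- 1L
    pos <- margin
    while (gid < config$n_genes) {
      n_int <- rpois(1, config$introns_per_gene_mean)
      ex_len <- round(runif(n_int + 1, config$exon_length_range[1],
                            config$exon_length_range[2]))
      in_len <- draw_intron_lengths(n_int, config)
      span <- sum(ex_len) + sum(in_len)
      gap <- round(runif(1, config$min_intergenic,
                         config$min_intergenic + 800))
      gstart <- pos + gap
      if (gstart + span > config$chrom_length - margin) {
        if (ci == config$n_chroms)
          stop("could not place all genes without overlap; ",
               "lower n_genes or increase chrom_length/n_chroms")
        ci <- ci + 1L
        pos <- margin
        next
      }
      gid <- gid + 1L
      id <- sprintf("SYNG%04d", gid)
      strand <- sample(c("+", "-"), 1)
      # exon/intron chain left to right in genomic coordinates
      widths <- as.vector(rbind(ex_len, c(in_len, NA)))
      widths <- widths[!is.na(widths)]
      bounds <- gstart + cumsum(c(0, widths))
      ex_i <- seq(1, length(widths), by = 2)
      exon_start <- bounds[ex_i]
      exon_end <- bounds[ex_i + 1]
      gend <- gstart + span
      if (n_int > 0) {
        in_i <- seq(2, length(widths), by = 2)
        int_start <- bounds[in_i]
        int_end <- bounds[in_i + 1]
        cls <- sample(names(splice_dinucs), n_int, replace = TRUE,
                      prob = config$splice_class_weights)
        for (k in seq_len(n_int)) {
          d <- splice_dinucs[[cls[k]]]
          don <- strsplit(d[["donor"]], "")[[1]]
          acc <- strsplit(d[["acceptor"]], "")[[1]]
          if (strand == "+") {
            seqs[[ci]][(int_start[k] + 1):(int_start[k] + 2)] <- don
            seqs[[ci]][(int_end[k] - 1):int_end[k]] <- acc
          } else {
            comp <- c(A = "T", C = "G", G = "C", T = "A")
            seqs[[ci]][(int_end[k] - 1):int_end[k]] <- rev(comp[don])
            seqs[[ci]][(int_start[k] + 1):(int_start[k] + 2)] <- rev(comp[acc])
          }
        }
        introns[[length(introns) + 1]] <- data.frame(
          locus_id = id, chrom = chroms[ci], strand = strand,
          start = int_start, end = int_end, splice_class = cls,
          length = int_end - int_start, stringsAsFactors = FALSE)
      }
      utr <- draw_utr_lengths(1, config)
      tss <- if (strand == "+") gstart - utr else gend - 1L + utr
      cls_tss <- sample(names(config$tss_offsets_by_class), 1,
                        prob = config$tss_class_weights[
                          names(config$tss_offsets_by_class)])
      genes[[gid]] <- data.frame(
        locus_id = id, chrom = chroms[ci], strand = strand,
        start = gstart, end = gend, tss = tss, tss_class = cls_tss,
        sigma = class_profile_sd(config, cls_tss), utr = utr,
        expression = rlnorm(1, config$expression_meanlog,
                            config$expression_sdlog),
        n_introns = n_int, stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(
        locus_id = id, chrom = chroms[ci], start = exon_start,
        end = exon_end, strand = strand, stringsAsFactors = FALSE)
      cds[[gid]] <- data.frame(locus_id = id, start = gstart, end = gend,
                               frame = 0L, stringsAsFactors = FALSE)
      pos <- gend
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      cbind(empty_loci()[0, ],
            data.frame(tss = integer(), tss_class = character(),
                       sigma = numeric(), utr = integer(),
                       expression = numeric(), n_introns = integer()))[0, ]
    exons_df <- if (length(exons)) do.call(rbind, exons) else empty_exons()
    introns_df <- if (length(introns)) do.call(rbind, introns) else
      data.frame(locus_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 splice_class = character(), length = integer(),
                 stringsAsFactors = FALSE)
    cds_df <- if (length(cds)) do.call(rbind, cds) else empty_cds()
    loci <- if (nrow(genes))
      data.frame(locus_id = genes$locus_id, chrom = genes$chrom,
                 start = genes$start, end = genes$end,
                 strand = genes$strand, kind = "protein_coding",
                 stringsAsFactors = FALSE) else empty_loci()
    sequences <- vapply(seqs, paste0, character(1), collapse = "")
    bundle <- genome_bundle(sequences,
                            list(loci = loci, exons = exons_df, cds = cds_df))
    rownames(genes) <- rownames(introns_df) <- NULL
    list(bundle = bundle,
         truth = list(genes = genes, introns = introns_df))
  })
}

#' Simulate stranded (spliced) reads
#'
#' Sense read counts per locus are Poisson with mean equal to the locus
#' expression draw; read positions are uniform on the mature (spliced)
#' transcript, so reads crossing a junction become multi-block spliced reads.
#' Antisense reads are single-block, placed with their strand-oriented
#' 5'-most base in the locus third selected by the configured bias.
#'
#' @param bundle,truth output of [simulate_genome_and_annotation()].
#' @param config the same [simulation_config()].
#' @return block-level read data frame (see [read_alignments()]).
#' @export
simulate_reads <- function(bundle, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- truth$genes
  if (!nrow(genes)) return(empty_reads())
  with_seed(config$seed + 22L, {
    out <- vector("list", nrow(genes) * 2)
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      ex <- bundle$exons[bundle$exons$locus_id == gene$locus_id, ,
                         drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      w <- ex$end - ex$start
      off <- cumsum(c(0, w))
      lt <- sum(w)
      rl <- min(config$read_length, lt)
      n_s <- rpois(1, gene$expression)
      if (n_s > 0) {
        a <- sample.int(lt - rl + 1L, n_s, replace = TRUE) - 1L
        b <- a + rl
        blocks <- list()
        for (j in seq_len(nrow(ex))) {
          hit <- which(off[j] < b & off[j] + w[j] > a)
          if (!length(hit)) next
          blocks[[j]] <- data.frame(
            read_id = sprintf("%s_s%d", gene$locus_id, hit),
            chrom = gene$chrom, strand = gene$strand,
            start = ex$start[j] + pmax(0L, a[hit] - off[j]),
            end = ex$start[j] + pmin(w[j], b[hit] - off[j]),
            block = j, stringsAsFactors = FALSE)
        }
        sense <- do.call(rbind, blocks)
        # renumber block indices per read 1..k
        sense <- sense[order(sense$read_id, sense$start), , drop = FALSE]
        sense$block <- as.integer(
          stats::ave(sense$start, sense$read_id, FUN = seq_along))
        out[[2 * g - 1]] <- sense
      }
      n_a <- rpois(1, gene$expression * config$antisense_fraction)
      if (n_a > 0) {
        thirds <- split_locus_thirds(gene)   # 5'/central/3', genomic coords
        p <- antisense_third_probs(config$antisense_bias,
                                   config$antisense_bias_strength)
        pick <- sample(c("five_prime", "central", "three_prime"), n_a,
                       replace = TRUE, prob = p)
        tstart <- vapply(pick, function(k) thirds[[k]]["start"], numeric(1))
        tend <- vapply(pick, function(k) thirds[[k]]["end"], numeric(1))
        anchor <- floor(runif(n_a, tstart, tend))  # 5'-most base of the read
        as_strand <- if (gene$strand == "+") "-" else "+"
        rl2 <- min(config$read_length, gene$end - gene$start)
        if (as_strand == "-") {   # 5'-most base is the genomic right end
          end <- anchor + 1L
          start <- pmax(gene$start, end - rl2)
        } else {
          start <- anchor
          end <- pmin(gene$end, start + rl2)
        }
        out[[2 * g]] <- data.frame(
          read_id = sprintf("%s_a%d", gene$locus_id, seq_len(n_a)),
          chrom = gene$chrom, strand = as_strand,
          start = as.integer(start), end = as.integer(end), block = 1L,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) return(empty_reads())
    rownames(res) <- NULL
    res
  })
}

antisense_third_probs <- function(bias, s) {
  switch(bias,
    none = c(1, 1, 1) / 3,
    `5prime` = c(s, (1 - s) * 0.75, (1 - s) * 0.25),
    central = c((1 - s) / 2, s, (1 - s) / 2),
    `3prime` = c((1 - s) * 0.25, (1 - s) * 0.75, s))
}

# overall positional sd of a class's read-head mixture profile
class_profile_sd <- function(config, cls) {
  off <- config$tss_offsets_by_class[[cls]]
  sqrt(mean(off^2) - mean(off)^2 + config$tss_subpeak_sigma^2)
}

#' Simulate 5' read-head profiles
#'
#' Read heads around each true TSS are discretized draws from the class's
#' sub-peak mixture: a sub-peak offset is picked uniformly, then normal
#' spread `tss_subpeak_sigma` is added. A uniform per-base background
#' emulates read heads from partially degraded transcripts.
#'
#' @inheritParams simulate_reads
#' @return read-head data frame `chrom`, `pos`, `strand`, `count`.
#' @export
simulate_readheads <- function(bundle, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- truth$genes
  with_seed(config$seed + 33L, {
    parts <- list()
    if (nrow(genes)) {
      n <- config$rh_per_tss
      pos <- unlist(lapply(seq_len(nrow(genes)), function(g) {
        off <- config$tss_offsets_by_class[[genes$tss_class[g]]]
        sub <- off[sample.int(length(off), n, replace = TRUE)]
        round(genes$tss[g] + sub + rnorm(n, 0, config$tss_subpeak_sigma))
      }))
      parts$tss <- data.frame(
        chrom = rep(genes$chrom, each = n),
        pos = pos,
        strand = rep(genes$strand, each = n), stringsAsFactors = FALSE)
    }
    if (config$rh_background_rate > 0) {
      for (ch in names(bundle$chrom_lengths)) {
        len <- bundle$chrom_lengths[[ch]]
        for (st in c("+", "-")) {
          nb <- rpois(1, config$rh_background_rate * len)
          if (nb > 0)
            parts[[paste0(ch, st)]] <- data.frame(
              chrom = ch, pos = sample.int(len, nb, replace = TRUE) - 1L,
              strand = st, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(parts)) return(empty_readheads())
    d <- do.call(rbind, parts)
    d$pos <- pmin(pmax(d$pos, 0L),
                  bundle$chrom_lengths[d$chrom] - 1L)
    agg <- aggregate(list(count = rep(1L, nrow(d))),
                     by = list(chrom = d$chrom, pos = d$pos,
                               strand = d$strand), FUN = sum)
    agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
    rownames(agg) <- NULL
    agg
  })
}

#' Plant a promoter motif upstream of true TSS
#'
#' Writes a concrete motif into the genome at a drawn promoter offset
#' (position 0 = TSS; negative = upstream, gene-oriented) for a configured
#' fraction of genes. Planting is strand-corrected: on minus-strand genes the
#' reverse complement is written so the gene-oriented promoter sequence
#' carries the motif verbatim.
#'
#' @inheritParams simulate_reads
#' @return list with modified `bundle` and `plants` data frame
#'   (locus_id, offset, genomic start).
#' @export
plant_promoter_motifs <- function(bundle, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  motif <- toupper(config$motif)
  if (grepl("[^ACGT]", motif))
    stop("planted motif must be a concrete ACGT string")
  m <- nchar(motif)
  lo <- -200; hi <- 24 - m + 1
  if (config$motif_offset_law == "uniform") {
    r <- config$motif_offset_range
    if (r[1] < lo || r[2] > hi)
      stop("motif offset range outside promoter window [-200, ",
           hi, "]")
  } else if (config$motif_offset_mean < lo ||
             config$motif_offset_mean > hi) {
    stop("motif offset mean outside promoter window")
  }
  genes <- truth$genes
  if (!nrow(genes))
    return(list(bundle = bundle,
                plants = data.frame(locus_id = character(),
                                    offset = integer(), gstart = integer())))
  with_seed(config$seed + 44L, {
    planted <- runif(nrow(genes)) < config$motif_plant_prob
    idx <- which(planted)
    offs <- if (config$motif_offset_law == "uniform")
      sample(seq(config$motif_offset_range[1], config$motif_offset_range[2]),
             length(idx), replace = TRUE)
    else
      pmin(pmax(round(rnorm(length(idx), config$motif_offset_mean,
                            config$motif_offset_sd)), lo), hi)
    seqs <- bundle$sequences
    gstarts <- integer(length(idx))
    for (k in seq_along(idx)) {
      gene <- genes[idx[k], ]
      if (gene$strand == "+") {
        gs <- gene$tss + offs[k]
        substr(seqs[[gene$chrom]], gs + 1, gs + m) <- motif
      } else {
        gs <- gene$tss - offs[k] - m + 1L
        substr(seqs[[gene$chrom]], gs + 1, gs + m) <- revcomp(motif)
      }
      gstarts[k] <- gs
    }
    newb <- genome_bundle(seqs, list(loci = bundle$loci,
                                     exons = bundle$exons, cds = bundle$cds))
    list(bundle = newb,
         plants = data.frame(locus_id = genes$locus_id[idx],
                             offset = offs, gstart = gstarts,
                             stringsAsFactors = FALSE))
  })
}
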