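test_that("intron extraction keys junctions exactly and counts support", {
  reads <- rbind(
    make_read("r1", blocks = list(c(0, 50), c(109, 150))),
    make_read("r2", blocks = list(c(10, 50), c(109, 160))),
    make_read("r3", blocks = list(c(20, 50), c(109, 170))),
    make_read("r4", blocks = list(c(20, 50), c(110, 170))),  # 1-nt shift
    make_read("r5", blocks = list(c(200, 260))))             # unspliced
  ic <- extract_introns(reads)
  expect_equal(nrow(ic), 2L)
  expect_equal(ic$support[ic$start == 50 & ic$end == 109], 3L)
  expect_equal(ic$support[ic$start == 50 & ic$end == 110], 1L)
  expect_equal(nrow(extract_introns(make_read("u", blocks = list(c(0, 50))))),
               0L)
})

test_that("intron length bounds from the mapping settings are applied", {
  reads <- rbind(
    make_read("short", blocks = list(c(0, 10), c(15, 30))),    # 5 nt gap
    make_read("long", blocks = list(c(100, 110), c(5000, 5020))),
    make_read("ok", blocks = list(c(200, 210), c(269, 290))))
  ic <- extract_introns(reads)
  expect_equal(nrow(ic), 1L)
  expect_equal(ic$length, 59L)
})

test_that("splice classes read strand-corrected dinucleotides", {
  #                 0123456789012345678
  genome <- c(chr1 = "AAGTAAGTCCCCTAGAAAA")
  intr <- data.frame(chrom = "chr1", strand = "+", start = 2L, end = 15L,
                     stringsAsFactors = FALSE)
  cls <- classify_splice_sites(intr, genome)
  expect_equal(cls$splice_class, "GT_AG")
  expect_equal(cls$donor2, "GT")
  # same interval on minus strand reads the reverse complement
  intr_m <- transform(intr, strand = "-")
  cls_m <- classify_splice_sites(intr_m, genome)
  expect_equal(cls_m$donor2, "CT")
  expect_equal(cls_m$splice_class, "other")
  # a genuine minus-strand GT..AG: genomic CT..AC
  genome2 <- c(chr1 = "AACTTTTTTTTACAAAA")
  intr2 <- data.frame(chrom = "chr1", strand = "-", start = 2L, end = 13L,
                      stringsAsFactors = FALSE)
  expect_equal(classify_splice_sites(intr2, genome2)$splice_class, "GT_AG")
  # AT-AC and other
  genome3 <- c(chr1 = "AAATTTTTTTTACAAAA")
  intr3 <- data.frame(chrom = "chr1", strand = "+", start = 2L, end = 13L,
                      stringsAsFactors = FALSE)
  expect_equal(classify_splice_sites(intr3, genome3)$splice_class, "AT_AC")
  genome4 <- c(chr1 = "AACCTTTTTTTAGAAAA")
  expect_equal(classify_splice_sites(intr3, genome4)$splice_class, "other")
})

test_that("contig-edge introns are classed other with a warning", {
  genome <- c(chr1 = "GTAAG")
  intr <- data.frame(chrom = "chr1", strand = "+", start = 0L, end = 10L,
                     stringsAsFactors = FALSE)
  expect_warning(cls <- classify_splice_sites(intr, genome), "edge")
  expect_equal(cls$splice_class, "other")
})

test_that("splice consensus tallies positional frequencies", {
  # two introns GTAAGT... / GTGAGT...: position 3 splits 50/50 A/G
  genome <- c(chr1 = paste0("CAG", "GTAAGT", "TTTTTTTT", "TAG",
                            "CAG", "GTGAGT", "TTTTTTTT", "TAG"))
  intr <- data.frame(chrom = "chr1", strand = "+", start = c(3L, 23L),
                     end = c(20L, 40L), stringsAsFactors = FALSE)
  cons <- splice_consensus(intr, genome, k = 6)
  expect_equal(unname(cons$donor["G", 1]), 100)
  expect_equal(unname(cons$donor["T", 2]), 100)
  expect_equal(unname(cons$donor["A", 3]), 50)
  expect_equal(unname(cons$donor["G", 3]), 50)
  expect_true(all(abs(colSums(cons$donor) - 100) < 1e-9))
  expect_equal(unname(cons$acceptor["G", 3]), 100)
  expect_equal(unname(cons$exon_upstream["A", 1]), 100)  # ..AG upstream
  expect_equal(unname(cons$exon_upstream["G", 2]), 100)
  # single intron: 100% of its own sequence everywhere
  c1 <- splice_consensus(intr[1, ], genome, k = 6)
  expect_true(all(c1$donor %in% c(0, 100)))
})

test_that("junction matching categories partition the input", {
  annotated <- data.frame(chrom = "chr1", strand = "+",
                          start = c(100L, 500L), end = c(160L, 559L),
                          stringsAsFactors = FALSE)
  obs <- data.frame(chrom = "chr1",
                    strand = c("+", "+", "+", "+", "-"),
                    start = c(100L, 100L, 90L, 120L, 100L),
                    end = c(160L, 170L, 160L, 140L, 160L),
                    stringsAsFactors = FALSE)
  m <- match_to_annotation(obs, annotated)
  expect_equal(m$matches$category,
               c("both_junctions", "five_prime_only", "three_prime_only",
                 "overlap_no_junction", "no_overlap"))
  expect_equal(sum(m$counts), nrow(obs))
  # strand-awareness: on '-' the donor is the interval end
  ann_m <- data.frame(chrom = "chr1", strand = "-", start = 200L, end = 260L,
                      stringsAsFactors = FALSE)
  obs_m <- data.frame(chrom = "chr1", strand = "-", start = 190L, end = 260L,
                      stringsAsFactors = FALSE)
  expect_equal(match_to_annotation(obs_m, ann_m)$matches$category,
               "five_prime_only")
})

test_that("intron-versus-locus relations are strand-aware", {
  loci <- make_loci(c("g_plus", "g_minus", "sno"),
                    start = c(1000, 3000, 5000),
                    end = c(2000, 4000, 5100),
                    strand = c("+", "-", "+"))
  intr <- data.frame(
    chrom = "chr1",
    strand = c("+", "+", "+", "-", "+", "+"),
    start = c(1200L, 900L, 1800L, 3800L, 4900L, 7000L),
    end = c(1300L, 1100L, 2100L, 4100L, 5200L, 7100L),
    stringsAsFactors = FALSE)
  rel <- classify_intron_vs_locus(intr, loci)
  expect_equal(rel, c("contained",        # inside gene body
                      "extends_5prime",   # past + gene left (5') edge
                      "extends_3prime",   # past + gene right (3') edge
                      "extends_5prime",   # past - gene right edge = its 5'
                      "spans_locus",      # encloses the snoRNA locus
                      "intergenic"))
  # partition: every intron gets exactly one label
  expect_equal(length(rel), nrow(intr))
})

test_that("transcript sets group by single-linkage same-strand overlap", {
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-"),
    start = c(0L, 80L, 500L, 0L),
    end = c(100L, 200L, 600L, 100L), stringsAsFactors = FALSE)
  g <- group_transcript_sets(tx)
  expect_equal(g$n_sets, 3L)
  expect_equal(g$n_multi, 1L)
  expect_equal(g$frac_multi, 1 / 3)
  # opposite strands at the same locus are distinct sets
  expect_false(g$sets$set_id[g$sets$transcript_id == "t1"] ==
                 g$sets$set_id[g$sets$transcript_id == "t4"])
  # chained overlap is transitive
  tx2 <- data.frame(transcript_id = c("a", "b", "c"), chrom = "chr1",
                    strand = "+", start = c(0L, 90L, 180L),
                    end = c(100L, 200L, 300L), stringsAsFactors = FALSE)
  expect_equal(group_transcript_sets(tx2)$n_sets, 1L)
})

test_that("exon skipping detection matches the constructed pattern", {
  intr <- data.frame(chrom = "c", strand = "+",
                     start = c(100L, 100L, 300L),
                     end = c(400L, 200L, 400L), stringsAsFactors = FALSE)
  ev <- detect_exon_skipping(intr)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$exon_start, ev$exon_end), c(200L, 300L))
  # overlapping short introns: no event
  intr_ov <- data.frame(chrom = "c", strand = "+",
                        start = c(100L, 100L, 250L),
                        end = c(400L, 300L, 400L), stringsAsFactors = FALSE)
  expect_equal(nrow(detect_exon_skipping(intr_ov)), 0L)
  # only one short intron: no event
  expect_equal(nrow(detect_exon_skipping(intr[1:2, ])), 0L)
})

test_that("exon skipping agrees with a brute-force triple loop", {
  oracle <- function(d) {
    hits <- 0
    n <- nrow(d)
    for (i in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == i || b == i || a == b) next
      L <- d[i, ]; s1 <- d[a, ]; s2 <- d[b, ]
      if (s1$start > s2$start) next         # count each pair once
      ok <- s1$start == L$start && s1$end < L$end &&
        (s1$end - s1$start) < (L$end - L$start) &&
        s2$end == L$end && s2$start > L$start &&
        (s2$end - s2$start) < (L$end - L$start) &&
        s1$end < s2$start
      hits <- hits + ok
    }
    hits
  }
  set.seed(77)
  for (rep in 1:40) {
    k <- sample(3:12, 1)
    start <- sample(0:300, k, replace = TRUE)
    len <- sample(c(10:50, 100, 200, 300), k, replace = TRUE)
    d <- unique(data.frame(chrom = "c", strand = "+", start = start,
                           end = start + len, stringsAsFactors = FALSE))
    expect_equal(nrow(detect_exon_skipping(d)), oracle(d))
  }
})

test_that("intron retention and premature stops follow the reading frame", {
  cds_body <- paste0(paste0(rep("GCT", 40), collapse = ""), "TAA")
  mk <- function(intron_seq) {
    g <- paste0(substr(cds_body, 1, 60), intron_seq,
                substr(cds_body, 61, nchar(cds_body)))
    list(genome = c(chr = g),
         exons = rbind(
           data.frame(transcript_id = "keep", chrom = "chr", strand = "+",
                      start = 0L, end = nchar(g), stringsAsFactors = FALSE),
           data.frame(transcript_id = "splice", chrom = "chr", strand = "+",
                      start = c(0L, 60L + nchar(intron_seq)),
                      end = c(60L, nchar(g)), stringsAsFactors = FALSE)),
         cds = c(0L, nchar(g)))
  }
  # 9-nt intron, no in-frame stop: retention without premature stop
  f1 <- mk("GTACTGCAG")
  ev1 <- detect_intron_retention(f1$exons, f1$genome, f1$cds)
  expect_equal(nrow(ev1), 1L)
  expect_false(ev1$premature_stop)
  # 9-nt intron carrying TAA in frame
  f2 <- mk("GTAAGTTAG")
  expect_true(detect_intron_retention(f2$exons, f2$genome, f2$cds)
              $premature_stop)
  # 59-nt intron: frameshift, a stop appears downstream almost surely
  set.seed(9)
  intr59 <- paste0("GT", paste0(sample(c("A", "C", "G", "T"), 55,
                                       replace = TRUE), collapse = ""), "AG")
  f3 <- mk(intr59)
  expect_true(detect_intron_retention(f3$exons, f3$genome, f3$cds)
              $premature_stop)
  # frame unknown: premature_stop is NA
  ev4 <- detect_intron_retention(f1$exons)
  expect_true(is.na(ev4$premature_stop))
})

test_that("intron length stats use linear-interpolation percentiles", {
  s <- intron_length_stats(59)
  expect_equal(s$median, 59)
  expect_equal(s$ci95, c(59, 59))
  s2 <- intron_length_stats(1:100)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$ci95, c(3.475, 97.525))
})

test_that("generator intron law recovers the configured median at scale", {
  cfg <- simulation_config(seed = 55)
  set.seed(100)
  lens <- tsskit:::draw_intron_lengths(5000, cfg)
  st <- intron_length_stats(lens)
  expect_lt(abs(st$median - 59), 2)
  expect_lt(abs(st$ci95[1] - 46), 4)
  expect_lt(abs(st$ci95[2] - 228) / 228, 0.15)
})

test_that("splice-class counts partition the intron total", {
  cfg <- simulation_config(seed = 56, n_genes = 30, n_chroms = 2)
  sim <- simulate_genome_and_annotation(cfg)
  reads <- simulate_reads(sim$bundle, sim$truth, cfg)
  intr <- extract_introns(reads)
  cls <- classify_splice_sites(intr, sim$bundle$sequences)
  tab <- table(factor(cls$splice_class,
                      levels = c("GT_AG", "AT_AC", "GC_AG", "other")))
  expect_equal(sum(tab), nrow(intr))
})
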