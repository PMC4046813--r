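test_that("promoter extraction is strand-corrected around the peak", {
  chr <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  genome <- c(chr1 = chr)
  plus <- extract_promoters(genome,
    data.frame(chrom = "chr1", strand = "+", peak = 1000L))
  expect_equal(plus$sequence, substr(chr, 801, 1025))   # genomic [800,1025)
  expect_equal(nchar(plus$sequence), 225L)
  expect_false(plus$truncated)
  minus <- extract_promoters(genome,
    data.frame(chrom = "chr1", strand = "-", peak = 1000L))
  expect_equal(minus$sequence,
               tsskit:::revcomp(substr(chr, 977, 1201))) # genomic [976,1201)
  # the base at promoter position 0 is the peak base (complemented on '-')
  expect_equal(substr(minus$sequence, 201, 201),
               tsskit:::revcomp(substr(chr, 1001, 1001)))
  near_edge <- extract_promoters(genome,
    data.frame(chrom = "chr1", strand = "+", peak = 50L))
  expect_true(near_edge$truncated)
  expect_equal(nchar(near_edge$sequence), 75L)
})

test_that("composition profiles normalise and find planted dinucleotides", {
  base_seq <- paste0(rep("G", 225), collapse = "")
  proms <- data.frame(sequence = rep(base_seq, 5), truncated = FALSE)
  # plant CA at promoter positions -1, 0 (string offsets 200, 201)
  substr(proms$sequence, 200, 201) <- "CA"
  cp <- composition_profiles(proms)
  expect_true(all(abs(colSums(cp$base) - 1) < 1e-12))
  expect_equal(unname(cp$base["C", "-1"]), 1)
  expect_equal(unname(cp$base["A", "0"]), 1)
  expect_equal(unname(cp$dinucleotide["CA", "-1"]), 1)
  expect_true(all(abs(colSums(cp$dinucleotide) - 1) < 1e-12))
  # uniform random sequences: all base frequencies near 0.25
  set.seed(19)
  rnd <- data.frame(sequence = random_dna(1000, 225), truncated = FALSE)
  cpr <- composition_profiles(rnd)
  expect_true(all(abs(cpr$base - 0.25) < 0.06))
})

test_that("IUPAC scanning matches degenerate patterns exactly", {
  expect_equal(scan_motif("GGTATAAGG", "TATAA")[[1]], 2L)
  expect_equal(scan_motif("AGATAA", "HGATAR")[[1]], 0L)
  expect_equal(scan_motif("GCGGGG", "SYGGGG")[[1]], 0L)
  expect_equal(scan_motif("AAAA", "N")[[1]], 0:3)
  expect_length(scan_motif("ACGT", "TATAA")[[1]], 0L)
  expect_error(scan_motif("ACGT", "AZ"), "IUPAC")
  # overlapping matches are all reported
  expect_equal(scan_motif("AAAA", "AA")[[1]], 0:2)
  # coordinate offset maps into promoter coordinates
  expect_equal(scan_motif("GGTATAAGG", "TATAA", coord_offset = -200L)[[1]],
               -198L)
})

test_that("palindromic motif hits mirror on the reverse complement", {
  set.seed(29)
  seqs <- random_dna(50, 100)
  rc <- tsskit:::revcomp(seqs)
  fwd <- scan_motif(seqs, "CACGTG")
  rev <- scan_motif(rc, "CACGTG")
  for (i in seq_along(seqs))
    expect_setequal(rev[[i]], sort(100 - 6 - fwd[[i]]))
})

test_that("Markov background training: homopolymer, uniform, normalisation", {
  bg_a <- train_markov_background(paste0(rep("A", 5000), collapse = ""),
                                  order = 3, pseudocount = 0.01)
  expect_gt(bg_a$trans["AAA", "A"], 0.999)
  expect_true(all(abs(rowSums(bg_a$trans) - 1) < 1e-12))
  set.seed(37)
  bg_u <- train_markov_background(random_dna(300, 400), order = 3)
  expect_true(all(abs(bg_u$trans - 0.25) < 0.05))
  expect_error(train_markov_background(character(0)), "empty")
})

test_that("expected counts match brute-force enumeration on short sequences", {
  brute_expected <- function(seqs, bg, motif) {
    ord <- bg$order
    words <- tsskit:::expand_iupac(motif)
    k <- nchar(motif)
    tot <- 0
    for (s in seqs) {
      L <- nchar(s)
      if (L < ord + k) next
      for (i in (ord + 1):(L - k + 1)) for (w in words) {
        p <- 1
        hist <- strsplit(substr(s, i - ord, i - 1), "")[[1]]
        wch <- strsplit(w, "")[[1]]
        for (j in seq_len(k)) {
          ctx <- paste0(c(hist, wch[seq_len(j - 1)]), collapse = "")
          ctx <- substr(ctx, nchar(ctx) - ord + 1, nchar(ctx))
          ri <- if (ord == 0) 1L else match(ctx, rownames(bg$trans))
          p <- p * bg$trans[ri, wch[j]]
        }
        tot <- tot + p
      }
    }
    tot
  }
  set.seed(43)
  seqs <- random_dna(6, 50)
  bg <- train_markov_background(random_dna(40, 300,
                                           prob = c(.3, .2, .2, .3)),
                                order = 3)
  for (motif in c("ACGT", "TTAGC", "CACGTG", "HGATAR", "SYGGGG")) {
    got <- motif_enrichment(motif, seqs, bg)
    expect_equal(got$expected, brute_expected(seqs, bg, motif),
                 tolerance = 1e-12)
  }
})

test_that("order-0 uniform background expected count has the closed form", {
  bg0 <- train_markov_background(
    paste0(rep("ACGT", 5000), collapse = ""), order = 0, pseudocount = 1e-9)
  L <- 50L
  got <- motif_enrichment("ACGT", paste0(rep("A", L), collapse = ""), bg0)
  expect_equal(got$expected, (L - 3) * 0.25^4, tolerance = 1e-6)
  # observed == expected gives z = 0
  me <- data.frame(observed = 4, expected = 4)
  expect_equal((me$observed - me$expected) / sqrt(me$expected), 0)
})

test_that("a planted motif is detected with a large positive z", {
  set.seed(47)
  proms <- random_dna(300, 225)
  plant <- sample(300, 150)
  substr(proms[plant], 131, 136) <- "CACGTG"   # offset -70
  bg <- train_markov_background(random_dna(200, 300), order = 3)
  z <- motif_enrichment("CACGTG", proms, bg)$z
  expect_gt(z, 10)
  # unplanted data: |z| small
  z0 <- motif_enrichment("CACGTG", random_dna(300, 225), bg)$z
  expect_lt(abs(z0), 4)
})

test_that("motif enumeration ranks a planted motif first", {
  set.seed(53)
  proms <- random_dna(200, 225)
  substr(proms[sample(200, 120)], 131, 136) <- "CACGTG"
  bg <- train_markov_background(random_dna(150, 300), order = 3)
  ranked <- enumerate_and_rank_motifs(proms, bg, lengths = 6,
                                      min_count = 5, top_k = 20)
  top <- ranked$motif[1]
  # the winner matches CACGTG (either exactly or as a degenerate cover)
  expect_true("CACGTG" %in% tsskit:::expand_iupac(top))
  expect_equal(nrow(enumerate_and_rank_motifs(character(0), bg, 6)), 0L)
})

test_that("redundancy reduction keeps disjoint motifs, drops covers", {
  set.seed(59)
  proms <- random_dna(150, 225)
  substr(proms[1:70], 131, 136) <- "CACGTG"
  substr(proms[81:150], 51, 56) <- "TTTAAA"
  bg <- train_markov_background(random_dna(150, 300), order = 3)
  ranked <- data.frame(motif = c("CACGTG", "CACGTG", "TTTAAA"),
                       length = 6,
                       observed = c(70, 70, 70), expected = c(1, 1, 1),
                       z = c(69, 68.5, 68), stringsAsFactors = FALSE)
  ranked$motif[2] <- "CACGTN"   # degenerate cover of the same hits
  red <- reduce_redundancy(ranked, proms)
  expect_true("CACGTG" %in% red$motif)
  expect_true("TTTAAA" %in% red$motif)
  expect_false("CACGTN" %in% red$motif)
  expect_equal(nrow(reduce_redundancy(ranked[0, ], proms)), 0L)
})

test_that("positional chi-squared obeys algebraic identities", {
  # all n hits in one of k equal bins: chisq = n (k - 1)
  pu <- positional_uniformity(rep(-195L, 40), window = c(-200L, -1L),
                              bin = 10L)
  expect_equal(pu$chisq, 40 * (20 - 1))
  expect_equal(pu$df, 19L)
  # perfectly uniform integer hits: chisq = 0
  hits_u <- rep(seq(-195, -5, by = 10), each = 2)
  pu0 <- positional_uniformity(hits_u, window = c(-200L, -1L), bin = 10L)
  expect_equal(pu0$chisq, 0)
  # matches a hand-rolled sum((O-E)^2/E) with width-scaled expectation
  set.seed(67)
  hits <- sample(-200:24, 400, replace = TRUE)
  pu2 <- positional_uniformity(hits)
  O <- pu2$bins$observed
  w <- pu2$bins$end - pu2$bins$start + 1
  E <- 400 * w / 225
  expect_equal(pu2$chisq, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_false(pu2$low_power)
  expect_true(positional_uniformity(c(-70L, -60L))$low_power)
  expect_error(positional_uniformity(100L), "window")
})

test_that("a positionally planted motif rejects uniformity", {
  set.seed(71)
  proms <- random_dna(300, 225)
  off <- sample(-45:-30, 300, replace = TRUE)
  substr(proms, off + 201, off + 205) <- "TATAA"
  hits <- unlist(scan_motif(proms, "TATAA", coord_offset = -200L))
  pu <- positional_uniformity(hits)
  expect_lt(pu$p_value, 0.01)
  hot <- pu$bins$observed[pu$bins$start >= -50 & pu$bins$end <= -21]
  expect_gt(sum(hot), 0.5 * pu$n)
})

test_that("conservation 2x2 chi-squared matches the closed form", {
  # diagonal table [[50,0],[0,50]]: chisq = 100
  up_a <- c(setNames(rep("AACACGTGAA", 50), paste0("a", 1:50)),
            setNames(rep("AAAAAAAAAA", 50), paste0("a", 51:100)))
  up_b <- c(setNames(rep("TTCACGTGTT", 50), paste0("b", 1:50)),
            setNames(rep("TTTTTTTTTT", 50), paste0("b", 51:100)))
  pairs <- data.frame(a = paste0("a", 1:100), b = paste0("b", 1:100))
  res <- conservation_test(pairs, up_a, up_b, "CACGTG")
  expect_equal(res$chisq, 100)
  expect_equal(unname(res$table[1, 1]), 50)
  # closed form n(ad-bc)^2 / row/col products on a random table
  closed <- function(a, b, c, d)
    (a + b + c + d) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$chisq, closed(50, 0, 0, 50))
  # independent margins: chisq ~ 0
  up_a2 <- setNames(c(rep("AACACGTGAA", 50), rep("AAAAAAAAAA", 50)),
                    paste0("a", 1:100))
  up_b2 <- setNames(rep(c("TTCACGTGTT", "TTTTTTTTTT"), 50),
                    paste0("b", 1:100))
  res2 <- conservation_test(pairs, up_a2, up_b2, "CACGTG")
  expect_lt(res2$chisq, 1e-9)
  # unresolvable pairs are dropped with a warning
  pairs_bad <- rbind(pairs, data.frame(a = "missing", b = "b1"))
  expect_warning(res3 <- conservation_test(pairs_bad, up_a, up_b, "CACGTG"),
                 "dropped")
  expect_equal(res3$n_dropped, 1L)
})

test_that("the known-motif panel scans without error", {
  seqs <- random_dna(5, 225)
  for (m in known_motif_panel())
    expect_type(scan_motif(seqs, m), "list")
})
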