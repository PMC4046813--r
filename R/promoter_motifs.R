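IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

check_iupac <- function(motif) {
  m <- strsplit(toupper(motif), "")[[1]]
  bad <- !(m %in% names(IUPAC_CODES))
  if (any(bad))
    stop("invalid IUPAC symbol(s): ", paste(unique(m[bad]), collapse = ", "))
  m
}

# expand an IUPAC motif to all matching concrete words
expand_iupac <- function(motif, max_words = 4096L) {
  m <- check_iupac(motif)
  n_words <- prod(lengths(IUPAC_CODES[m]))
  if (n_words > max_words)
    stop("motif expands to ", n_words, " words (cap ", max_words, ")")
  do.call(paste0, expand.grid(IUPAC_CODES[m], stringsAsFactors = FALSE))
}

#' Extract promoter sequences around TSS peaks
#'
#' The promoter covers positions -`up` .. +`down` relative to the TSS peak
#' (position 0 = the peak base), strand-corrected so the sequence reads 5'
#' to 3' toward the gene; minus-strand promoters are reverse-complemented.
#' Windows running off the contig are truncated and flagged (truncated
#' promoters are excluded from positional statistics downstream).
#'
#' @param genome named character vector of chromosome sequences.
#' @param regions TSS table with `chrom`, `strand`, `peak` (and optionally
#'   `locus_id`, `cls` carried through).
#' @param up,down bases upstream/downstream of the peak (defaults 200/24,
#'   giving 225-nt promoters).
#' @return data frame `chrom`, `strand`, `peak`, `sequence`, `truncated`
#'   plus any carried columns.
#' @export
extract_promoters <- function(genome, regions, up = 200L, down = 24L) {
  lens <- nchar(genome)
  n <- nrow(regions)
  seqs <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]; pk <- regions$peak[i]
    if (regions$strand[i] == "+") {
      lo <- pk - up; hi <- pk + down          # inclusive 0-based
    } else {
      lo <- pk - down; hi <- pk + up
    }
    clo <- max(lo, 0L); chi <- min(hi, lens[[ch]] - 1L)
    trunc[i] <- clo != lo || chi != hi
    s <- substr(genome[[ch]], clo + 1L, chi + 1L)
    if (regions$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  out <- regions[, intersect(c("chrom", "strand", "peak", "locus_id", "cls"),
                             names(regions)), drop = FALSE]
  out$sequence <- seqs
  out$truncated <- trunc
  rownames(out) <- NULL
  out
}

#' Per-position base and dinucleotide composition
#'
#' Positional frequencies over a set of equal-length promoter sequences.
#' Position labels run -`up` .. +`down` (dinucleotide at position p covers
#' the pair p, p+1).
#'
#' @param promoters data frame from [extract_promoters()]; truncated
#'   promoters are dropped.
#' @param up upstream extent used for position labels (default 200).
#' @return list with `base` (4 x L frequency matrix), `dinucleotide`
#'   (16 x L-1), `positions`, `n`.
#' @export
composition_profiles <- function(promoters, up = 200L) {
  seqs <- promoters$sequence[!promoters$truncated]
  stopifnot(length(seqs) >= 1, length(unique(nchar(seqs))) == 1)
  L <- nchar(seqs[1])
  m <- do.call(rbind, strsplit(seqs, ""))
  bases <- c("A", "C", "G", "T")
  base <- apply(m, 2, function(col)
    table(factor(col, levels = bases)) / length(col))
  dn <- sapply(seq_len(L - 1), function(p) {
    pair <- paste0(m[, p], m[, p + 1])
    table(factor(pair, levels = as.vector(outer(bases, bases, paste0)))) /
      nrow(m)
  })
  pos <- seq(-up, length.out = L)
  colnames(base) <- pos
  colnames(dn) <- pos[-L]
  list(base = base, dinucleotide = dn, positions = pos, n = length(seqs))
}

#' Scan sequences for an IUPAC motif
#'
#' Exact degenerate pattern matching on the given (sense) strand; matches may
#' overlap. Offsets are 0-based within each sequence plus `coord_offset`
#' (use `coord_offset = -200` for promoter coordinates).
#'
#' @param sequences character vector of DNA sequences.
#' @param motif IUPAC motif string.
#' @param coord_offset added to every match offset.
#' @return list of integer offset vectors, one per sequence.
#' @export
scan_motif <- function(sequences, motif, coord_offset = 0L) {
  check_iupac(motif)
  if (!length(sequences)) return(list())
  hits <- Biostrings::vmatchPattern(motif,
    Biostrings::DNAStringSet(sequences), fixed = "subject")
  lapply(hits, function(h) IRanges::start(h) - 1L + coord_offset)
}

#' Train a Markov background model
#'
#' Maximum-likelihood transition probabilities of order `order` with
#' pseudocount smoothing, estimated from a background sequence set (e.g. the
#' regions 300 bp upstream of every annotated translation start).
#'
#' @param sequences character vector of background sequences.
#' @param order Markov order (default 3).
#' @param pseudocount added to every (context, base) count (default 1).
#' @return object of class `markov_background`: list with `order`,
#'   `pseudocount` and `trans`, a 4^order x 4 row-stochastic matrix with
#'   rownames the contexts ("" row for order 0).
#' @export
train_markov_background <- function(sequences, order = 3L, pseudocount = 1) {
  if (!length(sequences) || all(nchar(sequences) == 0))
    stop("empty background set")
  stopifnot(order >= 0, pseudocount > 0)
  sset <- Biostrings::DNAStringSet(toupper(sequences))
  counts <- colSums(Biostrings::oligonucleotideFrequency(sset, order + 1L))
  kmers <- names(counts)
  ctx <- if (order == 0) rep("", length(kmers)) else
    substr(kmers, 1, order)
  last <- substr(kmers, order + 1L, order + 1L)
  contexts <- if (order == 0) "" else
    sort(unique(do.call(paste0, expand.grid(
      rep(list(c("A", "C", "G", "T")), order), stringsAsFactors = FALSE))))
  trans <- matrix(pseudocount, nrow = length(contexts), ncol = 4,
                  dimnames = list(contexts, c("A", "C", "G", "T")))
  ri <- match(ctx, contexts)
  cidx <- match(last, c("A", "C", "G", "T"))
  for (i in seq_along(kmers))
    trans[ri[i], cidx[i]] <- trans[ri[i], cidx[i]] + counts[i]
  trans <- trans / rowSums(trans)
  structure(list(order = order, pseudocount = pseudocount, trans = trans),
            class = "markov_background")
}

# encode sequences as integer vectors 0..3 (A,C,G,T), NA otherwise
encode_dna <- function(s) {
  m <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
  m
}

#' Expected counts of every k-word under the Markov background
#'
#' For each concrete word w of length `k`, the expected number of
#' occurrences across the sequence set: the sum over sequences and start
#' positions of the probability that the background model emits w given the
#' position-specific left context (the actual sequence bases before the
#' word start). Scanning starts at offset `order` within each sequence so a
#' full context always exists.
#'
#' @param sequences character vector (e.g. promoter sequences).
#' @param background a [train_markov_background()] model.
#' @param k word length.
#' @return named numeric vector of length 4^k (names = words).
#' @keywords internal
word_expected_table <- function(sequences, background, k) {
  ord <- background$order
  tr <- background$trans
  nw <- 4L^k
  h <- min(ord, k)        # word chars whose context reaches into the sequence
  npre <- 4L^h
  # S[p] = sum over sequences/positions of P(word starts with prefix p |
  # position-specific left context)
  S <- numeric(npre)
  for (s in sequences) {
    e <- encode_dna(s)
    L <- length(e)
    if (L < ord + k) next
    starts <- (ord + 1L):(L - k + 1L)   # 1-based word starts, full context
    # context-from-sequence encodings per word char j = 1..h
    cj <- vector("list", h)
    for (j in seq_len(h)) {
      m <- ord - j + 1L                 # sequence chars in char-j context
      acc <- rep(0L, length(starts)); ok <- rep(TRUE, length(starts))
      for (t in seq_len(m)) {
        b <- e[starts - m + t - 1L]
        ok <- ok & !is.na(b)
        acc <- acc * 4L + ifelse(is.na(b), 0L, b)
      }
      cj[[j]] <- list(acc = acc, ok = ok)
    }
    if (h == 0) { S <- S + length(starts); next }
    for (p0 in 0:(npre - 1L)) {
      dig <- integer(h); rest <- p0
      for (j in h:1) { dig[j] <- rest %% 4L; rest <- rest %/% 4L }
      pr <- rep(1, length(starts))
      prefval <- 0L
      for (j in seq_len(h)) {
        ctx <- cj[[j]]$acc * 4L^(j - 1L) + prefval
        pr <- pr * ifelse(cj[[j]]$ok, tr[ctx + 1L, dig[j] + 1L], 0)
        prefval <- prefval * 4L + dig[j]
      }
      S[p0 + 1L] <- S[p0 + 1L] + sum(pr)
    }
  }
  ids <- 0:(nw - 1L)
  expected <- S[(ids %/% 4L^(k - h)) + 1L]
  if (k > h) {
    # remaining chars: context lies fully inside the word
    for (j in (h + 1L):k) {
      ctx_id <- (ids %/% 4L^(k - j + 1L)) %% 4L^ord
      ch_id <- (ids %/% 4L^(k - j)) %% 4L
      expected <- expected * tr[cbind(ctx_id + 1L, ch_id + 1L)]
    }
  }
  names(expected) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  expected
}

# observed counts of all k-words starting at offset >= order
word_observed_table <- function(sequences, k, order) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  keep <- nchar(sequences) >= order + k
  if (!any(keep)) return(setNames(numeric(4^k), words))
  sub <- substring(sequences[keep], order + 1L)
  colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sub), k))
}

#' Enrichment of one motif against the Markov background
#'
#' `observed` is the exact-match count of the motif over all sequences
#' (scanning from offset `order` so observed and expected cover the same
#' positions); `expected` sums, over positions and over the concrete words
#' matching the motif, the Markov probability of emitting the word given the
#' position-specific context. The variance is approximated as Poisson
#' (`variance = expected`), so `z = (obs - exp) / sqrt(exp)`.
#'
#' @param motif IUPAC motif (length 6-10 typical, any length accepted).
#' @param promoters character vector of promoter sequences or a data frame
#'   from [extract_promoters()].
#' @param background a [train_markov_background()] model.
#' @return one-row data frame `motif`, `observed`, `expected`, `z`
#'   (`z = NA` flagged when `expected` is 0).
#' @export
motif_enrichment <- function(motif, promoters, background) {
  seqs <- promoter_seqs(promoters)
  k <- nchar(motif)
  words <- expand_iupac(motif)
  exp_tab <- word_expected_table(seqs, background, k)
  obs_tab <- word_observed_table(seqs, k, background$order)
  observed <- sum(obs_tab[words])
  expected <- sum(exp_tab[words])
  z <- if (expected > 0) (observed - expected) / sqrt(expected) else NA_real_
  data.frame(motif = toupper(motif), observed = observed,
             expected = expected, z = z, stringsAsFactors = FALSE)
}

promoter_seqs <- function(promoters) {
  if (is.data.frame(promoters)) toupper(promoters$sequence)
  else toupper(promoters)
}

#' Enumerate and rank motifs by enrichment Z-score
#'
#' For each length, every concrete word present in the promoters at least
#' `min_count` times is scored (count-based pruning: absent and rare words
#' are skipped); degenerate variants with up to `max_ambiguous` ambiguity
#' symbols from `ambiguity_alphabet` are then generated around the
#' `expand_top` best-scoring words and scored as the sums of their matching
#' words. The top of the combined z-ranking is returned per length.
#'
#' @param promoters sequences or [extract_promoters()] data frame.
#' @param background a [train_markov_background()] model.
#' @param lengths motif lengths to enumerate (default 6:10).
#' @param max_ambiguous maximum ambiguous symbols per motif (default 2).
#' @param ambiguity_alphabet ambiguity symbols used (default R, Y, S, W, N).
#' @param min_count concrete words with fewer occurrences are skipped
#'   (default 5).
#' @param expand_top number of best concrete words seeding degenerate
#'   variants (default 200).
#' @param top_k motifs kept per length (default 50).
#' @return data frame `motif`, `length`, `observed`, `expected`, `z`,
#'   ranked by z within length.
#' @export
enumerate_and_rank_motifs <- function(promoters, background, lengths = 6:10,
                                      max_ambiguous = 2L,
                                      ambiguity_alphabet = c("R", "Y", "S",
                                                             "W", "N"),
                                      min_count = 5L, expand_top = 200L,
                                      top_k = 50L) {
  seqs <- promoter_seqs(promoters)
  if (!length(seqs))
    return(data.frame(motif = character(), length = integer(),
                      observed = numeric(), expected = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (k in lengths) {
    obs_tab <- word_observed_table(seqs, k, background$order)
    exp_tab <- word_expected_table(seqs, background, k)
    zw <- ifelse(exp_tab > 0, (obs_tab - exp_tab) / sqrt(exp_tab), NA_real_)
    present <- obs_tab >= min_count
    if (!any(present)) next
    d1 <- data.frame(motif = names(obs_tab)[present], length = k,
                     observed = unname(obs_tab[present]),
                     expected = unname(exp_tab[present]),
                     z = unname(zw[present]), stringsAsFactors = FALSE)
    seeds <- d1$motif[order(-d1$z)][seq_len(min(expand_top, nrow(d1)))]
    amb <- ambiguous_variants(seeds, max_ambiguous, ambiguity_alphabet)
    d2 <- NULL
    if (length(amb)) {
      stats <- vapply(amb, function(mt) {
        words <- expand_iupac(mt)
        c(sum(obs_tab[words]), sum(exp_tab[words]))
      }, numeric(2))
      d2 <- data.frame(motif = amb, length = k, observed = stats[1, ],
                       expected = stats[2, ],
                       z = ifelse(stats[2, ] > 0,
                                  (stats[1, ] - stats[2, ]) /
                                    sqrt(stats[2, ]), NA_real_),
                       stringsAsFactors = FALSE)
    }
    d <- rbind(d1, d2)
    d <- d[order(-d$z), , drop = FALSE]
    out[[as.character(k)]] <- head(d, top_k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# degenerate variants of concrete words: replace up to max_ambiguous
# positions by compatible codes from the alphabet
ambiguous_variants <- function(words, max_ambiguous, alphabet) {
  if (max_ambiguous < 1 || !length(words)) return(character(0))
  compat <- lapply(setNames(nm = c("A", "C", "G", "T")), function(b)
    alphabet[vapply(alphabet, function(a) b %in% IUPAC_CODES[[a]],
                    logical(1))])
  k <- nchar(words[1])
  res <- character(0)
  one_sub <- function(ws) {
    v <- character(0)
    for (p in seq_len(k)) {
      base_at <- substr(ws, p, p)
      for (b in c("A", "C", "G", "T")) {
        sel <- ws[base_at == b]
        if (!length(sel)) next
        for (code in compat[[b]]) {
          w2 <- sel
          substr(w2, p, p) <- code
          v <- c(v, w2)
        }
      }
    }
    unique(v)
  }
  lvl <- words
  for (a in seq_len(max_ambiguous)) {
    lvl <- one_sub(lvl)
    # keep only variants whose ambiguous-symbol count equals a (avoid
    # re-substituting the same position)
    n_amb <- nchar(gsub("[ACGT]", "", lvl))
    lvl <- unique(lvl[n_amb == a])
    res <- c(res, lvl)
  }
  unique(res)
}

#' Greedy redundancy reduction of a ranked motif list
#'
#' Keeps the best-z motif, then drops any lower-ranked motif whose set of
#' promoters with at least one hit overlaps a kept motif's hit set with
#' Jaccard index above `threshold`. At most `max_keep` motifs are kept per
#' length.
#'
#' @param ranked data frame from [enumerate_and_rank_motifs()].
#' @param promoters the promoter sequences used for the ranking.
#' @param threshold Jaccard cutoff (default 0.5).
#' @param max_keep per length (default 20).
#' @return the pruned subset of `ranked`.
#' @export
reduce_redundancy <- function(ranked, promoters, threshold = 0.5,
                              max_keep = 20L) {
  if (!nrow(ranked)) return(ranked)
  seqs <- promoter_seqs(promoters)
  keep <- logical(nrow(ranked))
  for (k in unique(ranked$length)) {
    idx <- which(ranked$length == k)
    idx <- idx[order(-ranked$z[idx])]
    kept_sets <- list()
    for (i in idx) {
      hits <- scan_motif(seqs, ranked$motif[i])
      set <- which(lengths(hits) > 0)
      if (!length(set)) next
      redundant <- any(vapply(kept_sets, function(ks)
        length(intersect(ks, set)) / length(union(ks, set)) > threshold,
        logical(1)))
      if (!redundant && length(kept_sets) < max_keep) {
        keep[i] <- TRUE
        kept_sets[[length(kept_sets) + 1]] <- set
      }
    }
  }
  out <- ranked[keep, , drop = FALSE]
  out[order(out$length, -out$z), , drop = FALSE]
}

#' Chi-squared test of positional uniformity of motif hits
#'
#' Bins hit start offsets in `bin`-nt windows tiling the promoter window
#' (the last bin may be short; expected counts scale with bin width) and
#' tests goodness of fit to a uniform distribution across the promoter.
#'
#' @param hits integer vector of hit start offsets in promoter coordinates.
#' @param window promoter coordinate range, inclusive (default c(-200, 24)).
#' @param bin bin width in nt (default 10).
#' @return list of class `positional_distribution`: `bins` (start, end,
#'   observed, expected), `chisq`, `df`, `p_value`, `n`, `low_power` (TRUE
#'   when n < 5 per bin on average).
#' @export
positional_uniformity <- function(hits, window = c(-200L, 24L), bin = 10L) {
  stopifnot(length(hits) >= 1)
  if (any(hits < window[1] | hits > window[2]))
    stop("hit offset outside the promoter window")
  starts <- seq(window[1], window[2], by = bin)
  ends <- pmin(starts + bin - 1L, window[2])
  width <- ends - starts + 1L
  obs <- vapply(seq_along(starts), function(i)
    sum(hits >= starts[i] & hits <= ends[i]), numeric(1))
  n <- length(hits)
  expd <- n * width / sum(width)
  chisq <- sum((obs - expd)^2 / expd)
  df <- length(starts) - 1L
  structure(list(bins = data.frame(start = starts, end = ends,
                                   observed = obs, expected = expd),
                 chisq = chisq, df = df,
                 p_value = pchisq(chisq, df, lower.tail = FALSE),
                 n = n, low_power = n < 5 * length(starts)),
            class = "positional_distribution")
}

#' Motif conservation across orthologue pairs
#'
#' Scores every orthologue pair for motif presence (>= 1 exact IUPAC match
#' in each species' upstream region), builds the 2x2 table (both / A only /
#' B only / neither) and tests independence by chi-squared; both the
#' uncorrected and the Yates-corrected statistics are reported.
#'
#' @param pairs two-column data frame of gene ids (species A, species B).
#' @param upstream_a,upstream_b named character vectors of upstream
#'   sequences keyed by gene id.
#' @param motif IUPAC motif.
#' @return list of class `conservation_result`: `table` (2x2), `chisq`,
#'   `p_value` (uncorrected), `chisq_yates`, `p_value_yates`, `n_pairs`,
#'   `n_dropped`.
#' @export
conservation_test <- function(pairs, upstream_a, upstream_b, motif) {
  ok <- pairs[[1]] %in% names(upstream_a) & pairs[[2]] %in% names(upstream_b)
  if (any(!ok))
    warning(sum(!ok), " unresolvable pair(s) dropped")
  p <- pairs[ok, , drop = FALSE]
  in_a <- lengths(scan_motif(unname(upstream_a[p[[1]]]), motif)) > 0
  in_b <- lengths(scan_motif(unname(upstream_b[p[[2]]]), motif)) > 0
  tab <- table(factor(in_a, levels = c(TRUE, FALSE)),
               factor(in_b, levels = c(TRUE, FALSE)),
               dnn = c("A", "B"))
  plain <- suppressWarnings(chisq.test(tab, correct = FALSE))
  yates <- suppressWarnings(chisq.test(tab, correct = TRUE))
  structure(list(table = tab,
                 chisq = unname(plain$statistic),
                 p_value = plain$p.value,
                 chisq_yates = unname(yates$statistic),
                 p_value_yates = yates$p.value,
                 n_pairs = nrow(p), n_dropped = sum(!ok)),
            class = "conservation_result")
}

#' Reference panel of known fungal promoter motifs
#'
#' TATA box, CAT box, initiator, heat-shock element, carbon- and
#' nitrogen-regulatory motifs and the three positionally focused core
#' motifs recurrently found upstream of tight TSS.
#'
#' @return named character vector of IUPAC motifs.
#' @export
known_motif_panel <- function() {
  c(TATA_box = "TATAA", CAT_box = "CCAAT", initiator = "YYANWYY",
    heat_shock = "NGAANNTTCN", CreA = "SYGGGG", AreA = "HGATAR",
    core_CACGTG = "CACGTG", core_ACCGCC = "ACCGCC", core_CCTNAGG = "CCTNAGG")
}
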