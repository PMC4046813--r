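#' Extract read heads from stranded reads
#'
#' The read head (RH) is the base `offset` nt 5' of the read's 5'-most
#' aligned base (the offset accounts for a base trimmed during mapping):
#' on `+` the RH is `start - offset`, on `-` it is `(end - 1) + offset`.
#' Heads shifted off the contig are clamped to the edge with a warning.
#'
#' @param reads block-level read data frame.
#' @param offset signed shift toward the transcript 5' end (default 1).
#' @param chrom_lengths optional named lengths for clamping.
#' @return read-head data frame `chrom`, `pos`, `strand`, `count`.
#' @export
extract_readheads <- function(reads, offset = 1L, chrom_lengths = NULL) {
  if (!nrow(reads)) return(empty_readheads())
  sp <- reads[order(reads$read_id, reads$start), ]
  firsts <- !duplicated(sp$read_id)
  start5 <- tapply(sp$start, sp$read_id, min)
  end3 <- tapply(sp$end, sp$read_id, max)
  ids <- sp$read_id[firsts]
  d <- data.frame(chrom = sp$chrom[firsts], strand = sp$strand[firsts],
                  stringsAsFactors = FALSE)
  d$pos <- ifelse(d$strand == "+",
                  start5[ids] - offset, end3[ids] - 1L + offset)
  if (!is.null(chrom_lengths)) {
    hi <- chrom_lengths[d$chrom] - 1L
    if (any(d$pos < 0 | d$pos > hi)) {
      warning("read head(s) clamped to contig edge")
      d$pos <- pmin(pmax(d$pos, 0L), hi)
    }
  }
  agg <- aggregate(list(count = rep(1L, nrow(d))),
                   by = list(chrom = d$chrom, pos = d$pos,
                             strand = d$strand), FUN = sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
  rownames(agg) <- NULL
  agg
}

#' Call TSS regions from a read-head profile
#'
#' Greedy peak picking: repeatedly take the highest remaining RH position
#' with count >= `min_peak`, form the `window`-nt region centred on it
#' (truncated at contig edges), accept it iff the window holds at least
#' `min_total` remaining RH, then mask the window's positions. Equal-height
#' peaks are resolved toward the smaller coordinate; accepted regions never
#' share a base.
#'
#' @param profile read-head data frame `chrom`, `pos`, `strand`, `count`.
#' @param window region width in nt (odd; default 121).
#' @param min_total minimum RH within the window (default 50).
#' @param min_peak minimum RH at the peak itself (default 10).
#' @param chrom_lengths optional named lengths for edge truncation.
#' @return data frame `chrom`, `strand`, `start`, `end` (window, 0-based
#'   half-open), `peak`, `peak_height`, `n` (RH in window).
#' @export
call_tss_regions <- function(profile, window = 121L, min_total = 50L,
                             min_peak = 10L, chrom_lengths = NULL) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  out <- list()
  for (grp in split(profile, paste(profile$chrom, profile$strand))) {
    grp <- grp[order(grp$pos), ]
    pos <- grp$pos; cnt <- grp$count
    chlen <- if (!is.null(chrom_lengths)) chrom_lengths[[grp$chrom[1]]]
             else Inf
    alive <- rep(TRUE, length(pos))
    repeat {
      cand <- which(alive & cnt >= min_peak)
      if (!length(cand)) break
      pk <- cand[order(-cnt[cand], pos[cand])][1]
      lo <- max(pos[pk] - half, 0)
      hi <- min(pos[pk] + half, chlen - 1)
      inwin <- alive & pos >= lo & pos <= hi
      n <- sum(cnt[inwin])
      if (n >= min_total)
        out[[length(out) + 1]] <- data.frame(
          chrom = grp$chrom[1], strand = grp$strand[1],
          start = lo, end = hi + 1, peak = pos[pk],
          peak_height = cnt[pk], n = n, stringsAsFactors = FALSE)
      alive[inwin] <- FALSE
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), peak = integer(),
                      peak_height = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$strand, res$start), ]
  rownames(res) <- NULL
  res
}

#' Mirror-symmetrize a read-head profile about its peak
#'
#' `out[p] = in[p] + in[2*peak - p]`: the region is reversed around the peak
#' and added to the original, yielding an exactly symmetric distribution
#' with the same positional spread.
#'
#' @param counts named numeric vector: names are positions, values RH counts.
#' @param peak peak position (must lie in the region).
#' @return named numeric vector, symmetric about `peak`.
#' @export
mirror_profile <- function(counts, peak) {
  pos <- as.integer(names(counts))
  refl <- 2L * peak - pos
  allpos <- sort(unique(c(pos, refl)))
  orig <- setNames(rep(0, length(allpos)), allpos)
  orig[as.character(pos)] <- counts
  out <- orig[as.character(allpos)] + orig[as.character(2L * peak - allpos)]
  setNames(as.numeric(out), allpos)
}

#' Bootstrap confidence-interval length (CIL) of the mean RH position
#'
#' Draws `n_boot` resamples of size `n` from the symmetrized position
#' distribution and returns the length of the central `level` percentile
#' interval of the resample means. Distribution-free; deterministic under a
#' fixed seed. The analytic normal-theory counterpart is
#' `2 * z * sigma / sqrt(n)`.
#'
#' @param counts symmetrized profile (named numeric, see [mirror_profile()]).
#' @param n resample size: the original (unmirrored) RH total.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed recorded in the output.
#' @param statistic `"mean"` (default) or `"mode"` resample statistic; the
#'   mode variant is exploratory.
#' @return list of class `cil_estimate`: `cil`, `sigma` (sd of the
#'   symmetrized position distribution), `n`, `z`, `level`, `n_boot`, `seed`.
#' @export
bootstrap_cil <- function(counts, n, level = 0.95, n_boot = 2000L,
                          seed = 1L, statistic = c("mean", "mode")) {
  statistic <- match.arg(statistic)
  if (n < 2) stop("need n >= 2 read heads")
  stopifnot(length(counts) >= 1, all(counts >= 0), sum(counts) > 0)
  pos <- as.numeric(names(counts))
  prob <- counts / sum(counts)
  mu <- sum(pos * prob)
  sigma <- sqrt(sum(prob * (pos - mu)^2))
  z <- qnorm(1 - (1 - level) / 2)
  if (sigma == 0) {
    cil <- 0
  } else {
    stats_boot <- with_seed(seed, {
      idx <- matrix(sample.int(length(pos), n * n_boot, replace = TRUE,
                               prob = prob), nrow = n_boot)
      if (statistic == "mean") {
        rowMeans(matrix(pos[idx], nrow = n_boot))
      } else {
        apply(matrix(pos[idx], nrow = n_boot), 1, function(v) {
          t <- table(v); as.numeric(names(t)[which.max(t)])
        })
      }
    })
    qs <- quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                   type = 7)
    cil <- unname(diff(qs))
  }
  structure(list(cil = cil, sigma = sigma, n = n, z = z, level = level,
                 n_boot = n_boot, seed = seed, statistic = statistic),
            class = "cil_estimate")
}

#' Classify a TSS by its CIL
#'
#' `tight` (CIL <= 2), `intermediate` (2 < CIL <= 4), `diffuse` (CIL > 4);
#' the boundaries are inclusive downward.
#'
#' @param cil non-negative CIL value(s) in nt.
#' @return character vector of class labels.
#' @export
classify_tss <- function(cil) {
  if (any(cil < 0)) stop("CIL must be non-negative")
  ifelse(cil <= 2, "tight", ifelse(cil <= 4, "intermediate", "diffuse"))
}

#' Full TSS pipeline for one read-head table
#'
#' Calls TSS regions, mirror-symmetrizes each window about its peak,
#' bootstraps the CIL and classifies the region.
#'
#' @param rh read-head data frame.
#' @inheritParams call_tss_regions
#' @inheritParams bootstrap_cil
#' @return the region table with `cil` and `cls` columns.
#' @export
call_and_classify_tss <- function(rh, window = 121L, min_total = 50L,
                                  min_peak = 10L, chrom_lengths = NULL,
                                  level = 0.95, n_boot = 2000L, seed = 1L) {
  regions <- call_tss_regions(rh, window, min_total, min_peak, chrom_lengths)
  if (!nrow(regions)) {
    regions$cil <- numeric(0); regions$cls <- character(0)
    return(regions)
  }
  cil <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    w <- rh[rh$chrom == regions$chrom[i] & rh$strand == regions$strand[i] &
              rh$pos >= regions$start[i] & rh$pos < regions$end[i], ]
    sym <- mirror_profile(setNames(w$count, w$pos), regions$peak[i])
    cil[i] <- bootstrap_cil(sym, n = regions$n[i], level = level,
                            n_boot = n_boot,
                            seed = (seed + i) %% .Machine$integer.max)$cil
  }
  regions$cil <- cil
  regions$cls <- classify_tss(cil)
  regions
}

#' Link TSS regions to annotated genes
#'
#' A region links to a locus iff they share a strand and the peak lies within
#' `max_dist` nt upstream of the locus 5' end (`upstream_within_500` by
#' default); peaks inside a locus body are `internal`; the nearest eligible
#' locus wins. The UTR length is the distance from the peak to the locus 5'
#' end (the translation start when loci are annotated by CDS).
#'
#' @param regions TSS region table (needs `chrom`, `strand`, `peak`).
#' @param loci locus data frame.
#' @param max_dist maximum upstream distance (default 500).
#' @return the region table with `locus_id`, `relation`, `utr_length`.
#' @export
link_tss_to_genes <- function(regions, loci, max_dist = 500L) {
  n <- nrow(regions)
  regions$locus_id <- NA_character_
  regions$relation <- rep("unlinked", n)
  regions$utr_length <- NA_integer_
  for (i in seq_len(n)) {
    same <- loci$chrom == regions$chrom[i] & loci$strand == regions$strand[i]
    if (!any(same)) next
    l <- loci[same, ]
    pk <- regions$peak[i]
    inside <- pk >= l$start & pk < l$end
    d <- if (regions$strand[i] == "+") l$start - pk else pk - (l$end - 1L)
    elig <- d >= 1 & d <= max_dist
    if (any(elig)) {
      j <- which(elig)[which.min(d[elig])]
      regions$locus_id[i] <- l$locus_id[j]
      regions$relation[i] <- "upstream_within_500"
      regions$utr_length[i] <- d[j]
    } else if (any(inside)) {
      regions$locus_id[i] <- l$locus_id[which(inside)[1]]
      regions$relation[i] <- "internal"
    }
  }
  regions
}

#' 5' UTR length summary
#'
#' @param links output of [link_tss_to_genes()].
#' @return list `lengths`, `median`, `ci95`, `n` over regions linked
#'   upstream.
#' @export
utr_lengths <- function(links) {
  u <- links$utr_length[links$relation == "upstream_within_500"]
  list(lengths = u,
       median = if (length(u)) unname(median(u)) else NA_real_,
       ci95 = if (length(u)) unname(quantile(u, c(0.025, 0.975), type = 7))
              else c(NA_real_, NA_real_),
       n = length(u))
}
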