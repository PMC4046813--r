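# fixture builders shared across test files; everything is generated in code

make_loci <- function(ids, chrom = "chr1", start, end, strand,
                      kind = "protein_coding") {
  data.frame(locus_id = ids, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             stringsAsFactors = FALSE)
}

make_read <- function(id, chrom = "chr1", strand = "+", blocks) {
  # blocks: list of c(start, end)
  do.call(rbind, lapply(seq_along(blocks), function(i)
    data.frame(read_id = id, chrom = chrom, strand = strand,
               start = as.integer(blocks[[i]][1]),
               end = as.integer(blocks[[i]][2]), block = i,
               stringsAsFactors = FALSE)))
}

make_reads <- function(...) do.call(rbind, list(...))

# depth-vector -> coverage_track on a toy chromosome (strand +)
cov_from_depth <- function(depth, chrom = "chr1", strand = "+") {
  reads <- do.call(rbind, lapply(seq_along(depth), function(i) {
    if (depth[i] < 1) return(NULL)
    data.frame(read_id = paste0("d", i, "_", seq_len(depth[i])),
               chrom = chrom, strand = strand,
               start = i - 1L, end = i, block = 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(reads)) reads <- tsskit:::empty_reads()
  coverage_track(reads, stats::setNames(length(depth), chrom))
}

# discretized-normal read-head profile as a named weight vector
discnorm_profile <- function(n, sigma, centre = 0, span = ceiling(6 * sigma)) {
  pos <- seq(centre - span, centre + span)
  w <- n * (pnorm(pos + 0.5, centre, sigma) - pnorm(pos - 0.5, centre, sigma))
  w <- stats::setNames(w, pos)
  w[w > 0]
}

random_dna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
           collapse = ""), character(1))
}
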