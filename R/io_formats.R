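#' @import methods
#' @importFrom stats quantile rnorm rpois rbinom runif rlnorm pchisq qnorm
#'   chisq.test setNames aggregate median sd var
#' @importFrom utils read.table write.table head
NULL

# All internal coordinates are 0-based half-open (BED-native). GFF3/GTF
# coordinates (1-based inclusive) are converted at the I/O boundary and
# nowhere else.

#' Construct a genome bundle
#'
#' Bundles chromosome sequences with an annotation (loci, exons, CDS) and
#' validates that every locus lies within its chromosome.
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences; names are chromosome names and must be unique.
#' @param annotation list with elements `loci`, `exons`, `cds` as returned by
#'   [read_annotation()], or `NULL` for an annotation-free bundle.
#' @return object of class `genome_bundle`: list with `sequences` (named
#'   character), `loci`, `exons`, `cds` data frames and `chrom_lengths`.
#' @export
genome_bundle <- function(sequences, annotation = NULL) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  lens <- setNames(nchar(sequences), names(sequences))
  if (is.null(annotation)) {
    annotation <- list(loci = empty_loci(), exons = empty_exons(),
                       cds = empty_cds())
  }
  loci <- annotation$loci
  if (nrow(loci)) {
    bad <- !(loci$chrom %in% names(sequences)) |
      loci$start < 0 | loci$end > lens[loci$chrom]
    if (any(bad))
      stop("loci outside chromosome bounds: ",
           paste(loci$locus_id[bad], collapse = ", "))
  }
  validate_loci(loci, annotation$exons)
  structure(list(sequences = sequences, chrom_lengths = lens,
                 loci = loci, exons = annotation$exons,
                 cds = annotation$cds),
            class = "genome_bundle")
}

empty_loci <- function() {
  data.frame(locus_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), stringsAsFactors = FALSE)
}
empty_exons <- function() {
  data.frame(locus_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}
empty_cds <- function() {
  data.frame(locus_id = character(), start = integer(), end = integer(),
             frame = integer(), stringsAsFactors = FALSE)
}

validate_loci <- function(loci, exons) {
  if (nrow(loci) && any(loci$end <= loci$start))
    stop("locus with end <= start: ",
         paste(loci$locus_id[loci$end <= loci$start], collapse = ", "))
  if (!nrow(exons)) return(invisible(TRUE))
  ord <- order(exons$locus_id, exons$start)
  exons <- exons[ord, ]
  key <- match(exons$locus_id, loci$locus_id)
  if (anyNA(key)) stop("exon with unknown locus id")
  out <- exons$start < loci$start[key] | exons$end > loci$end[key]
  if (any(out))
    stop("exon outside its locus: ",
         paste(unique(exons$locus_id[out]), collapse = ", "))
  # disjoint within locus
  same <- exons$locus_id[-1] == exons$locus_id[-nrow(exons)]
  if (nrow(exons) > 1 && any(same & exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons within a locus")
  invisible(TRUE)
}

#' Read a genome FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), nm)
}

#' Write a genome FASTA file
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_genome <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 70L)
  invisible(path)
}

#' Read a GFF3/GTF annotation
#'
#' Accepts gene, exon and CDS features; exons may be parented on genes
#' directly or via mRNA/transcript features. GFF 1-based inclusive
#' coordinates are converted to internal 0-based half-open.
#'
#' @param path GFF3 or GTF file (format inferred by [rtracklayer::import()]).
#' @return list with data frames `loci` (locus_id, chrom, start, end, strand,
#'   kind), `exons` (locus_id, chrom, start, end, strand, ordered by start)
#'   and `cds` (locus_id, start, end, frame).
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("annotation parse error: ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_id <- function(i) {
    id <- if ("ID" %in% names(md)) as.character(md$ID[i]) else NA_character_
    if (all(is.na(id)) && "gene_id" %in% names(md))
      id <- as.character(md$gene_id[i])
    id
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(type == "gene" & strand == "*")) {
    warning("dropping unstranded gene records")
    keep <- !(type == "gene" & strand == "*")
    gr <- gr[keep]; md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    strand <- as.character(BiocGenerics::strand(gr))
  }
  gi <- which(type == "gene")
  kind <- if ("gene_biotype" %in% names(md)) {
    k <- as.character(md$gene_biotype[gi])
    k[is.na(k)] <- "protein_coding"
    k
  } else rep("protein_coding", length(gi))
  loci <- data.frame(
    locus_id = get_id(gi),
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    start = BiocGenerics::start(gr)[gi] - 1L,
    end = BiocGenerics::end(gr)[gi],
    strand = strand[gi], kind = kind, stringsAsFactors = FALSE)
  # map mRNA/transcript IDs to their gene parent so exons resolve either way
  parent_of <- character(0)
  tx <- which(type %in% c("mRNA", "transcript"))
  if (length(tx)) {
    tid <- get_id(tx)
    tpar <- parent_attr(md, tx)
    parent_of[tid] <- tpar
  }
  resolve_locus <- function(i) {
    p <- parent_attr(md, i)
    if (all(is.na(p)) && "gene_id" %in% names(md))
      p <- as.character(md$gene_id[i])
    up <- parent_of[p]
    ifelse(!is.na(up) & p %in% names(parent_of), unname(up), p)
  }
  ei <- which(type == "exon")
  exons <- data.frame(
    locus_id = resolve_locus(ei),
    chrom = as.character(GenomicRanges::seqnames(gr)[ei]),
    start = BiocGenerics::start(gr)[ei] - 1L,
    end = BiocGenerics::end(gr)[ei],
    strand = strand[ei], stringsAsFactors = FALSE)
  exons <- exons[order(exons$locus_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  ci <- which(type == "CDS")
  cds <- if (length(ci)) {
    ph <- if ("phase" %in% names(md)) suppressWarnings(
      as.integer(as.character(md$phase[ci]))) else rep(0L, length(ci))
    ph[is.na(ph)] <- 0L
    agg <- data.frame(locus_id = resolve_locus(ci),
                      start = BiocGenerics::start(gr)[ci] - 1L,
                      end = BiocGenerics::end(gr)[ci], frame = ph)
    # one CDS interval per locus: overall span, frame of first segment
    sp <- split(agg, agg$locus_id)
    do.call(rbind, lapply(sp, function(d) data.frame(
      locus_id = d$locus_id[1], start = min(d$start), end = max(d$end),
      frame = d$frame[which.min(d$start)], stringsAsFactors = FALSE)))
  } else empty_cds()
  rownames(cds) <- NULL
  validate_loci(loci, exons)
  list(loci = loci, exons = exons, cds = cds)
}

parent_attr <- function(md, i) {
  if ("Parent" %in% names(md)) {
    p <- md$Parent[i]
    if (methods::is(p, "CharacterList"))
      return(vapply(p, function(v) if (length(v)) v[[1]] else NA_character_,
                    character(1)))
    return(as.character(p))
  }
  rep(NA_character_, length(i))
}

#' Write an annotation as GFF3
#'
#' Inverse of [read_annotation()]: emits gene, exon and CDS features with
#' gene-parented exons. Internal 0-based half-open coordinates are converted
#' to GFF 1-based inclusive.
#'
#' @param annotation list with `loci`, `exons`, `cds` data frames.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  loci <- annotation$loci; exons <- annotation$exons; cds <- annotation$cds
  mk <- function(chrom, start, end, strand, type, id, parent, kind) {
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start + 1L, end), strand = strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- parent
    S4Vectors::mcols(gr)$gene_biotype <- kind
    gr
  }
  parts <- list()
  if (nrow(loci))
    parts$gene <- mk(loci$chrom, loci$start, loci$end, loci$strand, "gene",
                     loci$locus_id, NA_character_, loci$kind)
  if (nrow(exons))
    parts$exon <- mk(exons$chrom, exons$start, exons$end, exons$strand,
                     "exon", NA_character_, exons$locus_id, NA_character_)
  if (nrow(cds)) {
    key <- match(cds$locus_id, loci$locus_id)
    parts$cds <- mk(loci$chrom[key], cds$start, cds$end, loci$strand[key],
                    "CDS", NA_character_, cds$locus_id, NA_character_)
    S4Vectors::mcols(parts$cds)$phase <- cds$frame
  }
  gr <- do.call(c, unname(parts))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read spliced alignments from a BED12 file
#'
#' Blocks of each BED12 record become the aligned segments of a read; the gap
#' between consecutive blocks is a candidate intron. BED 0-based half-open
#' coordinates are kept as-is. Unstranded records are rejected with a warning
#' (the supported libraries are strand-specific).
#'
#' @param path BED12 (or BED6 for unspliced reads) file.
#' @return data frame with one row per block: `read_id`, `chrom`, `strand`,
#'   `start`, `end`, `block` (1-based index along the read).
#' @export
read_alignments <- function(path) {
  if (file.size(path) == 0) return(empty_reads())
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    warning(sum(strand == "*"), " unstranded read(s) rejected")
    gr <- gr[strand != "*"]
  }
  if (!length(gr)) return(empty_reads())
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("read", seq_along(gr))
  md <- S4Vectors::mcols(gr)
  if ("blocks" %in% names(md)) {
    bl <- md$blocks   # IRangesList, relative 1-based within the read
    nblk <- lengths(bl)
    ubl <- unlist(bl, use.names = FALSE)
    rs <- rep(BiocGenerics::start(gr) - 1L, nblk)  # read start, 0-based
    out <- data.frame(
      read_id = rep(nm, nblk),
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), nblk),
      strand = rep(as.character(BiocGenerics::strand(gr)), nblk),
      start = rs + BiocGenerics::start(ubl) - 1L,
      end = rs + BiocGenerics::end(ubl),
      block = unlist(lapply(nblk, seq_len)), stringsAsFactors = FALSE)
    ends <- rep(BiocGenerics::end(gr), nblk)
    if (any(out$end > ends))
      stop("inconsistent BED12 block fields (block beyond chromEnd)")
  } else {
    out <- data.frame(
      read_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      block = 1L, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

empty_reads <- function() {
  data.frame(read_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), block = integer(),
             stringsAsFactors = FALSE)
}

#' Write spliced alignments as BED12
#' @param reads block-level data frame as returned by [read_alignments()].
#' @param path output file.
#' @export
write_alignments <- function(reads, path) {
  if (!nrow(reads)) { file.create(path); return(invisible(path)) }
  sp <- split(reads[order(reads$read_id, reads$start), ], reads$read_id)
  grl <- lapply(sp, function(d) {
    GenomicRanges::GRanges(d$chrom[1],
      IRanges::IRanges(min(d$start) + 1L, max(d$end)), strand = d$strand[1],
      name = d$read_id[1],
      blocks = IRanges::IRangesList(
        IRanges::IRanges(d$start - min(d$start) + 1L, d$end - min(d$start))))
  })
  gr <- do.call(c, unname(grl))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a per-base read-head count table
#'
#' bedGraph-like TSV with columns chrom, pos0, pos1, strand, count; each row
#' covers the 0-based half-open interval `[pos0, pos1)` at a constant count.
#'
#' @param path TSV file (optional `#` header comment).
#' @return data frame `chrom`, `pos` (0-based base), `strand`, `count`,
#'   one row per base with count >= 1.
#' @export
read_readheads <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = c("chrom", "pos0", "pos1", "strand", "count"),
                  colClasses = c("character", "integer", "integer",
                                 "character", "integer"))
  if (!nrow(d)) return(empty_readheads())
  n <- d$pos1 - d$pos0
  if (any(n < 1)) stop("malformed read-head interval (pos1 <= pos0)")
  out <- data.frame(
    chrom = rep(d$chrom, n),
    pos = unlist(Map(seq.int, d$pos0, d$pos1 - 1L)),
    strand = rep(d$strand, n),
    count = rep(d$count, n), stringsAsFactors = FALSE)
  out[out$count > 0, , drop = FALSE]
}

empty_readheads <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             count = integer(), stringsAsFactors = FALSE)
}

#' Write a per-base read-head count table
#' @param rh data frame `chrom`, `pos`, `strand`, `count`.
#' @param path output file.
#' @export
write_readheads <- function(rh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos0\tpos1\tstrand\tcount", con)
  if (nrow(rh)) {
    d <- data.frame(rh$chrom, rh$pos, rh$pos + 1L, rh$strand, rh$count)
    write.table(d, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write genomic regions as GTF or BED
#'
#' Emits TSS regions, transfrags or any interval records. GTF output is
#' 1-based inclusive; BED stays 0-based half-open. Records falling outside
#' their chromosome are refused with a warning.
#'
#' @param records data frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `name`, `score`, `feature`.
#' @param path output file.
#' @param format `"gtf"` or `"bed"`.
#' @param chrom_lengths optional named lengths used to refuse out-of-bounds
#'   records.
#' @export
write_regions <- function(records, path, format = c("gtf", "bed"),
                          chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!is.null(chrom_lengths) && nrow(records)) {
    bad <- records$start < 0 |
      records$end > chrom_lengths[records$chrom] |
      !(records$chrom %in% names(chrom_lengths))
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      warning(sum(bad), " record(s) outside chromosome bounds refused")
      records <- records[!bad, , drop = FALSE]
    }
  }
  nm <- if ("name" %in% names(records)) records$name else
    paste0("region", seq_len(nrow(records)))
  sc <- if ("score" %in% names(records)) records$score else
    rep(0, nrow(records))
  ft <- if ("feature" %in% names(records)) records$feature else
    rep("region", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gtf") {
    writeLines("#tsskit regions", con)
    if (nrow(records)) {
      lines <- paste(records$chrom, "tsskit", ft,
                     records$start + 1L, records$end, sc, records$strand,
                     ".", sprintf('gene_id "%s"; transcript_id "%s";', nm, nm),
                     sep = "\t")
      writeLines(lines, con)
    }
  } else {
    writeLines("#tsskit regions", con)
    if (nrow(records)) {
      lines <- paste(records$chrom, records$start, records$end, nm, sc,
                     records$strand, sep = "\t")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read regions written by [write_regions()]
#' @param path file produced by [write_regions()].
#' @param format `"gtf"` or `"bed"`.
#' @return data frame `chrom`, `start`, `end`, `strand`, `name`, `score`
#'   in internal 0-based half-open coordinates.
#' @export
read_regions <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gtf") {
    data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.integer(vapply(f, `[`, "", 4)) - 1L,
      end = as.integer(vapply(f, `[`, "", 5)),
      strand = vapply(f, `[`, "", 7),
      name = sub('.*gene_id "([^"]*)".*', "\\1", vapply(f, `[`, "", 9)),
      score = suppressWarnings(as.numeric(vapply(f, `[`, "", 6))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.integer(vapply(f, `[`, "", 2)),
      end = as.integer(vapply(f, `[`, "", 3)),
      strand = vapply(f, `[`, "", 6),
      name = vapply(f, `[`, "", 4),
      score = suppressWarnings(as.numeric(vapply(f, `[`, "", 5))),
      stringsAsFactors = FALSE)
  }
}

# strand-aware reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run `expr` under a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
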