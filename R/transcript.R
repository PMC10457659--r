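#' Transcript model
#'
#' Exon/CDS structure of a single transcript, used to decide whether a read's
#' variants restore an intact protein. Exons and CDS bounds are genomic,
#' 0-based half-open; `cds_start`/`cds_end` delimit the coding sequence
#' *including* the stop codon, so the canonical translation ends with a stop.
#' Validation requires non-overlapping sorted exons, CDS inside the exon
#' union, canonical CDS length divisible by 3 and a terminal stop codon.
#'
#' @param gene gene symbol
#' @param chrom contig
#' @param strand `"+"` or `"-"`
#' @param exons data.frame with 0-based half-open `start`, `end`
#' @param cds_start,cds_end genomic CDS bounds (0-based half-open), stop codon
#'   included
#' @param genome_seq full contig sequence (character), used to derive the
#'   canonical protein and the genomic position of the canonical stop codon
#' @return an object of class `transcript_model` with derived
#'   `canonical_protein`, `canonical_stop_pos` (genomic position of the stop
#'   codon's first base in transcript orientation) and `canonical_cds_len`
#' @export
transcript_model <- function(gene, chrom, strand, exons, cds_start, cds_end,
                             genome_seq) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (nrow(exons) < 1L) stop("transcript needs at least one exon")
  if (any(exons$start >= exons$end)) stop("empty exon")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons overlap")
  covered <- any(exons$start <= cds_start & exons$end >= cds_start + 1L) &&
    any(exons$start <= cds_end - 1L & exons$end >= cds_end)
  if (!covered || cds_start >= cds_end)
    stop("CDS bounds must lie inside the exon union")

  tx <- structure(list(gene = gene, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start,
                       cds_end = cds_end),
                  class = "transcript_model")

  sp <- splice_cds(tx, genome_seq,
                   variants = data.frame(pos = integer(), ref = character(),
                                         alt = character()))
  n <- nchar(sp$seq)
  if (n %% 3L != 0L)
    stop("canonical CDS length is not divisible by 3")
  out <- translate_cds(sp$seq)
  if (!grepl("\\*$", out$aa_full) || out$premature_stop)
    stop("canonical CDS must end with its only stop codon")
  tx$canonical_protein <- out$protein
  tx$canonical_cds_len <- n
  tx$canonical_stop_pos <- sp$anchors[n - 2L]  # first base of the stop codon
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s %s(%s): %d exon(s), CDS %d-%d, protein %d aa>\n",
              x$gene, x$chrom, x$strand, nrow(x$exons), x$cds_start,
              x$cds_end, nchar(x$canonical_protein)))
  invisible(x)
}

#' Read a transcript model from TSV, GTF or GFF3
#'
#' The TSV format is a single-row, tab-separated table with columns
#' `gene`, `chrom`, `strand`, `exons` (1-based inclusive `"start-end;..."`),
#' `cds_start`, `cds_end` (1-based inclusive, stop codon included). GTF/GFF3
#' input (by file extension) must describe one transcript; its `exon`
#' features become the exon list and the span of its `CDS` features the CDS
#' bounds (extended by 3 nt to include the stop codon when a `stop_codon`
#' feature is present outside the CDS).
#'
#' @param path transcript file
#' @param genome_seq full contig sequence for the transcript's chromosome
#' @return a [transcript_model()]
#' @export
read_transcript <- function(path, genome_seq) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    ex <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    if (length(ex) < 1L || length(cds) < 1L)
      stop("GTF/GFF transcript must contain exon and CDS features")
    stopc <- gr[gr$type == "stop_codon"]
    cstart <- min(GenomicRanges::start(cds)) - 1L
    cend <- max(GenomicRanges::end(cds))
    if (length(stopc)) {
      cstart <- min(cstart, min(GenomicRanges::start(stopc)) - 1L)
      cend <- max(cend, max(GenomicRanges::end(stopc)))
    }
    gene <- if (!is.null(ex$gene_id)) ex$gene_id[1] else "gene"
    transcript_model(
      gene = gene,
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(BiocGenerics::strand(ex))[1],
      exons = data.frame(start = GenomicRanges::start(ex) - 1L,
                         end = GenomicRanges::end(ex)),
      cds_start = cstart, cds_end = cend, genome_seq = genome_seq)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "strand", "exons", "cds_start", "cds_end")
    if (!all(need %in% names(tab)) || nrow(tab) != 1L)
      stop("transcript TSV must have one row with columns: ",
           paste(need, collapse = ", "))
    pieces <- strsplit(strsplit(tab$exons, ";", fixed = TRUE)[[1]], "-",
                       fixed = TRUE)
    exons <- data.frame(
      start = vapply(pieces, function(p) as.integer(p[1]) - 1L, integer(1)),
      end = vapply(pieces, function(p) as.integer(p[2]), integer(1)))
    transcript_model(tab$gene, tab$chrom, tab$strand, exons,
                     cds_start = tab$cds_start - 1L, cds_end = tab$cds_end,
                     genome_seq = genome_seq)
  }
}

#' Write a transcript model as the 6-column TSV
#' @param tx a [transcript_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_transcript_tsv <- function(tx, path) {
  exons <- paste(sprintf("%d-%d", tx$exons$start + 1L, tx$exons$end),
                 collapse = ";")
  tab <- data.frame(gene = tx$gene, chrom = tx$chrom, strand = tx$strand,
                    exons = exons, cds_start = tx$cds_start + 1L,
                    cds_end = tx$cds_end)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  paste(rev(REVCOMP[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Splice the CDS of `tx` out of `genome_seq`, applying `variants` (a
# data.frame of normalized genomic edits: 0-based `pos`, anchor-free
# `ref`/`alt`). Returns the realized CDS string plus a genomic anchor per
# base (NA for inserted bases). For minus-strand transcripts the sequence is
# reverse-complemented; anchors then run from high to low coordinates, and
# each anchor is the genomic position of the base itself.
splice_cds <- function(tx, genome_seq, variants) {
  if (nrow(variants) > 1L) {
    variants <- variants[order(variants$pos), , drop = FALSE]
    vend <- variants$pos + nchar(variants$ref)
    if (any(variants$pos[-1L] < vend[-nrow(variants)]))
      stop("overlapping variants")
  }
  exonic <- logical(nrow(variants))
  for (k in seq_len(nrow(variants))) {
    p <- variants$pos[k]; pe <- p + max(nchar(variants$ref[k]), 1L)
    exonic[k] <- any(tx$exons$start <= p & tx$exons$end >= pe)
  }
  if (any(!exonic)) {
    warning("variant(s) outside exons treated as non-coding and ignored")
    variants <- variants[exonic, , drop = FALSE]
  }

  chars <- character(0)
  anchors <- integer(0)
  for (k in seq_len(nrow(tx$exons))) {
    es <- tx$exons$start[k]; ee <- tx$exons$end[k]
    ex_chars <- strsplit(substr(genome_seq, es + 1L, ee), "", fixed = TRUE)[[1]]
    ex_anchor <- seq.int(es, ee - 1L)
    vv <- variants[variants$pos >= es & variants$pos < ee, , drop = FALSE]
    for (j in rev(seq_len(nrow(vv)))) {   # apply right-to-left: stable offsets
      off <- vv$pos[j] - es
      lr <- nchar(vv$ref[j]); la <- nchar(vv$alt[j])
      if (off + lr > length(ex_chars))
        stop("variant crosses an exon boundary; not supported")
      if (lr > 0L &&
          paste(ex_chars[off + seq_len(lr)], collapse = "") != vv$ref[j])
        stop("variant ref allele does not match the genome")
      ins_chars <- if (la > 0L) strsplit(vv$alt[j], "", fixed = TRUE)[[1]]
                   else character(0)
      left <- seq_len(off)
      right <- if (off + lr < length(ex_chars))
        (off + lr + 1L):length(ex_chars) else integer(0)
      ex_chars <- c(ex_chars[left], ins_chars, ex_chars[right])
      ex_anchor <- c(ex_anchor[left], rep(NA_integer_, la), ex_anchor[right])
    }
    chars <- c(chars, ex_chars)
    anchors <- c(anchors, ex_anchor)
  }

  if (tx$strand == "-") {
    chars <- rev(REVCOMP[chars])
    anchors <- rev(anchors)
  }

  # Restrict to the CDS: take the run between the first and last base whose
  # anchor lies inside [cds_start, cds_end); inserted (NA-anchored) bases in
  # between are retained.
  in_cds <- !is.na(anchors) & anchors >= tx$cds_start & anchors < tx$cds_end
  if (!any(in_cds)) stop("CDS entirely removed by variants; cannot translate")
  lo <- which(in_cds)[1L]
  hi <- which(in_cds)[sum(in_cds)]
  list(seq = paste(chars[lo:hi], collapse = ""),
       anchors = anchors[lo:hi])
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon. A
#' trailing partial codon (when the length is not a multiple of 3) is
#' ignored; `frame_intact` records whether the length was a multiple of 3.
#'
#' @param cds nucleotide string, starting at a codon boundary, length >= 3
#' @return list with `protein` (amino acids up to, excluding, the first
#'   stop), `premature_stop` (a stop occurs before the final codon),
#'   `stop_index` (1-based codon index of the first stop, NA if none),
#'   `frame_intact`, and `aa_full` (translation of every complete codon,
#'   stops as `*`)
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) stop("cds shorter than one codon")
  n_codon <- n %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  stop_index <- which(aa == "*")[1L]
  protein <- if (!is.na(stop_index))
    paste(aa[seq_len(stop_index - 1L)], collapse = "")
  else paste(aa, collapse = "")
  list(protein = protein,
       premature_stop = !is.na(stop_index) && stop_index < n_codon,
       stop_index = stop_index,
       frame_intact = n %% 3L == 0L,
       aa_full = paste(aa, collapse = ""))
}

#' Translate a transcript rewritten with observed variants
#'
#' Splices the transcript's exons out of the genome (reverse-complementing on
#' the minus strand), applies the variants in genomic order, translates the
#' realized coding sequence, and compares the genomic position of the realized
#' stop codon with the canonical one. A read whose variants yield an intact
#' protein terminating at the canonical stop codon is a frame-restoring
#' (reversion) candidate. Any premature stop introduced upstream makes
#' `same_stop_as_canonical` false, which implicitly enforces that mutations
#' downstream of an introduced stop gain cannot revert.
#'
#' @param tx a [transcript_model()]
#' @param genome_seq full contig sequence
#' @param variants data.frame of normalized genomic edits (`pos` 0-based,
#'   anchor-free `ref`, `alt`); may have zero rows
#' @return a `protein_outcome` list: `protein`, `premature_stop`, `stop_pos`
#'   (genomic anchor of the first base of the realized stop codon, NA if
#'   none), `frame_intact` (net coding indel is 0 mod 3),
#'   `same_stop_as_canonical`
#' @export
translate_with_variants <- function(tx, genome_seq, variants = NULL) {
  if (is.null(variants))
    variants <- data.frame(pos = integer(), ref = character(),
                           alt = character(), stringsAsFactors = FALSE)
  sp <- splice_cds(tx, genome_seq, variants)
  n <- nchar(sp$seq)
  frame_intact <- (n %% 3L) == 0L
  out <- translate_cds(sp$seq)
  stop_pos <- NA_integer_
  if (!is.na(out$stop_index)) {
    first_base <- 3L * out$stop_index - 2L
    stop_pos <- sp$anchors[first_base]   # NA if the stop starts on an insertion
  }
  same_stop <- frame_intact && !is.na(out$stop_index) &&
    !is.na(stop_pos) && stop_pos == tx$canonical_stop_pos
  # "premature" = a stop realized strictly upstream (in transcript direction)
  # of the canonical stop codon.
  premature <- FALSE
  if (!is.na(out$stop_index) && !same_stop) {
    if (is.na(stop_pos)) premature <- TRUE
    else premature <- if (tx$strand == "+") stop_pos < tx$canonical_stop_pos
                      else stop_pos > tx$canonical_stop_pos
  }
  structure(list(protein = out$protein,
                 premature_stop = premature,
                 stop_pos = stop_pos,
                 frame_intact = frame_intact,
                 same_stop_as_canonical = same_stop),
            class = "protein_outcome")
}
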