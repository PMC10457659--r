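# In-memory builders shared across the suite. These avoid file I/O where the
# operation under test is pure computation.

# Build a reference_context directly from a window sequence and an
# anchor-free pathogenic edit at window-relative 0-based `e`.
toy_context <- function(ref_seq, e, ref, alt, min_homopolymer = 5L,
                        wstart = 0L, chrom = "chrT", contig_len = NULL) {
  maps <- revertscan:::build_coord_maps(nchar(ref_seq), e, nchar(ref),
                                        nchar(alt))
  anchor <- substr(ref_seq, e, e)        # base before the edit (may be "")
  pos1 <- wstart + e + 1L
  pv <- if (nzchar(ref) && nzchar(alt))
    pathogenic_variant(chrom, pos1, ref, alt)
  else pathogenic_variant(chrom, wstart + e, paste0(anchor, ref),
                          paste0(anchor, alt))
  structure(list(
    window = genomic_interval(chrom, wstart, wstart + nchar(ref_seq)),
    ref_seq = ref_seq,
    pers_seq = revertscan:::apply_edit_to_seq(ref_seq, e, ref, alt),
    ref2pers = maps$ref2pers, pers2ref = maps$pers2ref,
    variant = pv,
    edit = list(start = e, ref = ref, alt = alt),
    homopolymers = find_homopolymer_runs(ref_seq, min_homopolymer),
    contig_len = contig_len %||% (wstart + nchar(ref_seq))
  ), class = "reference_context")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small deterministic T-free coding body (no premature stop possible).
toy_body <- function(n_codons, cycle = c("GCA", "GAC", "CAG", "ACC",
                                         "GGA", "CCA")) {
  paste(rep(cycle, length.out = n_codons), collapse = "")
}

# A plus- or minus-strand single-exon toy transcript on a small contig.
# Returns list(contig, tx, cds_start, cds_end).
toy_gene <- function(strand = "+", n_codons = 40L, flank = 20L,
                     body = NULL) {
  if (is.null(body)) body <- toy_body(n_codons)
  gene <- paste0("ATG", body, "TAA")
  gg <- if (strand == "-") revertscan:::revcomp(gene) else gene
  contig <- paste0(strrep("ACGT", flank / 4L), gg, strrep("TTGG", flank / 4L))
  cds_start <- flank
  cds_end <- flank + nchar(gene)
  tx <- transcript_model("TOY", "chrT", strand,
                         data.frame(start = cds_start - 4L,
                                    end = cds_end + 4L),
                         cds_start, cds_end, contig)
  list(contig = contig, tx = tx, cds_start = cds_start, cds_end = cds_end)
}

# Write a one-contig FASTA and return its path.
write_toy_fasta <- function(contig, dir = tempfile(), chrom = "chrT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(contig, chrom)), path,
    width = 60L)
  path
}

# Tiny SAM writer for hand-built records.
write_toy_sam <- function(df, chrom, contig_len, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "reads.sam")
  revertscan:::write_sam(df, chrom, contig_len, path)
  path
}
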