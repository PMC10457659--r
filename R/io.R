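#' Load pathogenic variants from a VCF file
#'
#' One [pathogenic_variant()] per record; multi-allelic records are split
#' into one variant per alternate allele. Symbolic alleles (`<DEL>`,
#' breakends, `*`) are rejected with a message.
#'
#' @param vcf_path VCF v4.x file (site-only or single-sample)
#' @return list of [pathogenic_variant()]
#' @export
load_pathogenic_variants <- function(vcf_path) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "custom")
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L) stop("no variant records in ", vcf_path)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  ids <- names(rr)
  out <- list()
  for (k in seq_along(rr)) {
    aa <- as.character(alts[[k]])
    for (j in seq_along(aa)) {
      a <- aa[j]
      if (grepl("<", a, fixed = TRUE) || grepl("[", a, fixed = TRUE) ||
          grepl("]", a, fixed = TRUE) || a == "*" || a == ".")
        stop(sprintf("symbolic/structural ALT allele '%s' at %s:%d not supported",
                     a, chroms[k], poss[k]))
      id <- if (!is.null(ids) && nzchar(ids[k]) && ids[k] != ".") ids[k]
            else NULL
      if (!is.null(id) && length(aa) > 1L) id <- sprintf("%s_alt%d", id, j)
      out[[length(out) + 1L]] <-
        pathogenic_variant(chroms[k], poss[k], refs[k], a, id = id)
    }
  }
  out
}

#' Write pathogenic variants as a minimal VCF v4.2 file
#' @param variants list of [pathogenic_variant()]
#' @param path output file
#' @param contig_len optional named integer vector of contig lengths for the
#'   header
#' @return `path`, invisibly
#' @export
write_pathogenic_vcf <- function(variants, path, contig_len = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             "##source=revertscan")
  if (!is.null(contig_len))
    lines <- c(lines,
               sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_len), as.integer(contig_len)))
  lines <- c(lines, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (v in variants)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                              v$chrom, v$pos, v$id, v$ref, v$alt))
  writeLines(lines, path)
  invisible(path)
}

#' Fetch reads overlapping the alignment window
#'
#' Reads are loaded with Rsamtools (SAM text input is converted on the fly),
#' filtered on the duplicate flag and mapping quality, and shifted into
#' window-relative coordinates. Reads that are not fully contained in the
#' window are dropped (with a count reported via attribute `n_dropped`):
#' with the default 500 nt radius and short reads, every read covering the
#' pathogenic locus is fully contained.
#'
#' @param bam_path BAM (indexed or indexable) or SAM text file
#' @param ctx a [build_reference_context()] result
#' @param include_duplicates keep duplicate-flagged reads (default FALSE,
#'   mirroring duplicate marking upstream)
#' @param min_mapq minimum mapping quality (default 0: reversion-bearing
#'   reads may map poorly)
#' @return list of [alignment_record()], attributes `n_fetched`, `n_dropped`
#' @export
fetch_reads <- function(bam_path, ctx, include_duplicates = FALSE,
                        min_mapq = 0L) {
  if (grepl("\\.sam$", bam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(bam_path, dest, overwrite = TRUE,
                                 indexDestination = TRUE)
  } else if (!file.exists(paste0(bam_path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    Rsamtools::indexBam(bam_path)
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (!(ctx$window$chrom %in% names(hdr)))
    stop(sprintf(
      "contig '%s' absent from BAM header (BAM contigs: %s); check that FASTA and BAM use the same naming",
      ctx$window$chrom, paste(names(hdr), collapse = ", ")))

  which <- GenomicRanges::GRanges(
    ctx$window$chrom,
    IRanges::IRanges(ctx$window$start + 1L, ctx$window$end))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(
    which = which, flag = flag,
    mapqFilter = if (min_mapq > 0L) as.integer(min_mapq) else NA_integer_,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1L]]

  n <- length(res$qname)
  out <- vector("list", n)
  kept <- 0L; dropped <- 0L
  for (k in seq_len(n)) {
    cig <- normalize_match_ops(parse_cigar(res$cigar[k]))
    rs <- res$pos[k] - 1L - ctx$window$start
    span <- sum(cig$len[cig$op %in% REF_OPS])
    if (rs < 0L || rs + span > nchar(ctx$ref_seq)) {
      dropped <- dropped + 1L
      next
    }
    fl <- res$flag[k]
    kept <- kept + 1L
    out[[kept]] <- alignment_record(
      read_id = res$qname[k],
      query = toupper(as.character(res$seq[k])),
      ref_start = rs,
      cigar = cig,
      quals = as.character(res$qual[k]),
      is_duplicate = bitwAnd(fl, 1024L) > 0L,
      is_reverse = bitwAnd(fl, 16L) > 0L,
      mapq = res$mapq[k])
  }
  out <- out[seq_len(kept)]
  attr(out, "n_fetched") <- n
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a reversion report to TSV files
#'
#' Emits `alleles.tsv` (one row per distinct reversion allele) and
#' `supporting_reads.tsv` (one row per allele/read pair) with bit-stable
#' column order and formatting (VAF to 4 decimals), the report of record for
#' a run.
#'
#' @param report a `reversion_report` from [run_pipeline()]
#' @param out_dir writable output directory (created if missing)
#' @return named character vector of the files written, invisibly
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  allele_path <- file.path(out_dir, "alleles.tsv")
  reads_path <- file.path(out_dir, "supporting_reads.tsv")

  header <- c("variant_id", "allele_key", "category", "n_support", "depth",
              "vaf", "net_indel", "frame_restored", "same_stop",
              "homopolymer_flag")
  rows <- vapply(report$alleles, function(a) {
    paste(c(report$variant$id, a$key, a$category, a$n_support,
            report$depth_at_variant, sprintf("%.4f", a$vaf), a$net_indel,
            a$frame_restored, a$same_stop, a$homopolymer_flag),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), allele_path)

  rrows <- unlist(lapply(report$alleles, function(a) {
    sprintf("%s\t%s", a$key, a$supporting_reads)
  }))
  writeLines(c("allele_key\tread_id", rrows), reads_path)

  invisible(c(alleles = allele_path, supporting_reads = reads_path))
}

#' Re-read an alleles.tsv written by [write_report()]
#' @param path path to `alleles.tsv`
#' @return data.frame
#' @export
read_allele_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(variant_id = "character",
                            allele_key = "character"))
}
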