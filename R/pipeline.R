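#' Pipeline run configuration
#'
#' Bundles all inputs and tunable parameters of a reversion-detection run.
#'
#' @param bam_path aligned reads (BAM, or SAM text for fixtures)
#' @param vcf_path pathogenic variant(s), VCF v4.x
#' @param fasta_path reference FASTA
#' @param transcript_path transcript model (TSV, GTF or GFF3; see
#'   [read_transcript()])
#' @param window_radius alignment window half-width, nt (default 500)
#' @param min_perfect minimum perfect-match run for soft-clip rescue
#'   (default 20)
#' @param min_homopolymer minimum homopolymer run length flagged (default 5)
#' @param scoring a [scoring_scheme()] (default indel-lenient)
#' @param include_duplicates keep duplicate-flagged reads (default FALSE)
#' @param min_mapq minimum mapping quality (default 0)
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes per-variant TSV reports there
#' @return an object of class `run_config`
#' @export
run_config <- function(bam_path, vcf_path, fasta_path, transcript_path,
                       window_radius = 500L, min_perfect = 20L,
                       min_homopolymer = 5L, scoring = default_scoring(),
                       include_duplicates = FALSE, min_mapq = 0L,
                       out_dir = NULL) {
  for (p in c(bam_path, vcf_path, fasta_path, transcript_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (window_radius < 1L || min_perfect < 1L || min_homopolymer < 2L)
    stop("numeric parameters out of range")
  structure(list(bam_path = bam_path, vcf_path = vcf_path,
                 fasta_path = fasta_path, transcript_path = transcript_path,
                 window_radius = as.integer(window_radius),
                 min_perfect = as.integer(min_perfect),
                 min_homopolymer = as.integer(min_homopolymer),
                 scoring = scoring,
                 include_duplicates = isTRUE(include_duplicates),
                 min_mapq = as.integer(min_mapq), out_dir = out_dir),
            class = "run_config")
}

# Does a finalized record's aligned span cover the pathogenic edit?
covers_pathogenic <- function(rec, ctx) {
  span <- record_ref_span(rec)
  e <- ctx$edit$start; lr <- nchar(ctx$edit$ref)
  if (lr == 0L)  # insertion point: must straddle the junction
    span[1L] <= e - 1L && span[2L] >= e + 1L
  else
    span[1L] <= e && span[2L] >= e + lr
}

#' Run the full reversion-detection pipeline
#'
#' For each pathogenic variant in the VCF: build the reference context,
#' fetch reads, rescue soft clips, realign against the personalized
#' reference, normalize indel placement, extract observed variants, assess
#' frame restoration per read, and aggregate candidate reads into distinct
#' reversion alleles. Fully deterministic: identical inputs give identical
#' reports.
#'
#' @param cfg a [run_config()]
#' @param keep_reads also return the finalized per-read records and
#'   assessments (default FALSE)
#' @param quiet suppress per-stage counters (default FALSE)
#' @return list of `reversion_report` objects, one per pathogenic variant
#' @export
run_pipeline <- function(cfg, keep_reads = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  variants <- load_pathogenic_variants(cfg$vcf_path)
  reports <- vector("list", length(variants))

  genomes <- list()
  for (vi in seq_along(variants)) {
    pv <- variants[[vi]]
    if (is.null(genomes[[pv$chrom]]))
      genomes[[pv$chrom]] <- read_fasta_contig(cfg$fasta_path, pv$chrom)
    genome_seq <- genomes[[pv$chrom]]
    tx <- read_transcript(cfg$transcript_path, genome_seq)

    ctx <- build_reference_context(cfg$fasta_path, pv,
                                   window_radius = cfg$window_radius,
                                   min_homopolymer = cfg$min_homopolymer)
    reads <- fetch_reads(cfg$bam_path, ctx,
                         include_duplicates = cfg$include_duplicates,
                         min_mapq = cfg$min_mapq)

    n_rescued <- 0L; n_realigned <- 0L; n_normalized <- 0L
    finalized <- vector("list", length(reads))
    assessments <- vector("list", length(reads))
    for (k in seq_along(reads)) {
      rec <- reads[[k]]
      rec <- rescue_soft_clips(rec, ctx, cfg$scoring, cfg$min_perfect)
      rec <- realign_over_pathogenic(rec, ctx, cfg$scoring)
      rec <- normalize_indel_placement(rec, ctx)
      if ("softclip_rescued" %in% rec$provenance) n_rescued <- n_rescued + 1L
      if ("realigned_personalized" %in% rec$provenance)
        n_realigned <- n_realigned + 1L
      if ("normalized" %in% rec$provenance) n_normalized <- n_normalized + 1L
      finalized[[k]] <- rec
      obs <- extract_observed_variants(rec, ctx)
      assessments[[k]] <- assess_read(rec$read_id, obs, ctx, tx, genome_seq)
    }

    covering <- vapply(finalized, function(r)
      !r$is_duplicate && covers_pathogenic(r, ctx), logical(1))
    depth <- sum(covering)
    non_dup <- vapply(finalized, function(r) !r$is_duplicate, logical(1))
    alleles <- if (depth >= 1L)
      aggregate_alleles(assessments[covering & non_dup], depth, ctx)
    else list()

    n_cand <- sum(vapply(assessments[covering & non_dup],
                         function(a) a$is_candidate_reversion, logical(1)))
    if (!quiet)
      message(sprintf(
        "[%s] reads=%d rescued=%d realigned=%d normalized=%d depth=%d candidates=%d alleles=%d",
        pv$id, length(reads), n_rescued, n_realigned, n_normalized, depth,
        n_cand, length(alleles)))

    rep <- structure(list(
      variant = pv, alleles = alleles,
      n_reads_processed = length(reads),
      n_reads_rescued = n_rescued,
      n_reads_realigned = n_realigned,
      n_reads_normalized = n_normalized,
      depth_at_variant = depth,
      n_candidate_reads = n_cand,
      ctx = ctx
    ), class = "reversion_report")
    if (keep_reads) {
      rep$records <- finalized
      rep$assessments <- assessments
    }

    if (!is.null(cfg$out_dir)) {
      vdir <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9._-]", "_", pv$id))
      write_report(rep, vdir)
      log_path <- file.path(vdir, "run.log")
      writeLines(sprintf(
        "variant=%s reads=%d rescued=%d realigned=%d normalized=%d depth=%d candidates=%d alleles=%d",
        pv$id, length(reads), n_rescued, n_realigned, n_normalized, depth,
        n_cand, length(alleles)), log_path)
    }
    reports[[vi]] <- rep
  }
  reports
}

#' @export
print.reversion_report <- function(x, ...) {
  cat(sprintf(
    "<reversion report for %s: %d reads, depth %d, %d allele(s)>\n",
    x$variant$id, x$n_reads_processed, x$depth_at_variant,
    length(x$alleles)))
  for (a in x$alleles) print(a)
  invisible(x)
}
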