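# Deterministic synthetic-data generator: FASTA + transcript + VCF + SAM +
# truth JSON with planted pathogenic and reversion alleles, so the whole
# pipeline is testable with no external data.
#
# The toy gene's coding body is built from T-free codons (alphabet A/C/G).
# Every stop codon contains a T, so no reading frame of the body can contain
# a premature stop: any variant set with net indel length 0 mod 3 restores
# the canonical stop, and any other net length loses it. This isolates the
# frame-restoration logic from incidental stop-gain effects; CDSs with
# engineered premature stops are exercised separately in unit tests.

TFREE_CODONS <- apply(expand.grid(c("A", "C", "G"), c("A", "C", "G"),
                                  c("A", "C", "G")), 1, paste, collapse = "")

#' Fixture specification
#'
#' Describes a synthetic dataset: a toy single-exon gene on contig `chrT`
#' with a pathogenic variant at its CDS midpoint, plus planted reversion
#' alleles. Defaults emulate the clinical setting: 150 nt reads, reversion
#' indels within ~100 nt of the pathogenic mutation, low VAFs set by the
#' per-allele read counts, substitution-only sequencing errors.
#'
#' @param seed RNG seed; same seed gives byte-identical fixture files
#' @param window_len approximate length of the gene body in nt (default
#'   1080)
#' @param pathogenic either `NULL` (default: a 2 nt frameshift deletion at
#'   the CDS midpoint) or a list `list(offset, type, len)` with `offset`
#'   relative to the midpoint and `type` in `DEL`/`INS`/`SNV`
#' @param planted_alleles list of alleles, each
#'   `list(variants = list(list(offset, type, len, seq)), n_reads, category)`;
#'   `offset` is relative to the pathogenic edit start, `seq` supplies INS/SNV
#'   alternate bases. `category` `"reversion_spanning_deletion"` plants the
#'   deletion on the reference haplotype (it removes the pathogenic span);
#'   all other categories plant on the pathogenic haplotype.
#' @param n_reference_reads,n_pathogenic_only_reads background read counts
#'   (defaults 30/30)
#' @param read_len read length (default 150)
#' @param dup_fraction fraction of reads emitted a second time with the
#'   duplicate flag set (default 0)
#' @param error_rate per-base substitution error probability (default 0;
#'   indel errors are deliberately excluded so the indel logic is tested
#'   free of noise-model confounds)
#' @param strand toy gene strand (default `"+"`; `"-"` builds a minus-strand
#'   gene for BRCA1-like testing)
#' @param min_flank minimum read anchor on each side of every planted indel
#'   junction (default 25 nt, comfortably above the default soft-clip rescue
#'   threshold so every planted read is in principle recoverable)
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, window_len = 1080L, pathogenic = NULL,
                         planted_alleles = list(), n_reference_reads = 30L,
                         n_pathogenic_only_reads = 30L, read_len = 150L,
                         dup_fraction = 0, error_rate = 0, strand = "+",
                         min_flank = 25L) {
  stopifnot(read_len <= window_len,
            dup_fraction >= 0, dup_fraction <= 1,
            error_rate >= 0, error_rate <= 1)
  strand <- match.arg(strand, c("+", "-"))
  structure(list(seed = as.integer(seed), window_len = as.integer(window_len),
                 pathogenic = pathogenic, planted_alleles = planted_alleles,
                 n_reference_reads = as.integer(n_reference_reads),
                 n_pathogenic_only_reads = as.integer(n_pathogenic_only_reads),
                 read_len = as.integer(read_len),
                 dup_fraction = dup_fraction, error_rate = error_rate,
                 strand = strand, min_flank = as.integer(min_flank)),
            class = "fixture_spec")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
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

# Write SAM records (data.frame: qname, flag, pos1, mapq, cigar, seq) sorted
# by coordinate; deterministic bytes.
write_sam <- function(recs, chrom, contig_len, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, contig_len))
  if (nrow(recs)) {
    recs <- recs[order(recs$pos1, recs$qname), , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                    recs$qname, recs$flag, chrom, recs$pos1, recs$mapq,
                    recs$cigar, recs$seq,
                    strrep("I", nchar(recs$seq)))
    writeLines(c(hdr, body), path)
  } else writeLines(hdr, path)
  invisible(path)
}

# Substitution errors at rate `rate`; alt base uniform over the other three.
add_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

# Emulate a general-purpose aligner: stringent, bwa-mem-like local SW
# against the plain reference contig. Ends crossing pathogenic indels come
# out as mismatches, short gaps or soft clips -- exactly the suboptimal
# placements the pipeline must repair.
naive_align_read <- function(seq, contig) {
  aln <- smith_waterman(seq, contig, naive_scoring())
  if (aln$score <= 0) return(NULL)
  lead <- aln$query_start
  trail <- nchar(seq) - aln$query_end
  cig <- merge_cigar_ops(c(lead, aln$cigar$len, trail),
                         c("S", aln$cigar$op, "S"))
  list(pos1 = aln$target_start + 1L, cigar = render_cigar(cig))
}

# Resolve a planted-variant spec (offset/type/len/seq) against the contig.
# Returns normalized genomic edit: list(pos, ref, alt).
resolve_planted_variant <- function(v, contig, e_g) {
  pos <- e_g + as.integer(v$offset)
  if (identical(v$type, "DEL")) {
    list(pos = pos, ref = substr(contig, pos + 1L, pos + v$len), alt = "")
  } else if (identical(v$type, "INS")) {
    stopifnot(nzchar(v$seq))
    list(pos = pos, ref = "", alt = v$seq)
  } else if (identical(v$type, "SNV")) {
    list(pos = pos, ref = substr(contig, pos + 1L, pos + 1L), alt = v$seq)
  } else stop("unknown planted variant type: ", v$type)
}

# Apply normalized genomic edits (list of list(pos, ref, alt)) to a contig;
# returns the haplotype string plus the haplotype position of each edit's
# junction point.
build_haplotype <- function(contig, edits) {
  if (!length(edits)) return(list(seq = contig, junctions = integer(0)))
  ord <- order(vapply(edits, `[[`, integer(1), "pos"))
  edits <- edits[ord]
  pos <- vapply(edits, `[[`, integer(1), "pos")
  ref <- vapply(edits, `[[`, character(1), "ref")
  alt <- vapply(edits, `[[`, character(1), "alt")
  if (any(pos[-1L] < (pos + nchar(ref))[-length(pos)]))
    stop("planted variants overlap")
  seq <- contig
  for (k in rev(seq_along(edits)))
    seq <- apply_edit_to_seq(seq, pos[k], ref[k], alt[k])
  shift <- cumsum(c(0L, (nchar(alt) - nchar(ref))[-length(pos)]))
  list(seq = seq, junctions = pos + shift)
}

# Sample `n` read start positions (0-based, on the haplotype) such that each
# read covers every junction with at least `flank` anchored bases.
sample_read_starts <- function(n, junctions, read_len, hap_len, flank) {
  lo <- max(0L, max(junctions) + flank - read_len)
  hi <- min(hap_len - read_len, min(junctions) - flank)
  if (hi < lo)
    stop("planted variants too far apart for the read length/flank")
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Generate a complete synthetic fixture
#'
#' Emits `ref.fa` (+ `.fai`), `transcript.tsv`, `pathogenic.vcf`,
#' `reads.sam` and `truth.json` under `out_dir`. Reads are given the
#' placements a stringent general-purpose aligner would produce (local
#' Smith-Waterman with bwa-mem-like scoring against the plain reference), so
#' reads whose ends cross the pathogenic deletion carry the classic
#' mismatch-plus-shifted-gap misalignments the realignment stages must
#' repair. Fully reproducible from `spec$seed`.
#'
#' @param spec a [fixture_spec()]
#' @param out_dir output directory (created if needed)
#' @return list with file `paths`, the `truth` list, and internal geometry
#'   (`contig`, `e_g`, pathogenic variant)
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, generate_fixture_impl(spec, out_dir))
}

generate_fixture_impl <- function(spec, out_dir) {
  chrom <- "chrT"
  flank_len <- 60L
  n_codons <- spec$window_len %/% 3L
  body <- paste(sample(TFREE_CODONS, n_codons, replace = TRUE),
                collapse = "")
  gene <- paste0("ATG", body, "TAA")
  if (spec$strand == "-") gene_genomic <- revcomp(gene) else gene_genomic <- gene
  contig <- paste0(
    paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
          collapse = ""),
    gene_genomic,
    paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
          collapse = ""))
  cds_start <- flank_len
  cds_end <- flank_len + nchar(gene)

  # pathogenic edit at (or near) the CDS midpoint, genomic coordinates
  mid <- cds_start + 3L * (n_codons %/% 2L)
  pspec <- spec$pathogenic
  if (is.null(pspec)) pspec <- list(offset = 0L, type = "DEL", len = 2L)
  p_pos <- mid + as.integer(pspec$offset %||% 0L)
  p_edit <- resolve_planted_variant(
    list(offset = p_pos - mid, type = pspec$type, len = pspec$len,
         seq = pspec$seq), contig, mid)
  e_g <- p_edit$pos

  # VCF (anchored) representation of the pathogenic edit
  if (nchar(p_edit$ref) == 0L || nchar(p_edit$alt) == 0L) {
    anchor <- substr(contig, e_g, e_g)
    pv <- pathogenic_variant(chrom, e_g, paste0(anchor, p_edit$ref),
                             paste0(anchor, p_edit$alt), id = "pathogenic1")
  } else {
    pv <- pathogenic_variant(chrom, e_g + 1L, p_edit$ref, p_edit$alt,
                             id = "pathogenic1")
  }

  exons <- data.frame(start = cds_start - 5L, end = cds_end + 5L)
  tx <- transcript_model("TOYGENE", chrom, spec$strand, exons,
                         cds_start, cds_end, contig)

  # --- reads ---------------------------------------------------------------
  read_len <- spec$read_len
  recs <- list()
  emit <- function(qname, seq, pos1, cigar, flag, mapq = 60L) {
    recs[[length(recs) + 1L]] <<- data.frame(
      qname = qname, flag = flag, pos1 = pos1, mapq = mapq,
      cigar = cigar, seq = seq, stringsAsFactors = FALSE)
  }
  sample_group <- function(prefix, n, hap, junctions, flank) {
    for (i in seq_len(n)) {
      start <- sample_read_starts(1L, junctions, read_len, nchar(hap$seq),
                                  flank)
      seq <- substr(hap$seq, start + 1L, start + read_len)
      seq <- add_read_errors(seq, spec$error_rate)
      aln <- naive_align_read(seq, contig)
      if (is.null(aln)) next
      flag <- if (runif(1) < 0.5) 16L else 0L
      emit(sprintf("%s_%04d", prefix, i), seq, aln$pos1, aln$cigar, flag)
    }
  }

  sample_group("ref", spec$n_reference_reads,
               list(seq = contig), e_g, flank = 10L)

  path_hap <- build_haplotype(contig, list(p_edit))
  sample_group("path", spec$n_pathogenic_only_reads, path_hap,
               path_hap$junctions, flank = 10L)

  truth_alleles <- list()
  for (ai in seq_along(spec$planted_alleles)) {
    al <- spec$planted_alleles[[ai]]
    sec <- lapply(al$variants, resolve_planted_variant, contig = contig,
                  e_g = e_g)
    spanning <- identical(al$category, "reversion_spanning_deletion")
    edits <- if (spanning) sec else c(list(p_edit), sec)
    hap <- build_haplotype(contig, edits)

    # construction check: the planted combination genuinely restores frame
    vdf <- data.frame(
      pos = vapply(edits, `[[`, integer(1), "pos"),
      ref = vapply(edits, `[[`, character(1), "ref"),
      alt = vapply(edits, `[[`, character(1), "alt"),
      stringsAsFactors = FALSE)
    out <- translate_with_variants(tx, contig, vdf)
    if (!out$same_stop_as_canonical)
      stop(sprintf("planted allele %d does not restore the reading frame", ai))

    key <- allele_truth_key(sec, contig)
    sample_group(sprintf("rev%02d", ai), al$n_reads, hap, hap$junctions,
                 flank = spec$min_flank)
    truth_alleles[[ai]] <- list(key = key, category = al$category,
                                n_support = al$n_reads)
  }

  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(qname = character(), flag = integer(), pos1 = integer(),
               mapq = integer(), cigar = character(), seq = character())

  # duplicate-flagged copies of a deterministic subset
  n_dup <- as.integer(floor(spec$dup_fraction * nrow(recs)))
  if (n_dup > 0L) {
    pick <- sample.int(nrow(recs), n_dup)
    dups <- recs[pick, , drop = FALSE]
    dups$qname <- paste0(dups$qname, ".dup")
    dups$flag <- bitwOr(dups$flag, 1024L)
    recs <- rbind(recs, dups)
  }

  depth <- as.integer(spec$n_reference_reads + spec$n_pathogenic_only_reads +
    sum(vapply(spec$planted_alleles, `[[`, numeric(1), "n_reads")))
  for (ai in seq_along(truth_alleles))
    truth_alleles[[ai]]$vaf <- truth_alleles[[ai]]$n_support / depth

  # --- files ---------------------------------------------------------------
  paths <- list(
    fasta = file.path(out_dir, "ref.fa"),
    transcript = file.path(out_dir, "transcript.tsv"),
    vcf = file.path(out_dir, "pathogenic.vcf"),
    sam = file.path(out_dir, "reads.sam"),
    truth = file.path(out_dir, "truth.json"))
  dna <- Biostrings::DNAStringSet(setNames(contig, chrom))
  Biostrings::writeXStringSet(dna, paths$fasta, width = 60L)
  Rsamtools::indexFa(paths$fasta)
  write_transcript_tsv(tx, paths$transcript)
  write_pathogenic_vcf(list(pv), paths$vcf,
                       contig_len = setNames(nchar(contig), chrom))
  write_sam(recs, chrom, nchar(contig), paths$sam)
  truth <- list(seed = spec$seed, pathogenic = list(
    chrom = chrom, pos = pv$pos, ref = pv$ref, alt = pv$alt, id = pv$id),
    depth = depth, alleles = truth_alleles)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  list(paths = paths, truth = truth, contig = contig, e_g = e_g,
       pathogenic = pv, transcript = tx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical demonstration fixture: ten low-VAF reversion alleles
#'
#' A [fixture_spec()] emulating the clinical picture of polyclonal reversion:
#' ten distinct alleles (frame-restoring secondary deletions of 1-13 nt,
#' insertions of 2-8 nt, and two spanning deletions that remove the
#' pathogenic span entirely) at 1-4.6% VAF over 1000x depth, with
#' substitution errors at 0.1% per base. Every planted combination nets to
#' an indel length of 0 mod 3.
#'
#' @param seed RNG seed (default 42)
#' @return a [fixture_spec()]
#' @export
demo_fixture_spec <- function(seed = 42L) {
  alleles <- list(
    list(variants = list(list(offset = 12L, type = "DEL", len = 1L)),
         n_reads = 10L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = 30L, type = "DEL", len = 4L)),
         n_reads = 14L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = -40L, type = "DEL", len = 7L)),
         n_reads = 18L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = 55L, type = "DEL", len = 10L)),
         n_reads = 22L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = -70L, type = "DEL", len = 13L)),
         n_reads = 26L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = 20L, type = "INS", seq = "CA")),
         n_reads = 30L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = -15L, type = "INS", seq = "GACCA")),
         n_reads = 34L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = 44L, type = "INS",
                              seq = "GACCAGCA")),
         n_reads = 38L, category = "reversion_secondary_indel"),
    list(variants = list(list(offset = -10L, type = "DEL", len = 33L)),
         n_reads = 42L, category = "reversion_spanning_deletion"),
    list(variants = list(list(offset = -25L, type = "DEL", len = 60L)),
         n_reads = 46L, category = "reversion_spanning_deletion"))
  fixture_spec(seed = seed, planted_alleles = alleles,
               n_reference_reads = 400L, n_pathogenic_only_reads = 320L,
               error_rate = 0.001)
}

# Canonical (left-aligned, 1-based genomic) key of a planted allele: must
# match the keys the pipeline reports.
allele_truth_key <- function(edits, contig) {
  parts <- vapply(edits, function(ed) {
    la <- left_align_edit(contig, ed$pos, ed$ref, ed$alt)
    sprintf("%d:%s>%s", la$start + 1L,
            if (nzchar(la$ref)) la$ref else "-",
            if (nzchar(la$alt)) la$alt else "-")
  }, character(1))
  ord <- order(as.integer(sub(":.*", "", parts)), parts)
  paste(parts[ord], collapse = ";")
}

#' Build the classic end-crossing misalignment worked example
#'
#' One 150 nt read over a germline 2 nt coding deletion plus an additional
#' 1 nt deletion, written with the suboptimal initial alignment
#' `10M1D140M` in which the germline deletion appears as one mismatched base
#' (in the first 10M) and a mis-placed single-base deletion. Running the
#' pipeline corrects the alignment to `4M2D6M1D140M`: three bases deleted in
#' total, restoring the reading frame. All bytes are deterministic (no RNG).
#'
#' @param out_dir output directory
#' @return list with file `paths`, the constructed read's true and initial
#'   CIGARs, and geometry (`s`, `e_g`, contig, pathogenic variant)
#' @export
make_fig1b_case <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chrom <- "chrT"
  flank_len <- 60L

  # deterministic T-free body from a fixed codon cycle
  cycle <- c("GCA", "GAC", "CAG", "ACC", "GGA", "CCA", "AGC", "CGA")
  n_codons <- 360L
  body <- paste(rep(cycle, length.out = n_codons), collapse = "")
  gene <- paste0("ATG", body, "TAA")
  contig <- paste0(strrep("ACGT", flank_len / 4L), gene,
                   strrep("TGCA", flank_len / 4L))
  cds_start <- flank_len
  cds_end <- flank_len + nchar(gene)

  # engineered segment: read span [s, s+153) on the reference
  s <- 599L
  seg <- paste0("CCGC",        # s+0 .. s+3
                "GAGAGACA",    # s+4 .. s+11 (germline GA deleted at s+4)
                "GC")          # s+12 (secondary 1 nt deletion), s+13
  stopifnot(nchar(seg) == 14L)
  contig <- paste0(substr(contig, 1L, s), seg,
                   substr(contig, s + nchar(seg) + 1L, nchar(contig)))
  stopifnot(nchar(contig) == flank_len * 2L + nchar(gene))

  # pathogenic: deletion of "GA" at s+4 (anchored VCF: POS = s+4 1-based)
  pv <- pathogenic_variant(chrom, s + 4L,
                           paste0("C", "GA"), "C", id = "pathogenic1")
  stopifnot(substr(contig, s + 4L, s + 6L) == "CGA")

  exons <- data.frame(start = cds_start - 5L, end = cds_end + 5L)
  tx <- transcript_model("TOYGENE", chrom, "+", exons, cds_start, cds_end,
                         contig)

  # the read: reference minus the germline GA (s+4..s+5) minus one G (s+12)
  read <- paste0(substr(contig, s + 1L, s + 4L),
                 substr(contig, s + 7L, s + 12L),
                 substr(contig, s + 14L, s + 153L))
  stopifnot(nchar(read) == 150L)

  # construction checks: pathogenic alone loses the canonical stop; the
  # pathogenic + secondary combination restores it (net -3)
  vp <- data.frame(pos = s + 4L, ref = "GA", alt = "")
  vs <- rbind(vp, data.frame(pos = s + 12L, ref = "G", alt = ""))
  stopifnot(!translate_with_variants(tx, contig, vp)$same_stop_as_canonical,
            translate_with_variants(tx, contig, vs)$same_stop_as_canonical)

  # one mismatch in the first 10M of the naive placement
  naive_ref <- substr(contig, s + 1L, s + 10L)
  stopifnot(sum(strsplit(substr(read, 1, 10), "")[[1]] !=
                  strsplit(naive_ref, "")[[1]]) == 1L)

  recs <- data.frame(qname = "fig1b_read", flag = 0L, pos1 = s + 1L,
                     mapq = 60L, cigar = "10M1D140M", seq = read,
                     stringsAsFactors = FALSE)

  paths <- list(
    fasta = file.path(out_dir, "ref.fa"),
    transcript = file.path(out_dir, "transcript.tsv"),
    vcf = file.path(out_dir, "pathogenic.vcf"),
    sam = file.path(out_dir, "reads.sam"))
  dna <- Biostrings::DNAStringSet(setNames(contig, chrom))
  Biostrings::writeXStringSet(dna, paths$fasta, width = 60L)
  Rsamtools::indexFa(paths$fasta)
  write_transcript_tsv(tx, paths$transcript)
  write_pathogenic_vcf(list(pv), paths$vcf,
                       contig_len = setNames(nchar(contig), chrom))
  write_sam(recs, chrom, nchar(contig), paths$sam)

  list(paths = paths, s = s, e_g = s + 4L, contig = contig,
       pathogenic = pv, read = read,
       initial_cigar = "10M1D140M", corrected_cigar = "4M2D6M1D140M")
}
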