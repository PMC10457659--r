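#' Read one contig from a FASTA file
#'
#' @param fasta_path path to a (plain-text) FASTA file
#' @param chrom contig to extract; names are truncated at the first whitespace
#' @return uppercase character string of the contig sequence
#' @export
read_fasta_contig <- function(fasta_path, chrom) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nms <- sub("\\s.*$", "", names(seqs))
  idx <- match(chrom, nms)
  if (is.na(idx))
    stop(sprintf("contig '%s' not found in %s (contigs: %s)",
                 chrom, fasta_path, paste(nms, collapse = ", ")))
  s <- toupper(as.character(seqs[[idx]]))
  if (grepl("[^ACGTN]", s))
    stop("reference contains ambiguity codes other than N; not supported")
  s
}

# Apply a normalized edit (0-based start, anchor-free ref/alt) to a sequence.
apply_edit_to_seq <- function(seq, start, ref, alt) {
  lr <- nchar(ref)
  if (lr > 0L && substr(seq, start + 1L, start + lr) != ref)
    stop("edit ref allele does not match sequence")
  paste0(substr(seq, 1L, start), alt, substr(seq, start + lr + 1L, nchar(seq)))
}

#' Build the windowed reference context around a pathogenic variant
#'
#' Extracts a window of `window_radius` nt on either side of the pathogenic
#' edit, rewrites it with the pathogenic allele to form the personalized
#' sequence, and builds the bidirectional coordinate map between the two along
#' with homopolymer-run annotation. The FASTA base at the variant position
#' must equal the declared ref allele (guards against genome-build mismatch).
#'
#' @param fasta_path reference FASTA
#' @param variant a [pathogenic_variant()]
#' @param window_radius window half-width in nt (default 500; small reversion
#'   indels sit within ~200 nt of the pathogenic mutation, so 500 adds margin)
#' @param min_homopolymer minimum run length flagged as a homopolymer
#'   (default 5)
#' @return an object of class `reference_context` with fields `window`,
#'   `ref_seq`, `pers_seq`, `ref2pers`, `pers2ref`, `variant`, `edit`
#'   (window-relative), `homopolymers`, `contig_len`
#' @export
build_reference_context <- function(fasta_path, variant, window_radius = 500L,
                                    min_homopolymer = 5L) {
  stopifnot(inherits(variant, "pathogenic_variant"))
  window_radius <- as.integer(window_radius)
  if (window_radius < 1L) stop("window_radius must be >= 1")
  contig <- read_fasta_contig(fasta_path, variant$chrom)
  clen <- nchar(contig)

  ed <- variant$edit
  lr <- nchar(ed$ref)
  if (ed$start + lr > clen || ed$start >= clen)
    stop("variant position lies beyond the contig end")
  fasta_ref <- substr(contig, variant$pos, variant$pos + nchar(variant$ref) - 1L)
  if (fasta_ref != variant$ref)
    stop(sprintf(
      "reference mismatch at %s:%d: FASTA has '%s', variant declares '%s'",
      variant$chrom, variant$pos, fasta_ref, variant$ref))

  wstart <- ed$start - window_radius
  wend <- ed$start + lr + window_radius
  if (wstart < 0L || wend > clen) {
    wstart <- max(0L, wstart)
    wend <- min(clen, wend)
    warning("alignment window truncated to contig bounds")
  }
  window <- genomic_interval(variant$chrom, wstart, wend)
  ref_seq <- substr(contig, wstart + 1L, wend)

  e <- ed$start - wstart                       # window-relative edit start
  la <- nchar(ed$alt)
  pers_seq <- apply_edit_to_seq(ref_seq, e, ed$ref, ed$alt)

  maps <- build_coord_maps(nchar(ref_seq), e, lr, la)

  structure(list(
    window = window,
    ref_seq = ref_seq,
    pers_seq = pers_seq,
    ref2pers = maps$ref2pers,
    pers2ref = maps$pers2ref,
    variant = variant,
    edit = list(start = e, ref = ed$ref, alt = ed$alt),
    homopolymers = find_homopolymer_runs(ref_seq, min_homopolymer),
    contig_len = clen
  ), class = "reference_context")
}

# Coordinate maps between the reference window and the personalized sequence.
# Stored as integer vectors of 0-based positions; NA marks positions with no
# image (bases deleted by, or inserted by, the pathogenic edit).
build_coord_maps <- function(len_ref, e, lr, la) {
  nshared <- min(lr, la)   # leading edit positions aligned across (SNV/DELINS)
  ref2pers <- integer(len_ref)
  for (p in seq_len(len_ref) - 1L) {
    ref2pers[p + 1L] <-
      if (p < e) p
      else if (p < e + nshared) p
      else if (p < e + lr) NA_integer_
      else p - lr + la
  }
  len_pers <- len_ref - lr + la
  pers2ref <- integer(len_pers)
  for (p in seq_len(len_pers) - 1L) {
    pers2ref[p + 1L] <-
      if (p < e) p
      else if (p < e + nshared) p
      else if (p < e + la) NA_integer_
      else p - la + lr
  }
  list(ref2pers = ref2pers, pers2ref = pers2ref)
}

#' Map a position between reference-window and personalized coordinates
#'
#' Positions are window-relative and 0-based on both sides. Positions inside
#' a span deleted (or inserted) by the pathogenic edit have no image and map
#' to `NA`.
#'
#' @param ctx a [build_reference_context()] result
#' @param pos 0-based position in the source coordinate system
#' @param direction `"ref2pers"` or `"pers2ref"`
#' @return 0-based position in the other system, or `NA`
#' @export
map_position <- function(ctx, pos, direction = c("ref2pers", "pers2ref")) {
  direction <- match.arg(direction)
  map <- ctx[[direction]]
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0L) || any(pos >= length(map)))
    stop("position outside the window")
  map[pos + 1L]
}

#' Find homopolymer runs in a sequence
#'
#' Maximal runs of a single repeated nucleotide with length at least
#' `min_run`. Homopolymers are a common source of sequencing indel artifacts,
#' so candidate reversion variants overlapping them are flagged downstream.
#'
#' @param seq nucleotide string
#' @param min_run minimum run length (default 5, adjustable; must be >= 2)
#' @return data.frame with 0-based half-open `start`, `end` and `base`
#' @export
find_homopolymer_runs <- function(seq, min_run = 5L) {
  min_run <- as.integer(min_run)
  if (min_run < 2L) stop("min_run must be >= 2")
  if (!nzchar(seq))
    return(data.frame(start = integer(), end = integer(),
                      base = character(), stringsAsFactors = FALSE))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(start = as.integer(ends[keep] - r$lengths[keep]),
             end = as.integer(ends[keep]),
             base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.reference_context <- function(x, ...) {
  cat(sprintf(
    "<reference_context %s:%d-%d (%d nt), personalized %d nt, %d homopolymer run(s)>\n",
    x$window$chrom, x$window$start, x$window$end, nchar(x$ref_seq),
    nchar(x$pers_seq), nrow(x$homopolymers)))
  invisible(x)
}
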