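#' Genomic interval
#'
#' Lightweight coordinate carrier used throughout the package. Coordinates are
#' 0-based half-open internally; 1-based formats (VCF POS, SAM POS, the
#' transcript TSV) are converted at I/O boundaries.
#'
#' @param chrom contig name (nonempty string)
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end, `start <= end`
#' @return an object of class `genomic_interval`
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end)
    stop("invalid interval: require 0 <= start <= end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval %s:%d-%d (0-based, half-open)>\n",
              x$chrom, x$start, x$end))
  invisible(x)
}

#' Width of a genomic interval
#' @param x a `genomic_interval`
#' @return integer width
#' @export
interval_width <- function(x) x$end - x$start

# Trim the shared prefix, then the shared suffix, of a ref/alt pair.
# Returns the minimal edit as a 0-based start plus (possibly empty) ref/alt.
normalize_edit <- function(pos0, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) && length(a) && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos0 <- pos0 + 1L
  }
  while (length(r) && length(a) && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(start = as.integer(pos0),
       ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Shift a pure insertion or deletion to its leftmost sequence-equivalent
# placement within `seq` (a character string, 0-based positions). Standard
# VCF-style left alignment; used to canonicalize allele keys so that
# placement-ambiguous indels from different reads collapse onto one key.
left_align_edit <- function(seq, start, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr > 0L && la > 0L) return(list(start = start, ref = ref, alt = alt))
  if (lr == 0L && la == 0L) return(list(start = start, ref = ref, alt = alt))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (lr > 0L) {  # deletion of ref[start .. start+lr)
    del <- strsplit(ref, "", fixed = TRUE)[[1]]
    while (start > 0L && chars[start] == del[lr]) {
      del <- c(chars[start], del[-lr])
      start <- start - 1L
    }
    list(start = start, ref = paste(del, collapse = ""), alt = "")
  } else {       # insertion before position start
    ins <- strsplit(alt, "", fixed = TRUE)[[1]]
    while (start > 0L && chars[start] == ins[la]) {
      ins <- c(chars[start], ins[-la])
      start <- start - 1L
    }
    list(start = start, ref = "", alt = paste(ins, collapse = ""))
  }
}

classify_alleles <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) {
    if (lr == 1L) "SNV" else "DELINS"
  } else if (lr > la) "DEL" else "INS"
}

#' Pathogenic variant
#'
#' The patient's known inactivating allele: the prior knowledge the whole
#' method exploits. Uses VCF conventions on input (1-based `pos`, anchored
#' indel alleles); the anchored representation is normalized internally to a
#' minimal anchor-free edit span.
#'
#' @param chrom contig name
#' @param pos 1-based VCF position
#' @param ref reference allele (uppercase ACGTN, nonempty)
#' @param alt alternate allele (uppercase ACGTN, nonempty, != ref)
#' @param id variant label
#' @return an object of class `pathogenic_variant` with derived fields
#'   `vclass` (SNV/DEL/INS/DELINS) and `edit` (the normalized 0-based edit)
#' @export
pathogenic_variant <- function(chrom, pos, ref, alt, id = NULL) {
  stopifnot(is.character(chrom), nzchar(chrom))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive 1-based position")
  for (a in c(ref, alt)) {
    if (!nzchar(a) || grepl("[^ACGTN]", a))
      stop("alleles must be nonempty uppercase ACGTN strings: ", a)
  }
  if (identical(ref, alt)) stop("ref and alt must differ")
  edit <- normalize_edit(pos - 1L, ref, alt)
  if (is.null(id)) id <- sprintf("%s:%d:%s>%s", chrom, pos, ref, alt)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt, id = id,
                 vclass = classify_alleles(ref, alt), edit = edit),
            class = "pathogenic_variant")
}

#' @export
print.pathogenic_variant <- function(x, ...) {
  cat(sprintf("<pathogenic %s: %s:%d %s>%s (%s)>\n",
              x$id, x$chrom, x$pos, x$ref, x$alt, x$vclass))
  invisible(x)
}
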