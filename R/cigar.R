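CIGAR_OPS <- c("M", "I", "D", "S", "H", "N", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")   # consume read bases
REF_OPS <- c("M", "D", "N", "=", "X")     # consume reference bases

new_cigar <- function(len, op) {
  structure(list(len = as.integer(len), op = as.character(op)),
            class = "cigar")
}

# Merge adjacent ops of the same kind and drop zero-length ops.
merge_cigar_ops <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(len) > 1L) {
    grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  new_cigar(len, op)
}

#' Parse a SAM CIGAR string
#'
#' @param text CIGAR text, e.g. `"10M1D140M"`
#' @return an object of class `cigar`: parallel `len` / `op` vectors
#' @export
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text) || text == "*") return(new_cigar(integer(), character()))
  pieces <- regmatches(text, gregexpr("([0-9]+)([MIDNSHP=X])", text))[[1]]
  if (paste(pieces, collapse = "") != text)
    stop("malformed CIGAR: ", text)
  len <- as.integer(sub("[MIDNSHP=X]$", "", pieces))
  op <- sub("^[0-9]+", "", pieces)
  if (any(len < 1L)) stop("zero-length CIGAR op in: ", text)
  new_cigar(len, op)
}

#' Render a CIGAR back to text
#' @param cig a `cigar`
#' @return CIGAR string (`"*"` if empty)
#' @export
render_cigar <- function(cig) {
  if (length(cig$len) == 0L) return("*")
  paste0(cig$len, cig$op, collapse = "")
}

#' @export
print.cigar <- function(x, ...) {
  cat("<cigar ", render_cigar(x), ">\n", sep = "")
  invisible(x)
}

#' Summarize a CIGAR
#'
#' @param cig a `cigar`
#' @return list with `query_len` (bases of the read consumed, soft clips
#'   included), `ref_span` (reference bases covered), `n_deleted`,
#'   `n_inserted`, `n_clipped` (soft-clipped bases)
#' @export
cigar_summary <- function(cig) {
  list(query_len = sum(cig$len[cig$op %in% QUERY_OPS]),
       ref_span = sum(cig$len[cig$op %in% REF_OPS]),
       n_deleted = sum(cig$len[cig$op == "D"]),
       n_inserted = sum(cig$len[cig$op == "I"]),
       n_clipped = sum(cig$len[cig$op == "S"]))
}

# Replace =/X by M (they carry the same placement information once the read
# sequence is available) and merge.
normalize_match_ops <- function(cig) {
  op <- cig$op
  op[op %in% c("=", "X")] <- "M"
  merge_cigar_ops(cig$len, op)
}

#' Alignment record
#'
#' A read's placement inside the reference window: the object that soft-clip
#' rescue, personalized realignment and indel normalization rewrite.
#'
#' @param read_id read name
#' @param query read bases (forward reference strand, as stored in SAM)
#' @param ref_start 0-based window-relative start of the first aligned base
#' @param cigar a `cigar` (or CIGAR text); `=`/`X` are normalized to `M`
#' @param quals optional per-base qualities
#' @param is_duplicate,is_reverse,mapq SAM flags of interest
#' @param provenance character vector recording rewrites applied
#' @return an object of class `alignment_record`
#' @export
alignment_record <- function(read_id, query, ref_start, cigar, quals = NULL,
                             is_duplicate = FALSE, is_reverse = FALSE,
                             mapq = 60L, provenance = character()) {
  if (is.character(cigar)) cigar <- parse_cigar(cigar)
  cigar <- normalize_match_ops(cigar)
  if (!all(cigar$op %in% CIGAR_OPS)) stop("unsupported CIGAR op")
  qlen <- cigar_summary(cigar)$query_len
  if (qlen != nchar(query))
    stop(sprintf("CIGAR consumes %d bases but read '%s' has %d",
                 qlen, read_id, nchar(query)))
  structure(list(read_id = read_id, query = query,
                 ref_start = as.integer(ref_start), cigar = cigar,
                 quals = quals, is_duplicate = isTRUE(is_duplicate),
                 is_reverse = isTRUE(is_reverse), mapq = as.integer(mapq),
                 provenance = provenance),
            class = "alignment_record")
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("<read %s @%d %s%s>\n", x$read_id, x$ref_start,
              render_cigar(x$cigar),
              if (length(x$provenance))
                paste0(" [", paste(x$provenance, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Scoring scheme for local alignment
#'
#' The default is deliberately lenient on small indels (the most common form
#' of reversion mutation): one 2-4 nt gap is preferred over two mismatches.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match positive match score (default 2)
#' @param mismatch mismatch penalty, `<= 0` (default -3)
#' @param gap_open gap opening penalty, `<= 0` (default -2)
#' @param gap_extend per-base gap extension penalty, `<= 0` (default -0.5)
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -2,
                           gap_extend = -0.5) {
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Default indel-lenient scoring scheme
#' @return a [scoring_scheme()] with match 2, mismatch -3, gap open -2,
#'   gap extend -0.5
#' @export
default_scoring <- function() scoring_scheme()

# Stringent bwa-mem-like scoring (match 1, mismatch -4, open -6, extend -1):
# used by the fixture generator to emulate a general-purpose aligner's
# behaviour around pathogenic indels (mismatch-encoded deletions, soft clips).
naive_scoring <- function() scoring_scheme(1, -4, -6, -1)

#' Smith-Waterman local alignment with affine gaps
#'
#' Deterministic: the best-scoring cell is chosen with smallest target end
#' then smallest query end, and the traceback prefers match over deletion
#' over insertion, which left-aligns indels. The `"ACGAGAT"` vs `"ACGAT"`
#' two-placement ambiguity therefore resolves to the leftmost deletion.
#'
#' @param query,target nonempty nucleotide strings
#' @param scheme a [scoring_scheme()]
#' @return an object of class `sw_alignment`: `score`, 0-based half-open
#'   `query_start`/`query_end` and `target_start`/`target_end`,
#'   `n_mismatch`, and `cigar` (M/I/D over the aligned region only)
#' @export
smith_waterman <- function(query, target, scheme = default_scoring()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  res <- .sw_align_cpp(query, target, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
  res$cigar <- new_cigar(res$cigar_len, res$cigar_op)
  res$cigar_len <- NULL
  res$cigar_op <- NULL
  class(res) <- "sw_alignment"
  res
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw score=%g target=[%d,%d) query=[%d,%d) %s mismatches=%d>\n",
              x$score, x$target_start, x$target_end, x$query_start,
              x$query_end, render_cigar(x$cigar), x$n_mismatch))
  invisible(x)
}

# Length of the longest run of exactly matched columns in an sw_alignment.
sw_max_perfect_run <- function(aln, query, target) {
  qi <- aln$query_start; ti <- aln$target_start
  best <- 0L; run <- 0L
  for (k in seq_along(aln$cigar$len)) {
    op <- aln$cigar$op[k]; L <- aln$cigar$len[k]
    if (op == "M") {
      for (b in seq_len(L)) {
        qc <- substr(query, qi + b, qi + b)
        tc <- substr(target, ti + b, ti + b)
        if (qc == tc && qc != "N") {
          run <- run + 1L
          if (run > best) best <- run
        } else run <- 0L
      }
      qi <- qi + L; ti <- ti + L
    } else if (op == "I") {
      qi <- qi + L; run <- 0L
    } else if (op == "D") {
      ti <- ti + L; run <- 0L
    }
  }
  best
}
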