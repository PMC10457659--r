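# --- internal alignment-record helpers ------------------------------------

# Number of mismatched M columns of `rec` against the window reference.
record_mismatch_count <- function(rec, ctx) {
  qi <- 0L; ri <- rec$ref_start; n <- 0L
  for (k in seq_along(rec$cigar$len)) {
    op <- rec$cigar$op[k]; L <- rec$cigar$len[k]
    if (op == "M") {
      q <- substr(rec$query, qi + 1L, qi + L)
      r <- substr(ctx$ref_seq, ri + 1L, ri + L)
      n <- n + sum(strsplit(q, "")[[1]] != strsplit(r, "")[[1]])
      qi <- qi + L; ri <- ri + L
    } else if (op %in% c("I", "S")) qi <- qi + L
    else if (op %in% c("D", "N")) ri <- ri + L
  }
  n
}

# Total soft-clipped bases of a record.
record_clip_total <- function(rec) sum(rec$cigar$len[rec$cigar$op == "S"])

# Reference span [start, end) covered by the aligned (non-clip) part.
record_ref_span <- function(rec) {
  c(rec$ref_start, rec$ref_start + cigar_summary(rec$cigar)$ref_span)
}

#' Reconstruct the read sequence implied by an alignment
#'
#' Walks the CIGAR emitting reference bases for `M`/`D`-free columns
#' (`M` copies the reference, `I` and `S` copy the read, `D`/`N` skip
#' reference). For a mismatch-free alignment this reproduces the read
#' exactly; it is the invariant checked by indel-placement normalization
#' (two placements are equivalent iff they imply the same sequence).
#'
#' @param rec an [alignment_record()]
#' @param ctx a [build_reference_context()] result
#' @return character string
#' @export
reconstruct_query <- function(rec, ctx) {
  out <- character(0)
  qi <- 0L; ri <- rec$ref_start
  for (k in seq_along(rec$cigar$len)) {
    op <- rec$cigar$op[k]; L <- rec$cigar$len[k]
    if (op == "M") {
      out <- c(out, substr(ctx$ref_seq, ri + 1L, ri + L))
      qi <- qi + L; ri <- ri + L
    } else if (op %in% c("I", "S")) {
      out <- c(out, substr(rec$query, qi + 1L, qi + L))
      qi <- qi + L
    } else if (op %in% c("D", "N")) {
      ri <- ri + L
    }
  }
  paste(out, collapse = "")
}

# --- soft-clip rescue ------------------------------------------------------

#' Rescue soft-clipped read ends by local alignment
#'
#' Large-deletion reversions are typically reported by general aligners as
#' soft-clipped read ends. Each terminal `S` segment is Smith-Waterman
#' aligned against the whole reference window; if the best placement contains
#' a contiguous run of at least `min_perfect` exactly matched bases and sits
#' on the correct side of the anchored alignment, the clip is converted to
#' aligned ops, joined to the anchor by the implied `D` (skipped reference)
#' and/or `I` (unplaced read bases). Otherwise the record is unchanged.
#'
#' @param rec an [alignment_record()]
#' @param ctx a [build_reference_context()] result
#' @param scheme a [scoring_scheme()]
#' @param min_perfect minimum perfectly matched run length (default 20)
#' @return a possibly rewritten [alignment_record()]; `provenance` gains
#'   `"softclip_rescued"` on change
#' @export
rescue_soft_clips <- function(rec, ctx, scheme = default_scoring(),
                              min_perfect = 20L) {
  ops <- rec$cigar$op
  if (!any(ops == "S")) return(rec)
  changed <- FALSE

  # 5' clip
  if (rec$cigar$op[1L] == "S") {
    cl <- rec$cigar$len[1L]
    if (cl >= min_perfect) {
      clip_seq <- substr(rec$query, 1L, cl)
      aln <- smith_waterman(clip_seq, ctx$ref_seq, scheme)
      ok <- aln$score > 0 &&
        sw_max_perfect_run(aln, clip_seq, ctx$ref_seq) >= min_perfect
      if (ok) {
        d <- rec$ref_start - aln$target_end          # skipped reference
        u <- cl - aln$query_end                      # unplaced read bases
        if (d >= 0L) {
          body <- rec$cigar
          body$len <- body$len[-1L]; body$op <- body$op[-1L]
          len <- c(aln$query_start, aln$cigar$len, u, d, body$len)
          op <- c("S", aln$cigar$op, "I", "D", body$op)
          keep <- len > 0L
          rec$cigar <- merge_cigar_ops(as.integer(len[keep]), op[keep])
          rec$ref_start <- aln$target_start
          changed <- TRUE
        }
      }
    }
  }

  # 3' clip
  nops <- length(rec$cigar$op)
  if (rec$cigar$op[nops] == "S") {
    cl <- rec$cigar$len[nops]
    if (cl >= min_perfect) {
      clip_seq <- substr(rec$query, nchar(rec$query) - cl + 1L,
                         nchar(rec$query))
      aln <- smith_waterman(clip_seq, ctx$ref_seq, scheme)
      ok <- aln$score > 0 &&
        sw_max_perfect_run(aln, clip_seq, ctx$ref_seq) >= min_perfect
      if (ok) {
        anchor_end <- record_ref_span(rec)[2L]
        d <- aln$target_start - anchor_end
        u <- aln$query_start
        if (d >= 0L) {
          body <- rec$cigar
          body$len <- body$len[-nops]; body$op <- body$op[-nops]
          trail <- cl - aln$query_end
          len <- c(body$len, u, d, aln$cigar$len, trail)
          op <- c(body$op, "I", "D", aln$cigar$op, "S")
          keep <- len > 0L
          rec$cigar <- merge_cigar_ops(as.integer(len[keep]), op[keep])
          changed <- TRUE
        }
      }
    }
  }

  if (changed) rec$provenance <- union(rec$provenance, "softclip_rescued")
  rec
}

# --- personalized realignment ----------------------------------------------

# Lift an alignment against the personalized sequence back to reference
# window coordinates, re-expressing the pathogenic edit as D/I ops.
lift_pers_alignment <- function(aln, ctx, query_len) {
  len <- integer(0); op <- character(0)
  prev_r <- NA_integer_
  ref_start <- NA_integer_
  p <- aln$target_start   # 0-based position in pers_seq

  push <- function(o, L) {
    len <<- c(len, as.integer(L)); op <<- c(op, o)
  }

  for (k in seq_along(aln$cigar$len)) {
    o <- aln$cigar$op[k]; L <- aln$cigar$len[k]
    if (o == "M") {
      for (b in seq_len(L)) {
        r <- ctx$pers2ref[p + 1L]
        if (is.na(r)) {
          push("I", 1L)        # read base sits on a pathogenic-inserted base
        } else {
          if (!is.na(prev_r) && r > prev_r + 1L)
            push("D", r - prev_r - 1L)
          push("M", 1L)
          if (is.na(ref_start)) ref_start <- r
          prev_r <- r
        }
        p <- p + 1L
      }
    } else if (o == "I") {
      push("I", L)
    } else if (o == "D") {
      for (b in seq_len(L)) {
        r <- ctx$pers2ref[p + 1L]
        if (!is.na(r)) {
          if (!is.na(prev_r) && r > prev_r + 1L)
            push("D", r - prev_r - 1L)
          push("D", 1L)
          prev_r <- r
        }
        p <- p + 1L
      }
    }
  }
  if (is.na(ref_start)) return(NULL)   # nothing aligned a reference base

  cig <- merge_cigar_ops(len, op)
  # Trim leading/trailing D (just shifts the span) and turn terminal I into S.
  while (length(cig$op) && cig$op[1L] %in% c("D")) {
    cig$len <- cig$len[-1L]; cig$op <- cig$op[-1L]
  }
  while (length(cig$op) && cig$op[length(cig$op)] == "D") {
    cig$len <- cig$len[-length(cig$len)]; cig$op <- cig$op[-length(cig$op)]
  }
  lead_s <- aln$query_start
  trail_s <- query_len - aln$query_end
  if (length(cig$op) && cig$op[1L] == "I") {
    lead_s <- lead_s + cig$len[1L]
    cig$len <- cig$len[-1L]; cig$op <- cig$op[-1L]
  }
  if (length(cig$op) && cig$op[length(cig$op)] == "I") {
    trail_s <- trail_s + cig$len[length(cig$len)]
    cig$len <- cig$len[-length(cig$len)]; cig$op <- cig$op[-length(cig$op)]
  }
  full <- merge_cigar_ops(c(lead_s, cig$len, trail_s),
                          c("S", cig$op, "S"))
  list(ref_start = ref_start, cigar = full)
}

# Does the record overlap the pathogenic edit span (with the insertion point
# widened by one base on each side for pure insertions)?
overlaps_pathogenic <- function(rec, ctx) {
  span <- record_ref_span(rec)
  e <- ctx$edit$start; lr <- nchar(ctx$edit$ref)
  lo <- if (lr == 0L) e - 1L else e
  hi <- if (lr == 0L) e + 1L else e + lr
  span[1L] < hi && span[2L] > lo
}

# Does the record's variant decomposition already include the pathogenic
# allele (by left-aligned sequence-equivalence)?
record_encodes_pathogenic <- function(rec, ctx) {
  v <- extract_observed_variants(rec, ctx)
  any(v$is_pathogenic_match)
}

#' Locally realign a read against the personalized reference
#'
#' When a read overlapping the pathogenic span shows mismatches, residual
#' soft clips, or indels that do not encode the pathogenic allele, the full
#' read is Smith-Waterman aligned against the personalized sequence (the
#' window rewritten with the pathogenic allele) under the indel-lenient
#' scheme. The new alignment is accepted only if it matches the personalized
#' genome perfectly in every aligned column (additional indels are allowed --
#' they are the candidate reversions; base mismatches are not) and does not
#' increase the number of clipped bases. On acceptance the alignment is
#' lifted back to reference coordinates, with the pathogenic edit
#' re-expressed as D/I ops; otherwise the input record is returned
#' bit-identical.
#'
#' @param rec an [alignment_record()]
#' @param ctx a [build_reference_context()] result
#' @param scheme a [scoring_scheme()]
#' @return a possibly rewritten [alignment_record()]; `provenance` gains
#'   `"realigned_personalized"` on change
#' @export
realign_over_pathogenic <- function(rec, ctx, scheme = default_scoring()) {
  if (!overlaps_pathogenic(rec, ctx)) return(rec)
  has_mm <- record_mismatch_count(rec, ctx) > 0L
  has_clip <- record_clip_total(rec) > 0L
  has_indel <- any(rec$cigar$op %in% c("I", "D"))
  trigger <- has_mm || has_clip ||
    (has_indel && !record_encodes_pathogenic(rec, ctx))
  if (!trigger) return(rec)

  aln <- smith_waterman(rec$query, ctx$pers_seq, scheme)
  if (aln$score <= 0 || aln$n_mismatch > 0L) return(rec)
  new_clip <- aln$query_start + (nchar(rec$query) - aln$query_end)
  if (new_clip > record_clip_total(rec)) return(rec)

  lifted <- lift_pers_alignment(aln, ctx, nchar(rec$query))
  if (is.null(lifted)) return(rec)
  rec$ref_start <- lifted$ref_start
  rec$cigar <- lifted$cigar
  rec$provenance <- union(rec$provenance, "realigned_personalized")
  rec
}

# --- indel-placement normalization -----------------------------------------

# Rebuild a CIGAR from a record's span plus an indel list. `indels` is a
# data.frame with 0-based window `pos`, `ref`, `alt` (anchor-free), sorted.
# Returns NULL when geometry is inconsistent.
rebuild_cigar <- function(rec, indels) {
  sm <- cigar_summary(rec$cigar)
  lead_s <- if (rec$cigar$op[1L] == "S") rec$cigar$len[1L] else 0L
  trail_s <- if (rec$cigar$op[length(rec$cigar$op)] == "S")
    rec$cigar$len[length(rec$cigar$len)] else 0L
  span_end <- rec$ref_start + sm$ref_span
  len <- integer(0); op <- character(0)
  cur <- rec$ref_start
  for (k in seq_len(nrow(indels))) {
    p <- indels$pos[k]
    lr <- nchar(indels$ref[k]); la <- nchar(indels$alt[k])
    if (p < cur) return(NULL)
    if (p > cur) { len <- c(len, p - cur); op <- c(op, "M"); cur <- p }
    if (lr > 0L) { len <- c(len, lr); op <- c(op, "D"); cur <- cur + lr }
    if (la > 0L) { len <- c(len, la); op <- c(op, "I") }
  }
  if (span_end < cur) return(NULL)
  if (span_end > cur) { len <- c(len, span_end - cur); op <- c(op, "M") }
  full <- merge_cigar_ops(c(lead_s, len, trail_s), c("S", op, "S"))
  if (cigar_summary(full)$query_len != nchar(rec$query)) return(NULL)
  full
}

#' Normalize indel placement onto the pathogenic span
#'
#' When the bases deleted (or inserted) by the pathogenic mutation sit in a
#' tandem-repeat context, a general aligner may place a sequence-equivalent
#' indel over the neighbouring repeat unit instead of over the pathogenic
#' span -- genetically implausible given the patient's known allele. If the
#' record carries an indel of the pathogenic length whose relocation onto the
#' pathogenic span implies the identical read sequence, the CIGAR is
#' rewritten to that placement. The operation is idempotent and never changes
#' the implied read sequence.
#'
#' @param rec an [alignment_record()]
#' @param ctx a [build_reference_context()] result
#' @return a possibly rewritten [alignment_record()]; `provenance` gains
#'   `"normalized"` on change
#' @export
normalize_indel_placement <- function(rec, ctx) {
  lr <- nchar(ctx$edit$ref); la <- nchar(ctx$edit$alt)
  pure_del <- lr > 0L && la == 0L
  pure_ins <- lr == 0L && la > 0L
  if (!pure_del && !pure_ins) return(rec)
  e <- ctx$edit$start

  v <- extract_observed_variants(rec, ctx, left_align = FALSE)
  kinds <- if (pure_del) "DEL" else "INS"
  idx <- which(v$kind == kinds &
                 nchar(v$ref) == lr & nchar(v$alt) == la & v$pos != e)
  if (!length(idx)) return(rec)

  indels <- v[v$kind != "SNV", , drop = FALSE]
  indels <- indels[order(indels$pos), , drop = FALSE]
  orig_mm <- record_mismatch_count(rec, ctx)
  orig_impl <- reconstruct_query(rec, ctx)

  for (i in idx) {
    # sequence equivalence over the whole window: applying the indel at its
    # current position or at the pathogenic span must yield the same sequence
    old <- v[i, ]
    h1 <- apply_edit_try(ctx$ref_seq, old$pos, old$ref, old$alt)
    h2 <- apply_edit_try(ctx$ref_seq, e, ctx$edit$ref, ctx$edit$alt)
    if (is.null(h1) || is.null(h2) || h1 != h2) next

    cand <- indels
    cand$pos[cand$pos == old$pos & cand$ref == old$ref &
               cand$alt == old$alt] <- e
    if (pure_del) cand$ref[cand$pos == e & cand$kind == "DEL" &
                             nchar(cand$ref) == lr] <- ctx$edit$ref
    else cand$alt[cand$pos == e & cand$kind == "INS" &
                    nchar(cand$alt) == la] <- ctx$edit$alt
    cand <- cand[order(cand$pos), , drop = FALSE]
    new_cig <- rebuild_cigar(rec, cand)
    if (is.null(new_cig)) next

    cand_rec <- rec
    cand_rec$cigar <- new_cig
    if (record_mismatch_count(cand_rec, ctx) > orig_mm) next
    if (reconstruct_query(cand_rec, ctx) != orig_impl) next
    cand_rec$provenance <- union(cand_rec$provenance, "normalized")
    return(cand_rec)
  }
  rec
}

apply_edit_try <- function(seq, start, ref, alt) {
  tryCatch(apply_edit_to_seq(seq, start, ref, alt), error = function(e) NULL)
}

# --- variant extraction ----------------------------------------------------

#' Extract observed variants from a finalized alignment
#'
#' Walks the CIGAR emitting SNVs (mismatched `M` columns), deletions (`D`)
#' and insertions (`I`) in 0-based window coordinates. Indels are left
#' aligned so that placement-ambiguous observations from different reads
#' collapse onto one canonical representation; a variant is marked
#' `is_pathogenic_match` when its left-aligned form equals the left-aligned
#' pathogenic edit. Columns involving `N` are skipped (N never counts as a
#' match, nor as evidence of a variant).
#'
#' @param rec an [alignment_record()]
#' @param ctx a [build_reference_context()] result
#' @param left_align left-align indels (default TRUE)
#' @return data.frame with `pos`, `ref`, `alt`, `kind`, `is_pathogenic_match`
#' @export
extract_observed_variants <- function(rec, ctx, left_align = TRUE) {
  pos <- integer(0); ref <- character(0); alt <- character(0)
  kind <- character(0)
  qi <- 0L; ri <- rec$ref_start
  wlen <- nchar(ctx$ref_seq)
  for (k in seq_along(rec$cigar$len)) {
    op <- rec$cigar$op[k]; L <- rec$cigar$len[k]
    if (op == "M") {
      if (ri + L > wlen) stop("CIGAR walks past the window end")
      q <- strsplit(substr(rec$query, qi + 1L, qi + L), "")[[1]]
      r <- strsplit(substr(ctx$ref_seq, ri + 1L, ri + L), "")[[1]]
      mm <- which(q != r & q != "N" & r != "N")
      if (length(mm)) {
        pos <- c(pos, ri + mm - 1L)
        ref <- c(ref, r[mm]); alt <- c(alt, q[mm])
        kind <- c(kind, rep("SNV", length(mm)))
      }
      qi <- qi + L; ri <- ri + L
    } else if (op == "I") {
      pos <- c(pos, ri)
      ref <- c(ref, ""); alt <- c(alt, substr(rec$query, qi + 1L, qi + L))
      kind <- c(kind, "INS")
      qi <- qi + L
    } else if (op == "D") {
      if (ri + L > wlen) stop("CIGAR walks past the window end")
      pos <- c(pos, ri)
      ref <- c(ref, substr(ctx$ref_seq, ri + 1L, ri + L)); alt <- c(alt, "")
      kind <- c(kind, "DEL")
      ri <- ri + L
    } else if (op == "S") qi <- qi + L
    else if (op == "N") ri <- ri + L
  }

  if (left_align && length(pos)) {
    for (k in which(kind != "SNV")) {
      la <- left_align_edit(ctx$ref_seq, pos[k], ref[k], alt[k])
      pos[k] <- la$start; ref[k] <- la$ref; alt[k] <- la$alt
    }
  }

  pe <- left_align_edit(ctx$ref_seq, ctx$edit$start, ctx$edit$ref,
                        ctx$edit$alt)
  is_pm <- logical(length(pos))
  for (k in seq_along(pos)) {
    ck <- if (left_align) list(start = pos[k], ref = ref[k], alt = alt[k])
          else left_align_edit(ctx$ref_seq, pos[k], ref[k], alt[k])
    is_pm[k] <- ck$start == pe$start && ck$ref == pe$ref && ck$alt == pe$alt
  }

  out <- data.frame(pos = pos, ref = ref, alt = alt, kind = kind,
                    is_pathogenic_match = is_pm, stringsAsFactors = FALSE)
  out[order(out$pos, out$kind), , drop = FALSE]
}
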