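# Convert window-relative observed variants to genomic, anchor-free edits.
observed_to_genomic <- function(variants, ctx) {
  if (nrow(variants) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  data.frame(pos = variants$pos + ctx$window$start,
             ref = variants$ref, alt = variants$alt,
             stringsAsFactors = FALSE)
}

# Display key for one variant: 1-based genomic position, "-" for empty allele.
format_variant_key <- function(pos, ref, alt, ctx) {
  gpos <- pos + ctx$window$start + 1L
  sprintf("%d:%s>%s",
          gpos,
          if (nzchar(ref)) ref else "-",
          if (nzchar(alt)) alt else "-")
}

#' Assess one read for frame restoration
#'
#' Translates the transcript rewritten with all of the read's observed
#' variants (pathogenic plus secondaries) and classifies the read. A read is
#' a candidate reversion when the realized protein is intact with the same
#' stop codon as the canonical transcript, via one of three routes: the
#' pathogenic allele plus secondary frame-restoring indel(s)
#' (`reversion_secondary_indel`), a larger deletion that removes the
#' pathogenic span entirely (`reversion_spanning_deletion`), or a base change
#' within the pathogenic span replacing its consequence
#' (`reversion_snv`). Reads carrying neither route are `reference_read`
#' (translation canonical) or `not_reverted`. Any premature stop introduced
#' upstream forces `same_stop_as_canonical` to false, so mutations downstream
#' of an introduced stop gain can never rescue a read.
#'
#' @param read_id read name
#' @param variants observed variants from [extract_observed_variants()]
#' @param ctx a [build_reference_context()] result
#' @param tx a [transcript_model()]
#' @param genome_seq full contig sequence
#' @return an object of class `reversion_assessment`
#' @export
assess_read <- function(read_id, variants, ctx, tx, genome_seq) {
  carries <- any(variants$is_pathogenic_match)
  e <- ctx$edit$start + ctx$window$start      # genomic edit start
  lr <- nchar(ctx$edit$ref)

  gvars <- observed_to_genomic(variants, ctx)
  outcome <- tryCatch(
    translate_with_variants(tx, genome_seq, gvars),
    error = function(err) {
      warning("translation failed for read ", read_id, ": ",
              conditionMessage(err))
      structure(list(protein = "", premature_stop = TRUE,
                     stop_pos = NA_integer_, frame_intact = FALSE,
                     same_stop_as_canonical = FALSE),
                class = "protein_outcome")
    })

  spanning <- FALSE
  if (lr > 0L && nrow(variants)) {
    dels <- variants[variants$kind == "DEL" & !variants$is_pathogenic_match, ,
                     drop = FALSE]
    if (nrow(dels)) {
      gpos <- dels$pos + ctx$window$start
      spanning <- any(gpos <= e & gpos + nchar(dels$ref) >= e + lr &
                        nchar(dels$ref) > lr)
    }
  }
  snv_at_path <- FALSE
  if (nrow(variants)) {
    snvs <- variants[variants$kind == "SNV" & !variants$is_pathogenic_match, ,
                     drop = FALSE]
    if (nrow(snvs)) {
      gpos <- snvs$pos + ctx$window$start
      hi <- if (lr == 0L) e + 1L else e + lr
      snv_at_path <- any(gpos >= e & gpos < hi)
    }
  }
  has_secondary_indel <- any(variants$kind %in% c("DEL", "INS") &
                               !variants$is_pathogenic_match)

  if (outcome$same_stop_as_canonical) {
    category <- if (carries && has_secondary_indel) "reversion_secondary_indel"
    else if (spanning) "reversion_spanning_deletion"
    else if (snv_at_path) "reversion_snv"
    else if (carries) "not_reverted"      # e.g. in-frame pathogenic variant
    else "reference_read"
  } else {
    category <- "not_reverted"
  }

  is_candidate <- outcome$same_stop_as_canonical &&
    category %in% c("reversion_secondary_indel",
                    "reversion_spanning_deletion", "reversion_snv")

  structure(list(read_id = read_id, observed = variants,
                 carries_pathogenic = carries, outcome = outcome,
                 category = category, is_candidate_reversion = is_candidate),
            class = "reversion_assessment")
}

#' Aggregate per-read assessments into distinct reversion alleles
#'
#' Candidate reads are grouped by their canonical allele key: the sorted
#' `"pos:ref>alt"` string of the read's non-pathogenic variants (left-aligned,
#' 1-based genomic positions). Each allele records its supporting reads, VAF
#' (`n_support / depth_at_variant`), and a homopolymer flag set when any of
#' its variants intersects a homopolymer run in the window (a common
#' sequencing-artifact context).
#'
#' @param assessments list of [assess_read()] results for one pathogenic
#'   variant
#' @param depth_at_variant non-duplicate reads covering the pathogenic
#'   position (the VAF denominator); must be >= 1
#' @param ctx a [build_reference_context()] result
#' @return list of `reversion_allele` objects, sorted by descending support
#'   then key
#' @export
aggregate_alleles <- function(assessments, depth_at_variant, ctx) {
  depth_at_variant <- as.integer(depth_at_variant)
  if (is.na(depth_at_variant) || depth_at_variant < 1L)
    stop("depth_at_variant must be >= 1")

  cand <- Filter(function(a) isTRUE(a$is_candidate_reversion), assessments)
  if (!length(cand)) return(list())

  keys <- vapply(cand, function(a) {
    v <- a$observed[!a$observed$is_pathogenic_match, , drop = FALSE]
    v <- v[order(v$pos, v$kind, v$alt), , drop = FALSE]
    paste(mapply(format_variant_key, v$pos, v$ref, v$alt,
                 MoreArgs = list(ctx = ctx)), collapse = ";")
  }, character(1))

  alleles <- lapply(unique(keys), function(key) {
    members <- cand[keys == key]
    v <- members[[1L]]$observed[!members[[1L]]$observed$is_pathogenic_match, ,
                                drop = FALSE]
    hp <- ctx$homopolymers
    flag <- FALSE
    if (nrow(hp) && nrow(v)) {
      vs <- v$pos
      ve <- v$pos + pmax(nchar(v$ref), 1L)
      for (k in seq_len(nrow(v)))
        flag <- flag || any(vs[k] < hp$end & ve[k] > hp$start)
    }
    ids <- vapply(members, function(a) a$read_id, character(1))
    net <- sum(nchar(members[[1L]]$observed$alt) -
                 nchar(members[[1L]]$observed$ref))
    structure(list(
      key = key,
      variants = v,
      supporting_reads = sort(ids),
      n_support = length(ids),
      vaf = length(ids) / depth_at_variant,
      homopolymer_flag = flag,
      category = members[[1L]]$category,
      net_indel = net,
      frame_restored = members[[1L]]$outcome$frame_intact,
      same_stop = members[[1L]]$outcome$same_stop_as_canonical
    ), class = "reversion_allele")
  })

  ord <- order(-vapply(alleles, `[[`, integer(1), "n_support"),
               vapply(alleles, `[[`, character(1), "key"))
  alleles[ord]
}

#' @export
print.reversion_allele <- function(x, ...) {
  cat(sprintf("<allele %s: %s, support=%d, vaf=%.4f%s>\n",
              x$key, x$category, x$n_support, x$vaf,
              if (x$homopolymer_flag) ", homopolymer" else ""))
  invisible(x)
}
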