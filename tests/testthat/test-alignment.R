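# A shared unique-ish window for rescue tests: random 400-mer, fixed seed.
make_rescue_window <- function() {
  set.seed(31)
  w <- ora_random_seq(400)
  toy_context(w, 200L, substr(w, 201L, 202L), "")   # 2 nt pathogenic del
}

test_that("soft-clip rescue recovers a large deletion and is conservative", {
  ctx <- make_rescue_window()
  w <- ctx$ref_seq
  # true structure: 30 matched bases at [100,130), 50 nt deletion, 120 at
  # [180,300); the naive aligner reports the first 30 bases as a soft clip
  read <- paste0(substr(w, 101, 130), substr(w, 181, 300))
  rec <- alignment_record("r1", read, 180L, "30S120M")
  out <- rescue_soft_clips(rec, ctx, min_perfect = 20L)
  expect_identical(render_cigar(out$cigar), "30M50D120M")
  expect_identical(out$ref_start, 100L)
  expect_true("softclip_rescued" %in% out$provenance)
  expect_identical(out$query, rec$query)

  # 3' clip, mirrored
  read2 <- paste0(substr(w, 21, 140), substr(w, 191, 220))
  rec2 <- alignment_record("r2", read2, 20L, "120M30S")
  out2 <- rescue_soft_clips(rec2, ctx, min_perfect = 20L)
  expect_identical(render_cigar(out2$cigar), "120M50D30M")
  expect_identical(out2$ref_start, 20L)

  # no soft clips: untouched no-op
  rec3 <- alignment_record("r3", substr(w, 51, 150), 50L, "100M")
  expect_identical(rescue_soft_clips(rec3, ctx), rec3)

  # clip too short for the required perfect run: unchanged
  read4 <- paste0(substr(w, 121, 130), substr(w, 181, 300))
  rec4 <- alignment_record("r4", read4, 180L, "10S120M")
  expect_identical(rescue_soft_clips(rec4, ctx, min_perfect = 20L), rec4)
})

test_that("personalized realignment accepts only perfect matches", {
  set.seed(32)
  w <- ora_random_seq(200)
  e <- 100L
  ctx <- toy_context(w, e, substr(w, e + 1L, e + 2L), "")  # 2 nt del
  pers <- ctx$pers_seq

  # read drawn from the personalized haplotype with one extra 4 nt deletion
  p0 <- 40L                       # pers-space read start
  read <- paste0(substr(pers, p0 + 1L, p0 + 70L),
                 substr(pers, p0 + 75L, p0 + 120L))  # 4 nt del inside pers
  # give it a deliberately poor initial placement: all-M with mismatches
  rec <- alignment_record("q1", read, p0, sprintf("%dM", nchar(read)))
  out <- realign_over_pathogenic(rec, ctx)
  expect_true("realigned_personalized" %in% out$provenance)
  expect_identical(out$query, read)
  expect_identical(cigar_summary(out$cigar)$n_deleted, 2L + 4L)
  expect_identical(cigar_summary(out$cigar)$query_len, nchar(read))
  expect_identical(revertscan:::record_mismatch_count(out, ctx), 0L)

  # a read exactly matching the reference is never displaced
  ref_read <- substr(w, 61, 160)
  rec2 <- alignment_record("q2", ref_read, 60L, "100M")
  expect_identical(realign_over_pathogenic(rec2, ctx), rec2)

  # mismatches against the personalized genome: rejected bit-identically
  bad <- read
  substr(bad, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 30, 30))[1]
  rec3 <- alignment_record("q3", bad, p0, sprintf("%dM", nchar(bad)))
  expect_identical(realign_over_pathogenic(rec3, ctx), rec3)
})

test_that("realignment lifts insertions across the pathogenic edit", {
  set.seed(33)
  w <- ora_random_seq(200)
  e <- 100L
  ins <- "GGACC"
  ctx <- toy_context(w, e, "", ins)    # 5 nt pathogenic insertion
  pers <- ctx$pers_seq
  read <- substr(pers, 61, 170)        # spans the insertion
  rec <- alignment_record("q1", read, 60L, sprintf("%dM", nchar(read)))
  out <- realign_over_pathogenic(rec, ctx)
  expect_true("realigned_personalized" %in% out$provenance)
  expect_identical(cigar_summary(out$cigar)$n_inserted, 5L)
  v <- extract_observed_variants(out, ctx)
  expect_true(any(v$is_pathogenic_match & v$kind == "INS"))
})

test_that("indel placement normalizes onto the pathogenic span", {
  #           0123456789012345678901
  w <- paste0("TTTTTCC", "ACGAGAT", "GGCCTTA")
  ctx <- toy_context(w, 9L, "GA", "")           # first GA of ACGAGAT
  # record deleting the second GA (positions 11,12): sequence-equivalent
  read <- paste0(substr(w, 8, 11), substr(w, 14, 21))
  rec <- alignment_record("n1", read, 7L, "4M2D8M")
  out <- normalize_indel_placement(rec, ctx)
  expect_identical(render_cigar(out$cigar), "2M2D10M")
  expect_true("normalized" %in% out$provenance)
  expect_identical(reconstruct_query(out, ctx), reconstruct_query(rec, ctx))
  # idempotent
  out2 <- normalize_indel_placement(out, ctx)
  expect_identical(out2$cigar, out$cigar)
  # already on the pathogenic span: untouched
  rec3 <- alignment_record("n2", read, 7L, "2M2D10M")
  expect_identical(normalize_indel_placement(rec3, ctx)$cigar, rec3$cigar)
})

test_that("normalization preserves reconstruction on random tandem contexts", {
  set.seed(34)
  for (rep_i in 1:30) {
    unit_len <- sample(1:3, 1)
    unit <- ora_random_seq(unit_len)
    n_rep <- sample(3:5, 1)
    left <- ora_random_seq(20)
    right <- ora_random_seq(20)
    w <- paste0(left, strrep(unit, n_rep), right)
    e <- 20L                                  # first repeat unit
    ctx <- toy_context(w, e, unit, "")
    # plant the deletion over a later repeat unit
    k <- sample(seq_len(n_rep - 1L), 1)
    dpos <- e + k * unit_len
    read <- paste0(substr(w, 6, dpos), substr(w, dpos + unit_len + 1L,
                                              nchar(w) - 5L))
    cig <- sprintf("%dM%dD%dM", dpos - 5L, unit_len,
                   nchar(w) - 5L - dpos - unit_len)
    rec <- alignment_record("t", read, 5L, cig)
    out <- normalize_indel_placement(rec, ctx)
    expect_identical(reconstruct_query(out, ctx), read)
    expect_identical(out$query, read)
    v <- extract_observed_variants(out, ctx)
    expect_true(any(v$is_pathogenic_match))
    # idempotence
    expect_identical(normalize_indel_placement(out, ctx)$cigar, out$cigar)
  }
})

test_that("observed-variant extraction decomposes alignments", {
  set.seed(35)
  w <- ora_random_seq(300)
  ctx <- toy_context(w, 151L, substr(w, 152L, 153L), "")
  # perfect reference read: empty decomposition
  rec <- alignment_record("p", substr(w, 51, 150), 50L, "100M")
  expect_identical(nrow(extract_observed_variants(rec, ctx)), 0L)

  # planted SNV + DEL + INS recovered exactly
  q <- paste0(substr(w, 41, 80),          # 40M
              "ACGTA",                    # 5I
              substr(w, 81, 120),         # 40M (del of 121..130 follows)
              substr(w, 131, 170))        # 40M
  chars <- strsplit(q, "")[[1]]
  chars[10] <- setdiff(c("A", "C", "G", "T"), chars[10])[1]   # SNV at w[49]
  q <- paste(chars, collapse = "")
  rec2 <- alignment_record("v", q, 40L, "40M5I40M10D40M")
  v <- extract_observed_variants(rec2, ctx, left_align = FALSE)
  expect_identical(v$kind[order(v$pos)], c("SNV", "INS", "DEL"))
  expect_identical(v$pos[v$kind == "SNV"], 49L)
  expect_identical(v$pos[v$kind == "INS"], 80L)
  expect_identical(v$alt[v$kind == "INS"], "ACGTA")
  expect_identical(v$pos[v$kind == "DEL"], 120L)
  expect_identical(v$ref[v$kind == "DEL"], substr(w, 121, 130))
  expect_false(any(v$is_pathogenic_match))

  # pathogenic-matching deletion flagged
  q3 <- paste0(substr(w, 101, 151), substr(w, 154, 200))
  rec3 <- alignment_record("pm", q3, 100L, "51M2D47M")
  v3 <- extract_observed_variants(rec3, ctx)
  expect_identical(nrow(v3), 1L)
  expect_true(v3$is_pathogenic_match)
})

test_that("rewrites conserve the read string and its CIGAR query length", {
  ctx <- make_rescue_window()
  w <- ctx$ref_seq
  reads <- list(
    alignment_record("a", paste0(substr(w, 101, 130), substr(w, 181, 300)),
                     180L, "30S120M"),
    alignment_record("b", substr(w, 151, 260), 150L, "110M"),
    alignment_record("c", paste0(substr(w, 151, 202), substr(w, 205, 260)),
                     150L, "52M2D56M"))
  for (rec in reads) {
    for (fn in list(
      function(r) rescue_soft_clips(r, ctx, min_perfect = 20L),
      function(r) realign_over_pathogenic(r, ctx),
      function(r) normalize_indel_placement(r, ctx))) {
      out <- fn(rec)
      expect_identical(out$query, rec$query)
      expect_identical(cigar_summary(out$cigar)$query_len, nchar(rec$query))
      rec <- out
    }
  }
})
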