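test_that("personalized sequence rewrites the pathogenic allele", {
  # the classic tandem-repeat case: deleting the first GA of ACGAGAT
  dir <- tempfile()
  contig <- paste0("GGGTTT", "ACGAGAT", "TTTGGG")
  fa <- write_toy_fasta(contig, dir)
  # ACGAGAT at 1-based 7..13; the first GA is at 1-based 9..10
  pv <- pathogenic_variant("chrT", 8L, "CGA", "C")   # anchored 2 nt deletion
  ctx <- build_reference_context(fa, pv, window_radius = 4L)
  expect_identical(ctx$ref_seq, substr(contig, 5L, 14L))  # "TTACGAGATT"
  expect_identical(ctx$edit$ref, "GA")
  # personalized window drops the first GA: AC-GAT
  expect_identical(ctx$pers_seq, "TTACGATT")

  # SNV: length preserved, one substituted base
  pv2 <- pathogenic_variant("chrT", 8L, "C", "A")
  ctx2 <- build_reference_context(fa, pv2, window_radius = 5L)
  expect_identical(nchar(ctx2$pers_seq), nchar(ctx2$ref_seq))
  d <- which(strsplit(ctx2$pers_seq, "")[[1]] !=
               strsplit(ctx2$ref_seq, "")[[1]])
  expect_length(d, 1L)

  # guards
  expect_error(build_reference_context(fa, pathogenic_variant("chrX", 7L,
               "AGA", "A")), "contig")
  expect_error(build_reference_context(fa, pathogenic_variant("chrT", 7L,
               "AAA", "A")), "mismatch")
  expect_warning(build_reference_context(fa, pv, window_radius = 50L),
                 "truncated")
})

test_that("deletion round-trip: re-inserting deleted bases restores ref_seq", {
  set.seed(101)
  dir <- tempfile()
  for (rep_i in 1:20) {
    contig <- ora_random_seq(120)
    fa <- write_toy_fasta(contig, dir)
    del_len <- sample(1:10, 1)
    p0 <- sample(30:70, 1)                       # 0-based deletion start
    ref <- substr(contig, p0, p0 + del_len)      # anchored: base at p0-1
    pv <- pathogenic_variant("chrT", p0, ref, substr(ref, 1, 1))
    ctx <- build_reference_context(fa, pv, window_radius = 25L)
    e <- ctx$edit$start
    rebuilt <- paste0(substr(ctx$pers_seq, 1, e), ctx$edit$ref,
                      substr(ctx$pers_seq, e + 1, nchar(ctx$pers_seq)))
    expect_identical(rebuilt, ctx$ref_seq)
    expect_identical(nchar(ctx$pers_seq),
                     nchar(ctx$ref_seq) - nchar(ctx$edit$ref) +
                       nchar(ctx$edit$alt))
  }
})

test_that("coordinate map round-trips over random edits", {
  set.seed(202)
  for (rep_i in 1:100) {
    L <- sample(40:120, 1)
    seq <- ora_random_seq(L)
    kind <- sample(c("DEL", "INS", "SNV"), 1)
    e <- sample(5:(L - 15), 1)
    edit <- switch(kind,
      DEL = list(ref = substr(seq, e + 1, e + sample(1:6, 1)), alt = ""),
      INS = list(ref = "", alt = ora_random_seq(sample(1:6, 1))),
      SNV = list(ref = substr(seq, e + 1, e + 1),
                 alt = setdiff(c("A", "C", "G", "T"),
                               substr(seq, e + 1, e + 1))[1]))
    ctx <- toy_context(seq, e, edit$ref, edit$alt)
    p <- seq_len(L) - 1L
    q <- map_position(ctx, p, "ref2pers")
    ok <- !is.na(q)
    expect_identical(map_position(ctx, q[ok], "pers2ref"), p[ok])
    p2 <- seq_len(nchar(ctx$pers_seq)) - 1L
    q2 <- map_position(ctx, p2, "pers2ref")
    ok2 <- !is.na(q2)
    expect_identical(map_position(ctx, q2[ok2], "ref2pers"), p2[ok2])
    # identity left of the edit; deleted span maps to the sentinel
    if (e > 0) expect_identical(map_position(ctx, e - 1L, "ref2pers"), e - 1L)
    if (kind == "DEL")
      expect_true(all(is.na(
        vapply(e:(e + nchar(edit$ref) - 1L), map_position, integer(1),
               ctx = ctx, direction = "ref2pers"))))
  }
  ctx <- toy_context("ACGTACGT", 2L, "GT", "")
  expect_error(map_position(ctx, 99L), "outside")
})

test_that("homopolymer runs: defaults, maximality, brute-force oracle", {
  runs <- find_homopolymer_runs("TTAAAAAGG", 5L)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$start, 2L)
  expect_identical(runs$end, 7L)
  expect_identical(runs$base, "A")
  expect_identical(nrow(find_homopolymer_runs("ACGT", 5L)), 0L)
  expect_identical(nrow(find_homopolymer_runs("", 5L)), 0L)
  expect_error(find_homopolymer_runs("AAAA", 1L), "min_run")

  set.seed(303)
  for (rep_i in 1:50) {
    s <- ora_random_seq(sample(10:80, 1), alphabet = c("A", "C"))
    mr <- sample(2:6, 1)
    got <- find_homopolymer_runs(s, mr)
    want <- ora_homopolymers(s, mr)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$base, want$base)
    # maximal and non-overlapping
    if (nrow(got) > 1L)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
})

test_that("translate_cds follows the standard code and flags stops", {
  out <- translate_cds("ATGAAATAG")
  expect_identical(out$protein, "MK")
  expect_false(out$premature_stop)
  out2 <- translate_cds("ATGTAAAAA")
  expect_identical(out2$protein, "M")
  expect_true(out2$premature_stop)
  expect_error(translate_cds("AT"), "codon")

  set.seed(404)
  for (rep_i in 1:30) {
    cds <- ora_random_seq(3L * sample(2:40, 1))
    out <- translate_cds(cds)
    expect_identical(out$aa_full, paste(ora_translate(cds), collapse = ""))
  }
})

test_that("translate_with_variants: identity, frame restoration, strands", {
  for (strand in c("+", "-")) {
    g <- toy_gene(strand)
    out <- translate_with_variants(g$tx, g$contig)
    expect_identical(out$protein, g$tx$canonical_protein)
    expect_true(out$same_stop_as_canonical)
    expect_false(out$premature_stop)
    expect_identical(out$stop_pos, g$tx$canonical_stop_pos)

    # 2 nt pathogenic deletion + 4 nt secondary deletion: net -6, restored
    mid <- g$cds_start + 60L
    v2 <- data.frame(pos = c(mid, mid + 10L),
                     ref = c(substr(g$contig, mid + 1, mid + 2),
                             substr(g$contig, mid + 11, mid + 14)),
                     alt = c("", ""))
    out2 <- translate_with_variants(g$tx, g$contig, v2)
    expect_true(out2$frame_intact)
    expect_true(out2$same_stop_as_canonical)

    # pathogenic alone: frameshift, stop lost
    out3 <- translate_with_variants(g$tx, g$contig, v2[1, ])
    expect_false(out3$frame_intact)
    expect_false(out3$same_stop_as_canonical)
  }
})

test_that("an engineered premature stop blocks restoration", {
  # CDS ATG|GTA|ACC|GGG|AAA|CCC|TAA: deleting the G of codon 2 shifts the
  # frame so codon 2 reads TAA -> immediate premature stop.
  body <- "GTAACCGGGAAACCC"
  g <- toy_gene("+", body = body)
  del1 <- data.frame(pos = g$cds_start + 3L, ref = "G", alt = "")
  out <- translate_with_variants(g$tx, g$contig, del1)
  expect_true(out$premature_stop)
  expect_false(out$same_stop_as_canonical)
  expect_identical(out$protein, "M")
  # independent check: translate the mutant CDS with the oracle table
  cds <- paste0("ATG", body, "TAA")
  mutant <- paste0(substr(cds, 1, 3), substr(cds, 5, nchar(cds)))
  aa <- ora_translate(mutant)
  expect_identical(which(aa == "*")[1], 2L)
})

test_that("net indel length not divisible by 3 never keeps the frame", {
  set.seed(505)
  g <- toy_gene("+", n_codons = 60L)
  for (rep_i in 1:25) {
    n_var <- sample(1:3, 1)
    pos <- sort(sample(seq(g$cds_start + 6L, g$cds_start + 150L, by = 12L),
                       n_var))
    vv <- do.call(rbind, lapply(pos, function(p) {
      if (runif(1) < 0.5) {
        l <- sample(1:5, 1)
        data.frame(pos = p, ref = substr(g$contig, p + 1, p + l), alt = "")
      } else {
        data.frame(pos = p, ref = "", alt = ora_random_seq(sample(1:5, 1)))
      }
    }))
    net <- sum(nchar(vv$alt) - nchar(vv$ref))
    out <- translate_with_variants(g$tx, g$contig, vv)
    expect_identical(out$frame_intact, net %% 3L == 0L)
    if (net %% 3L != 0L) expect_false(out$same_stop_as_canonical)
  }
})

test_that("variants outside exons are ignored with a warning", {
  g <- toy_gene("+")
  v <- data.frame(pos = 2L, ref = substr(g$contig, 3L, 3L), alt = "")
  expect_warning(out <- translate_with_variants(g$tx, g$contig, v),
                 "non-coding")
  expect_true(out$same_stop_as_canonical)
})
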