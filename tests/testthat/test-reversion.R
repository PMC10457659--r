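empty_observed <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             kind = character(), is_pathogenic_match = logical(),
             stringsAsFactors = FALSE)
}

obs_row <- function(pos, ref, alt, kind, pm = FALSE) {
  data.frame(pos = pos, ref = ref, alt = alt, kind = kind,
             is_pathogenic_match = pm, stringsAsFactors = FALSE)
}

test_that("read assessment classifies the canonical reversion routes", {
  g <- toy_gene("+", n_codons = 60L)
  e <- g$cds_start + 60L
  pref <- substr(g$contig, e + 1L, e + 2L)
  ctx <- toy_context(g$contig, e, pref, "")

  # pathogenic 2 nt DEL + secondary 4 nt DEL (net -6): candidate
  v <- rbind(obs_row(e, pref, "", "DEL", TRUE),
             obs_row(e + 12L, substr(g$contig, e + 13L, e + 16L), "", "DEL"))
  a <- assess_read("r1", v, ctx, g$tx, g$contig)
  expect_identical(a$category, "reversion_secondary_indel")
  expect_true(a$is_candidate_reversion)
  expect_true(a$outcome$same_stop_as_canonical)

  # empty variant list: reference read, not a candidate
  a2 <- assess_read("r2", empty_observed(), ctx, g$tx, g$contig)
  expect_identical(a2$category, "reference_read")
  expect_false(a2$is_candidate_reversion)

  # pathogenic alone: inactivated, not reverted
  a3 <- assess_read("r3", v[1, ], ctx, g$tx, g$contig)
  expect_identical(a3$category, "not_reverted")
  expect_false(a3$is_candidate_reversion)

  # spanning deletion removing the pathogenic span (net -6): candidate
  sp <- obs_row(e - 2L, substr(g$contig, e - 1L, e + 4L), "", "DEL")
  a4 <- assess_read("r4", sp, ctx, g$tx, g$contig)
  expect_identical(a4$category, "reversion_spanning_deletion")
  expect_true(a4$is_candidate_reversion)

  # net indel not divisible by 3 (-2 - 2 = -4) is never a candidate
  v5 <- rbind(v[1, ],
              obs_row(e + 12L, substr(g$contig, e + 13L, e + 14L), "", "DEL"))
  a5 <- assess_read("r5", v5, ctx, g$tx, g$contig)
  expect_false(a5$is_candidate_reversion)
  expect_false(a5$outcome$frame_intact)
})

test_that("a secondary indel downstream of the induced stop cannot revert", {
  # CDS ATG|GTA|ACC|GGG|AAA|CCC|TAA; deleting the G of codon 2 puts TAA in
  # frame immediately, so a downstream 2 nt deletion (net -3) cannot rescue.
  body <- "GTAACCGGGAAACCC"
  g <- toy_gene("+", body = body)
  e <- g$cds_start + 3L
  ctx <- toy_context(g$contig, e, "G", "")
  v <- rbind(obs_row(e, "G", "", "DEL", TRUE),
             obs_row(e + 6L, substr(g$contig, e + 7L, e + 8L), "", "DEL"))
  a <- assess_read("r", v, ctx, g$tx, g$contig)
  expect_true(a$outcome$frame_intact)          # net -3
  expect_true(a$outcome$premature_stop)
  expect_identical(a$category, "not_reverted")
  expect_false(a$is_candidate_reversion)
})

test_that("a base change within a pathogenic stop-gain can revert", {
  # plant TAC in the CDS; pathogenic SNV C>A creates stop TAA; a read with
  # C>T at the same site (TAT, tyrosine-like substitute) restores coding
  body <- paste0(toy_body(10L), "TAC", toy_body(10L))
  g <- toy_gene("+", body = body)
  cpos <- g$cds_start + 3L + 30L + 2L          # the C of TAC
  expect_identical(substr(g$contig, cpos + 1L, cpos + 1L), "C")
  ctx <- toy_context(g$contig, cpos, "C", "A")
  v <- obs_row(cpos, "C", "T", "SNV")
  a <- assess_read("r", v, ctx, g$tx, g$contig)
  expect_identical(a$category, "reversion_snv")
  expect_true(a$is_candidate_reversion)
})

make_assessment <- function(read_id, observed, category, candidate = TRUE) {
  structure(list(read_id = read_id, observed = observed,
                 carries_pathogenic = any(observed$is_pathogenic_match),
                 outcome = list(frame_intact = TRUE,
                                same_stop_as_canonical = candidate),
                 category = category,
                 is_candidate_reversion = candidate),
            class = "reversion_assessment")
}

test_that("allele aggregation groups, counts and sorts deterministically", {
  w <- paste0(strrep("CG", 20), "AAAAAA", strrep("GC", 20))
  ctx <- toy_context(w, 10L, substr(w, 11L, 12L), "")
  pm <- obs_row(10L, substr(w, 11L, 12L), "", "DEL", TRUE)
  del4 <- obs_row(20L, substr(w, 21L, 24L), "", "DEL")
  del1 <- obs_row(30L, substr(w, 31L, 31L), "", "DEL")

  as_list <- c(
    lapply(1:3, function(i) make_assessment(sprintf("a%d", i),
                                            rbind(pm, del4),
                                            "reversion_secondary_indel")),
    lapply(1:2, function(i) make_assessment(sprintf("b%d", i),
                                            rbind(pm, del1),
                                            "reversion_secondary_indel")),
    list(make_assessment("ref1", empty_observed(), "reference_read",
                         candidate = FALSE)))
  al <- aggregate_alleles(as_list, 100L, ctx)
  expect_length(al, 2L)
  expect_identical(al[[1]]$n_support, 3L)
  expect_equal(al[[1]]$vaf, 0.03)
  expect_identical(al[[1]]$supporting_reads, c("a1", "a2", "a3"))
  expect_identical(al[[2]]$n_support, 2L)
  # partition: every candidate in exactly one allele
  expect_identical(sum(vapply(al, `[[`, integer(1), "n_support")), 5L)
  expect_false(any(duplicated(vapply(al, `[[`, character(1), "key"))))
  # deterministic: same input, same output
  expect_identical(aggregate_alleles(as_list, 100L, ctx), al)
  expect_error(aggregate_alleles(as_list, 0L, ctx), "depth")
})

test_that("variants inside homopolymer runs are flagged", {
  w <- paste0(strrep("CG", 20), "AAAAAA", strrep("GC", 20))
  ctx <- toy_context(w, 10L, substr(w, 11L, 12L), "")
  expect_identical(nrow(ctx$homopolymers), 1L)
  pm <- obs_row(10L, substr(w, 11L, 12L), "", "DEL", TRUE)
  ins_in_run <- obs_row(42L, "", "A", "INS")       # inside the A6 run
  ins_outside <- obs_row(20L, "", "C", "INS")
  al <- aggregate_alleles(list(
    make_assessment("h1", rbind(pm, ins_in_run),
                    "reversion_secondary_indel"),
    make_assessment("h2", rbind(pm, ins_outside),
                    "reversion_secondary_indel")), 10L, ctx)
  flags <- setNames(vapply(al, `[[`, logical(1), "homopolymer_flag"),
                    vapply(al, function(a) a$supporting_reads[1],
                           character(1)))
  expect_true(flags[["h1"]])
  expect_false(flags[["h2"]])
})
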