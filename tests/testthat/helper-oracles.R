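# Independent oracles for property and acceptance tests. These deliberately
# do not reuse the package's own algorithm code paths.

# --- translation oracle: explicit codon lookup -----------------------------

ORA_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

ora_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  aa <- character(n)
  for (k in seq_len(n)) {
    codon <- substr(cds, 3L * k - 2L, 3L * k)
    aa[k] <- if (codon %in% names(ORA_CODON_TABLE)) ORA_CODON_TABLE[[codon]]
             else "X"
  }
  aa
}

# --- homopolymer oracle: brute-force predecessor scan ----------------------

ora_homopolymers <- function(seq, min_run) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- data.frame(start = integer(), end = integer(), base = character(),
                    stringsAsFactors = FALSE)
  i <- 1L
  while (i <= length(chars)) {
    j <- i
    while (j < length(chars) && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_run)
      out <- rbind(out, data.frame(start = i - 1L, end = j,
                                   base = chars[i],
                                   stringsAsFactors = FALSE))
    i <- j + 1L
  }
  out
}

# --- Smith-Waterman oracles ------------------------------------------------

# Pure-R affine-gap local DP implementing the same declared tie-break
# contract as the compiled implementation, coded independently: best cell =
# max score, smallest target end, smallest query end; traceback prefers
# M > D > I, gap-close over gap-extend.
ora_gotoh <- function(query, target, sch) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(t)
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  F_ <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (j in seq_len(n)) for (i in seq_len(m)) {
    sub <- if (q[i] == t[j] && q[i] != "N") sch$match else sch$mismatch
    E[i + 1L, j + 1L] <- max(H[i + 1L, j] + sch$gap_open + sch$gap_extend,
                             E[i + 1L, j] + sch$gap_extend)
    F_[i + 1L, j + 1L] <- max(H[i, j + 1L] + sch$gap_open + sch$gap_extend,
                              F_[i, j + 1L] + sch$gap_extend)
    H[i + 1L, j + 1L] <- max(0, H[i, j] + sub, E[i + 1L, j + 1L],
                             F_[i + 1L, j + 1L])
    if (H[i + 1L, j + 1L] > best) {
      best <- H[i + 1L, j + 1L]; bi <- i; bj <- j
    }
  }
  ops <- character(0)
  i <- bi; j <- bj; state <- "H"
  if (best > 0) repeat {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h <= 0) break
      sub <- if (q[i] == t[j] && q[i] != "N") sch$match else sch$mismatch
      if (h == H[i, j] + sub) {
        ops <- c("M", ops); i <- i - 1L; j <- j - 1L
      } else if (h == E[i + 1L, j + 1L]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      ops <- c("D", ops)
      if (E[i + 1L, j + 1L] ==
          H[i + 1L, j] + sch$gap_open + sch$gap_extend) state <- "H"
      j <- j - 1L
    } else {
      ops <- c("I", ops)
      if (F_[i + 1L, j + 1L] ==
          H[i, j + 1L] + sch$gap_open + sch$gap_extend) state <- "H"
      i <- i - 1L
    }
    if (i == 0L && j == 0L) break
  }
  r <- rle(ops)
  list(score = best, query_start = i, query_end = bi,
       target_start = j, target_end = bj,
       cigar = if (length(ops)) paste0(r$lengths, r$values, collapse = "")
               else "*")
}

# Exhaustive enumeration of every gapped local alignment (no DP, no memo):
# returns the maximum local score. Tractable only for tiny sequences.
ora_enum_score <- function(query, target, sch) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(t)
  go <- sch$gap_open; ge <- sch$gap_extend
  rec <- function(i, j, state) {
    # best score obtainable continuing from (i, j), allowed to stop now
    best <- 0
    if (i < m && j < n) {
      sub <- if (q[i + 1L] == t[j + 1L] && q[i + 1L] != "N") sch$match
             else sch$mismatch
      best <- max(best, sub + rec(i + 1L, j + 1L, 0L))
    }
    if (j < n) {
      cost <- if (state == 1L) ge else go + ge
      best <- max(best, cost + rec(i, j + 1L, 1L))
    }
    if (i < m) {
      cost <- if (state == 2L) ge else go + ge
      best <- max(best, cost + rec(i + 1L, j, 2L))
    }
    best
  }
  best <- 0
  for (i0 in 0:(m - 1L)) for (j0 in 0:(n - 1L))
    best <- max(best, rec(i0, j0, 0L))
  best
}

# --- random generators -----------------------------------------------------

ora_random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

ora_random_cigar <- function() {
  ops <- c("M", "I", "D", "S", "N")
  n <- sample(1:8, 1)
  kinds <- sample(ops, n, replace = TRUE)
  # canonical form: merge adjacent repeats so render(parse(x)) == x holds
  keep <- c(TRUE, kinds[-1] != kinds[-n])
  kinds <- kinds[keep]
  lens <- sample(1:200, length(kinds), replace = TRUE)
  paste0(lens, kinds, collapse = "")
}
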