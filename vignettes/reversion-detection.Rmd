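---
title: "Detecting reversion mutations by pathogenic-variant-aware realignment"
author: "revertscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reversion mutations by pathogenic-variant-aware realignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revertscan)
```

## The problem

Tumors arising in carriers of pathogenic *BRCA1/2* alleles are homologous-
recombination deficient and respond to PARP inhibitors and platinum. Under
that selective pressure, subclones carrying *reversion mutations* — secondary
events that restore the inactivated gene's reading frame — expand and confer
resistance. Reversion alleles have two properties that defeat standard
variant calling:

* they sit at low variant allele frequency (typically 1–5% in circulating
  tumor DNA), so few reads support any one allele; and
* the reads that carry them are systematically *misaligned*: a general-purpose
  aligner scores the read against the plain reference, where the combination
  of the patient's germline indel plus the somatic reversion indel is more
  cheaply explained as mismatches, a mis-placed gap, or a soft-clipped read
  end.

revertscan exploits the one piece of prior knowledge a caller normally lacks:
the patient's pathogenic variant is *known*. Analysis is confined to a window
around that locus (genome-wide realignment would be prohibitively expensive
and is pointless — reversions can only exist near the lesion they revert),
and the aligner's decisions are re-litigated there.

## The procedure

For each pathogenic variant in the input VCF, `run_pipeline()` applies five
stages to every read overlapping the window:

1. **Soft-clip rescue** (`rescue_soft_clips`). Each terminal soft-clip is
   Smith-Waterman aligned against the whole window. If the best placement
   contains a run of at least `min_perfect` (default 20) exactly matched
   bases on the correct side of the anchored alignment, the clip is converted
   to aligned ops, joined to the anchor by the implied deletion (and/or
   insertion). This recovers large-deletion reversions that aligners report
   only as clipped read ends.
2. **Personalized realignment** (`realign_over_pathogenic`). The window is
   rewritten to carry the pathogenic allele (the *personalized reference*)
   and the read is locally realigned against it with an indel-lenient scheme.
   The new alignment is accepted only when every aligned base matches the
   personalized sequence exactly — additional indels are permitted (they are
   the candidate reversions), base mismatches are not — and the clipped base
   count does not grow. Accepted alignments are lifted back to reference
   coordinates through the window↔personalized coordinate map, re-expressing
   the pathogenic edit as explicit D/I ops.
3. **Indel-placement normalization** (`normalize_indel_placement`). When the
   pathogenic indel sits in a tandem-repeat context (reference `ACGAGAT`,
   deletion of the first `GA`), aligners may place a sequence-equivalent gap
   over the neighbouring repeat unit. If relocating such an indel onto the
   pathogenic span implies the identical read sequence, the CIGAR is
   rewritten to the genetically plausible placement. The operation is
   idempotent and reconstruction-preserving.
4. **Decomposition and translation** (`extract_observed_variants`,
   `assess_read`). The final CIGAR is decomposed into SNVs/insertions/
   deletions (indels left-aligned, pathogenic identity decided by
   left-aligned sequence equivalence), the transcript is rewritten with the
   read's variants, spliced (reverse-complemented for minus-strand genes such
   as *BRCA1*) and translated. A read is a candidate reversion iff the
   realized protein is intact and terminates at the *same genomic stop codon*
   as the canonical transcript. Because any premature stop forfeits that
   condition, mutations downstream of an introduced stop gain can never
   rescue a read.
5. **Aggregation** (`aggregate_alleles`). Candidate reads are grouped by the
   sorted `pos:ref>alt` string of their non-pathogenic variants. Each allele
   reports its supporting reads, VAF (support / non-duplicate reads covering
   the pathogenic position after realignment), and a homopolymer flag when
   any variant intersects a run of ≥ `min_homopolymer` (default 5) identical
   bases — the classic Illumina indel-artifact context.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_radius` | 500 nt | window half-width; small reversion indels sit within ~200 nt of the pathogenic site, 500 adds margin at negligible cost |
| `min_perfect` | 20 nt | perfect-match run required to rescue a soft clip; long enough to be near-unique in a ≤ 1 kb window |
| `min_homopolymer` | 5 | shortest homonucleotide run flagged as artifact-prone |
| scoring | +2 / −3 / −2 / −0.5 | match / mismatch / gap open / per-base gap extend; one 2–4 nt gap is preferred over two mismatches, which is what makes end-crossing germline indels realignable |
| `include_duplicates` | FALSE | duplicate-flagged reads are excluded from evidence and depth |
| `min_mapq` | 0 | no mapping-quality filter by default — reversion-bearing reads may map poorly |

Gap cost is `gap_open + L × gap_extend`. All scores are multiples of 0.5, so
floating-point comparisons in the dynamic program are exact.

## Numerical and design choices

* **Determinism.** There is no randomness anywhere in alignment or calling.
  Smith-Waterman ties are broken by: best cell with smallest target end then
  smallest query end; traceback preferring match over deletion over
  insertion, which left-aligns indels. The same contract is implemented
  independently in pure R in the test suite and checked on >10⁴ random pairs.
* **Tie-breaking vs. clipping.** Under the default scheme, a 2 nt gap (cost
  3) is more expensive than abandoning a single trailing match (cost 2); on
  very short sequences the optimal local alignment may therefore clip rather
  than gap. In pipeline context reads carry long anchors on both sides, and
  personalized-realignment acceptance additionally refuses alignments that
  increase clipping.
* **Coordinates.** 0-based half-open everywhere internally; VCF and SAM
  positions are converted at I/O boundaries. VCF anchored indels are
  normalized to anchor-free edits (shared prefix, then shared suffix,
  trimmed).
* **Canonical-stop comparison.** Restoration is judged by the genomic
  position of the realized stop codon's first base (transcript orientation),
  the strictest reading; protein length alone would accept alleles that move
  the stop.
* **Realignment trigger.** A read is realigned when it overlaps the
  pathogenic span and shows a mismatch, a residual soft clip, or an indel
  that does not already encode the pathogenic allele. A read that matches
  the plain reference perfectly is never displaced: without that guard, a
  wild-type read would "match" the personalized genome via a spurious
  compensating insertion.
* **Degenerate inputs.** A window extending past a contig end is truncated
  with a warning, never shifted. Ambiguity codes other than N are rejected at
  load; N never counts as a match nor as variant evidence. Reads not fully
  contained in the window are dropped (and counted): with the default radius
  every read covering the locus is contained.

## What the synthetic data does and does not establish

`generate_fixture()` builds a toy single-exon gene on a ~1.2 kb contig with a
pathogenic variant at the CDS midpoint and planted reversion alleles, then
emits FASTA/VCF/transcript/SAM/truth-JSON. Design choices, fixed once:

* **Initial alignments are earned, not scripted**: each simulated read is
  aligned to the plain reference by Smith-Waterman under a stringent
  bwa-mem-like scheme (+1/−4/−6/−1). Reads whose ends cross the pathogenic
  indel therefore come out with exactly the pathology the method targets —
  mismatch-encoded deletions, mis-placed gaps, soft-clipped tails — without
  hand-writing CIGARs. (The classic worked example, `make_fig1b_case()`, is
  the exception: its `10M1D140M` record is constructed byte-for-byte.)
* **T-free coding body.** The toy CDS body uses only A/C/G codons, so no
  reading frame can contain a stop codon: frame arithmetic alone decides
  whether the canonical stop is restored. This isolates the indel logic;
  premature-stop behaviour is exercised separately on hand-engineered CDSs.
* **Anchoring.** Planted reads cover every indel junction with ≥ 25 nt
  (background reads ≥ 10 nt), above the 20 nt rescue threshold. Reads
  anchored below the threshold are undetectable by construction — the
  method's own stated limit, not the simulator's job to hide.
* **Errors are substitutions only** (default rate 0; the demonstration
  fixture uses 10⁻³), isolating indel logic from noise-model confounds.

A green test on these fixtures establishes that the realignment/translation/
aggregation machinery recovers planted truth through realistic misalignment;
it does not establish performance on real cfDNA (fragment-length structure,
quality-correlated errors, mapping ambiguity in segmental duplications are
all absent), nor splice-site reversions, nor multi-isoform genes — all out of
scope.

## Known limitations

* One transcript model per run; no isoform handling, no splice-site
  reversion annotation.
* Paired-end mate information is unused; base qualities do not inform the
  alignment score.
* Genome-wide scanning is out of scope by design; the method requires the
  pathogenic variant as input.
* Translation treats the rest of the transcript as reference: compound
  haplotypes outside the read are invisible.
* A read whose error SNV left-aligns an indel onto another variant is
  assessed conservatively (translation failure ⇒ not a candidate); this is
  logged as a warning.
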