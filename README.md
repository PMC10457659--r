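# revertscan

Automatic detection of **reversion mutations** — the secondary events that
restore the reading frame of a DNA-repair gene inactivated by a known
pathogenic variant (classically a germline frameshift deletion in
*BRCA1/2*), and the dominant mechanism of acquired resistance to PARP
inhibitors and platinum therapy.

## Why a dedicated tool

Reversion alleles appear at 1–5% variant allele frequency in circulating
tumor DNA, and the reads that carry them are systematically misaligned:
against the plain reference, the combination of the germline indel plus the
somatic reversion indel is more cheaply explained as mismatches, a mis-placed
gap, or a soft-clipped read end. Standard callers therefore miss them.

revertscan exploits the prior knowledge that the pathogenic variant exists.
Within a window around it (default ±500 nt), each read is:

1. **soft-clip rescued** — clipped ends are Smith-Waterman aligned back into
   the window (accepted on a ≥ 20 nt perfect-match run), recovering
   large-deletion reversions;
2. **realigned against a personalized reference** — the window rewritten to
   carry the pathogenic allele — under indel-lenient scoring
   (+2/−3 mismatch/−2 gap open/−0.5 per-base extend); accepted only on a
   perfect base-level match (extra indels allowed: they are the candidate
   reversions);
3. **normalized** — sequence-equivalent indel placements are moved onto the
   pathogenic span (the `ACGAGAT` / `AC-GAT` tandem-repeat ambiguity);
4. **translated** through the transcript model (minus-strand genes
   supported): a read is a candidate reversion iff the rewritten transcript
   yields an intact protein ending at the *same stop codon* as the canonical
   one, i.e. net coding indel ≡ 0 (mod 3) and no premature stop;
5. **aggregated** into distinct reversion alleles keyed by their
   (left-aligned) non-pathogenic variants, each reported with supporting
   reads, VAF = support / depth at the pathogenic position, and a flag for
   variants inside homopolymer runs (≥ 5 nt by default), a common sequencing
   artifact context.

Inputs: reference FASTA, pathogenic variant(s) as VCF, aligned reads as
BAM (or SAM text), and a transcript model (GTF/GFF3 or a 6-column TSV).
Outputs: `alleles.tsv` + `supporting_reads.tsv` per variant, and a lollipop
allele map.

## Worked example

The package ships a deterministic generator for the classic end-crossing
misalignment: a 150 nt read spanning a germline 2 nt coding deletion plus a
1 nt somatic deletion, initially aligned as `10M1D140M` with the germline
deletion hidden as a mismatch — an alignment in which no frame-restoring
event is visible.

```r
library(revertscan)
fx  <- make_fig1b_case("scratch/fig1b")
cfg <- run_config(fx$paths$sam, fx$paths$vcf, fx$paths$fasta,
                  fx$paths$transcript)
rep <- run_pipeline(cfg, keep_reads = TRUE)[[1]]
render_cigar(rep$records[[1]]$cigar)
print(rep)
```

prints

```
[pathogenic1] reads=1 rescued=0 realigned=1 normalized=0 depth=1 candidates=1 alleles=1
corrected CIGAR: 4M2D6M1D140M
<reversion report for pathogenic1: 1 reads, depth 1, 1 allele(s)>
<allele 612:G>-: reversion_secondary_indel, support=1, vaf=1.0000>
```

The alignment is corrected to `4M2D6M1D140M`: the 2 nt germline deletion is
restored to its own span, the extra 1 nt deletion (`612:G>-`, three deleted
bases in total, net −3) restores the reading frame, and the read is reported
as one supporting read of a frame-restoring reversion allele.

At scale, `demo_fixture_spec()` plants ten distinct reversion alleles
(secondary deletions/insertions and spanning deletions) at 1–4.6% VAF over
1000× depth with 10⁻³ substitution errors; the pipeline recovers exactly the
ten planted allele keys with no spurious allele at support ≥ 2 (see
`tests/testthat/test-acceptance.R`).

## Command line

```sh
exec/revertscan --bam reads.bam --vcf pathogenic.vcf --fasta ref.fa \
    --transcript tx.tsv [--window 500] [--min-perfect 20] \
    [--min-homopolymer 5] [--keep-duplicates] [--min-mapq 0] --out outdir
```

Exit code 0 on success, including runs that find zero reversion alleles.

## Scope

Preprocessing (alignment, duplicate marking, sorting/indexing) is assumed
done upstream. Out of scope: genome-wide scanning, transcript retrieval from
Ensembl, isoform handling, splice-site reversions, paired-end mate rescue,
base-quality-aware scoring.
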