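Package: revertscan
Title: Reversion Mutation Detection by Pathogenic-Variant-Aware Local Realignment
Version: 0.1.0
Authors@R:
    person("Riley", "Stanton", email = "riley.stanton@example.org",
           role = c("aut", "cre"))
Description: Detects reversion mutations that restore the reading frame of a
    gene inactivated by a known pathogenic variant (for example a germline
    frameshift deletion in BRCA1/2), a common mechanism of resistance to PARP
    inhibitors and platinum therapy. Reads near the pathogenic locus are
    re-examined with soft-clip Smith-Waterman rescue, local realignment
    against a personalized reference rewritten to carry the pathogenic allele,
    and indel-placement normalization. Each corrected read is translated
    through a transcript model to decide whether its variants restore an
    intact protein ending at the canonical stop codon, and candidate reads are
    aggregated into distinct reversion alleles with supporting-read reports,
    variant allele frequencies, homopolymer flags and a lollipop plot. A
    deterministic synthetic-data generator produces FASTA/VCF/SAM/transcript
    fixtures with planted reversion alleles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
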