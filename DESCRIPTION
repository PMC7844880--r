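Package: seqsentry
Title: Rapid Quality Control of Raw Sequencing Reads via a Variant-Centric Reduced Reference
Version: 0.1.0
Authors@R: person("seqsentry", "developers", email = "seqsentry@example.org", role = c("aut", "cre"))
Description: Fast quality assessment of raw short-read sequencing data without
    full-genome alignment. Builds a reduced reference genome from flanking
    sequences of known common SNPs, filters unalignable reads with a
    mismatch-tolerant spaced 16-of-32 k-mer hash, aligns the surviving reads
    with a seed-and-extend mini-aligner, and derives base-, read- and
    variant-level QC metrics: quality-by-cycle, empirical base quality, GC
    bias, depth, PCR duplicate rate, a censoring-corrected (Kaplan-Meier)
    insert-size distribution, genotype likelihoods at panel markers, and
    likelihood-based estimates of DNA contamination and genetic ancestry from
    an SVD allele-frequency panel. Includes a fully deterministic read
    simulator used as the test bed for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    Rsamtools,
    VariantAnnotation
Config/testthat/edition: 3
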