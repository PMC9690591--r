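Package: cnvpopscan
Title: Population Genomics of Copy-Number Variants: Merging, QC,
    Fst Selection Scans and Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of copy-number
    variants (deletions, duplications, insertions) genotyped across a
    cohort. Provides group-level de-redundancy of structural-variant
    calls by reciprocal overlap and genotype concordance, site-level
    quality control including an exact one-sided excess-heterozygosity
    test, per-variant Wright's Fst between two populations with a
    top-percentile selection scan, gene-model-based annotation of
    variants, allele-frequency spectra, principal component analysis and
    neighbor-joining trees from genotype dosages, and a Balding-Nichols
    two-population simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
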