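Package: aseasb
Title: Allele-Specific Expression and Binding Analysis Across Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting allele-specific expression (ASE) and
    allele-specific ChIP-seq binding (ASB) from heterozygous SNPs in a
    pedigreed multi-tissue design. Builds a mapping-bias-masked reference by
    substituting a neutral allele at heterozygous sites, assigns parent of
    origin from sire (and dam) genotypes with a phase-linkage fallback,
    applies SNP-level count filters, combines SNPs per feature with an s x 2
    G-test of homogeneity, tests per-sample allelic imbalance against 1:1
    with a 1-df chi-square, quantifies cross-tissue heterogeneity with the
    same G-test, calls consensus peaks supported by at least two samples,
    correlates peak height with exon expression in counts per million within
    a stranded 100 kb window, and compares the direction of ASB and ASE in
    correlated peak-exon pairs. Includes a synthetic-data generator that
    reproduces the statistical structure of such a study so that every stage
    is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
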