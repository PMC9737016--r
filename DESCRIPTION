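Package: rohscan
Title: Runs of Homozygosity and Genomic Diversity Analysis for SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for population-genomic analysis of multi-sample diploid
    SNP panels: VCF ingestion with population-level site filters (minor
    allele frequency, missingness, exact Hardy-Weinberg test, site quality),
    per-site nucleotide diversity and observed heterozygosity, the GCTA-style
    genomic relationship matrix, sliding-window detection of runs of
    homozygosity (ROH), ROH-based inbreeding coefficients (F_ROH), calling
    of ROH islands (regions where ROH pile up across individuals), gene
    annotation of islands, and a seeded simulator that generates genotype
    panels with planted autozygous tracts and exported ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
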