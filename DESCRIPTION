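Package: capsimark
Title: Transcriptome-Based SNP and SSR Marker Discovery for Pepper
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of an in silico marker
    discovery pipeline for Capsicum transcriptome assemblies. Provides two
    SNP callers (a three-genotype pileup caller with a two-out-of-three
    homozygote rule, and an EST-alignment consensus caller), the associated
    distance and depth filters (splice-junction, adjacent-SNP, heterozygote
    and contig-end rules), MISA-style microsatellite (SSR) scanning with
    compound-motif merging and Primer3 task generation, 101-nt flanking
    window cross-assembly marker comparison, and assembly summary statistics
    (N50, GC content, size bins, marker density). A synthetic-data module
    generates transcript contigs for three near-isogenic homozygous
    genotypes with planted SNPs, heterozygous positions, SSRs, exon-exon
    junctions and Phred-scored short reads, plus a naive seed-and-extend
    mapper, so the whole pipeline is testable without external read sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
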