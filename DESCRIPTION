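Package: mosaicx
Title: Mosaic Allele-Resolved Single-Nucleus Transcriptomic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for allele-resolved single-nucleus 5' RNA-seq
    of X-linked mosaic tissue. Genotypes individual cells at a 100 bp locus
    from barcoded reads by local alignment and start-codon enumeration
    (ATG wild type versus TTG mutant), applies quality-control filters and
    reference-signature cell-type annotation, runs negative-binomial
    differential expression over a mosaic-stratified contrast design with
    equal-size downsampling and Benjamini-Hochberg correction, performs
    Fisher exact gene-set enrichment with odds ratios and exclusive (UpSet)
    intersections, detects signed co-expression modules with eigengenes,
    hub genes and module-trait correlations, and intersects differential
    expression across species through curated ortholog maps. A synthetic
    data generator emulates the statistical structure of a two genotype by
    two treatment mosaic cortex study so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    Matrix,
    Rcpp,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
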