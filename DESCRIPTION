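Package: qtlallele
Title: QTL-Allele System Analysis for Inbred Germplasm Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissects a quantitative trait into a multi-allelic QTL-allele
    system in a selfing germplasm population using a restricted two-stage
    multi-locus association approach: CV-weighted plot phenotype scoring,
    variance components and broad-sense heritability from expected mean
    squares, multi-allelic SNP linkage-disequilibrium-block (SNPLDB) marker
    construction, a two-stage multi-locus scan with QTL-by-environment terms
    under heritability control, QTL-allele matrix assembly, in-silico cross
    prediction by recombinant inbred progeny simulation, allele-frequency
    differentiation across resistance groups, and window/chi-square
    candidate-gene annotation.  Includes a synthetic-data generator that
    emulates a multi-environment soybean landrace antixenosis trial and
    packaged reference tables for regression testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
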