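Package: aneuvol
Title: Analysis Pipeline for Long-Term Experimental Evolution of Disomic Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse long-term experimental evolution of aneuploid
    (disomic) yeast populations: copy-number and karyotype-change inference
    from windowed read coverage, de novo mutation cataloguing from dual
    variant-caller call sets with ancestor subtraction and allele-fraction
    filters, apparent mutation rates with standard errors, composition
    normalised mutational spectra and signature similarity, localization
    binomial tests, an RNA-seq pipeline computing the expression shift
    towards the euploid wild type, doubling-time estimation from plate-reader
    growth curves, and a fully parameterised synthetic-data generator with
    ground-truth records for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer
Config/testthat/edition: 3
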