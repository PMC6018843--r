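Package: fuzzmap
Title: Bulk Segregant Mapping and Dosage Modelling of Recessive Seed-Fuzz Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genetic dissection of recessive, multilocus seed-coat fibre
    (fuzz) traits in allotetraploid cotton crosses. Provides pooled-bulk
    allele-frequency scanning with overlapping sliding windows and
    dual-bulk candidate-region calling, goodness-of-fit testing and model
    selection over k-recessive-gene Mendelian segregation models,
    single-marker association of genotype classes with fuzz percentage
    (with enhancer/suppressor/additive effect classification), homoeolog
    expression bookkeeping with a two-threshold dosage classifier of seed
    fibre phenotypes, and a seeded simulator of F2 and backcross-derived
    near-isogenic populations with pooled sequencing read counts, so the
    whole workflow can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
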