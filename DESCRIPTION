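Package: regpot
Title: Context-Dependent Regulatory Potential of Genetic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the regulatory potential of genetic variants from
    cell-type-specific chromatin features (peak hit, intensity and summit
    centrality for DNase and eleven histone marks), trains tissue-specific and
    generalized logistic models with backward stepwise AIC feature selection,
    fuses the resulting context-dependent potential with context-free
    functional prediction scores into a combined posterior probability, and
    uses that probability to weight SNPs in a Simes-type (GATES) gene-based
    association test and in permutation-based GWAS signal-enrichment analyses.
    Includes matched control-SNP samplers, cell-type specificity mapping, a
    synthetic fixture generator with planted ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
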