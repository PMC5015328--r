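Package: polarseq
Title: Two-Sided Regeneration Time-Course RNA-Seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq time courses sampled on two
    sides of a bisected animal (oral and physal/aboral regeneration in a
    cnidarian): median-of-ratios normalization, a negative-binomial GLM
    likelihood-ratio screen for time-responsive genes with
    Benjamini-Hochberg correction, Lin's concordance correlation
    coefficient for calling side-specific (polarized) genes,
    fold-change trend taxonomy, hierarchical and model-profile clustering
    of expression dynamics, and hypergeometric category enrichment.
    Includes a negative-binomial count simulator with planted gene classes
    and full ground truth for validating every stage.
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
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    DESeq2
Config/testthat/edition: 3
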