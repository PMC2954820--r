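Package: hipred
Title: Predicting Haploinsufficiency from Gene Properties and Scoring Deletion Pathogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies haplosufficient genes from deletion copy-number
    variants in healthy individuals via explicit loss-of-function rules,
    trains a linear discriminant model on genomic, evolutionary, functional
    and network properties to assign every predictable gene a probability of
    exhibiting haploinsufficiency, and converts those gene probabilities into
    deletion-level log-odds (LOD) pathogenicity scores judged against an
    empirical control distribution. Includes exact small-sample statistical
    kernels, predictive-mean-matching imputation, repeated cross-validation,
    enrichment tests, and a synthetic-data module that generates every input
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
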