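Package: stromage
Title: Age-Related Gene Expression Analysis of the Breast Tumour Stroma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression and gene set enrichment analysis of
    tumour-associated stroma profiled in young versus old patients. Implements
    signed fold-change differential expression between age groups with Wilcoxon
    rank-sum p-values, a running-sum gene set enrichment score with a
    permutation null and Benjamini-Hochberg FDR over curated senescence, DNA
    damage response, SASP and autophagy gene programmes, direction-stratified
    cross-dataset overlap validation with hypergeometric significance, probe to
    gene-symbol collapsing for normalized microarray matrices, a synthetic-data
    generator with known ground truth, and an end-to-end pipeline driven by a
    single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
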