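Package: pathsig
Title: Gene-Pathway Bipartite Network Scoring for Robust Cancer Prognosis Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes differentially expressed genes (DEGs) for cancer
    prognosis classification by re-scoring them with a two-step weighted
    projection of a gene-pathway bipartite network built over cancer-related
    KEGG pathways. Genes spread a unit resource equally over their pathways
    and pathways return the accumulated weight equally to their member genes;
    DEGs whose returned score reaches a threshold form the classifier
    signature. The package covers the full workflow: probeset-to-gene
    collapsing, pooled-variance t-test and fold-change DEG selection,
    survival milestone dichotomization, bipartite network construction and
    scoring, RBF-kernel support-vector classification with leave-one-out
    cross-validated grid search, paired original/swap robustness analysis,
    and a seeded synthetic-data generator that emulates two-class microarray
    studies with planted pathway-aligned signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
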