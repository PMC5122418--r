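Package: smirnet
Title: Small Molecule-miRNA Association Networks from Functional Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts associations between small molecules and microRNAs by
    comparing the biological functions perturbed by each. Differentially
    expressed gene signatures (SAM-style permutation testing, fold-change
    majority rules, and the Connectivity-Map amplitude statistic) are
    summarised as enriched ontology terms via an elim-style Fisher test, and
    entity pairs are scored with Lin term similarity under a best-match-average
    combination over a structural information-content model of the ontology.
    High-scoring pairs form a bipartite association network after thresholding
    at an upper normal quantile of the score distribution. Downstream tools
    evaluate predictions with permutation-null ROC curves, reposition drugs to
    diseases by hypergeometric enrichment of shared miRNAs, and stratify
    patient cohorts by K-means clustering of miRNA expression with log-rank
    survival comparison. A synthetic-data module generates ontologies,
    expression matrices, association scenarios and survival cohorts with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
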