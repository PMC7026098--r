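Package: cnvpheno
Title: Genotype-Phenotype Subgroup Discovery from Clinical Measures and
    CNV-Disrupted Biological Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for heterogeneous neurodevelopmental
    cohorts: clusters individuals into phenotypic subgroups from
    mixed-type clinical measures (weighted Gower distance, Ward2
    agglomeration, silhouette-based pruning, bootstrap Jaccard
    stability), maps rare high-confidence copy-number variants to
    brain-expressed genes, identifies disrupted Gene Ontology biological
    processes by hypergeometric enrichment with Benjamini-Hochberg
    correction and SimRel semantic-similarity redundancy reduction, and
    predicts the phenotypic subgroups from the binary process profiles
    with an information-content-stratified Bernoulli Naive Bayes
    classifier.  Includes a synthetic-cohort generator so every stage is
    testable without access to consortium-held data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    IRanges,
    S4Vectors,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    e1071,
    knitr
Config/testthat/edition: 3
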