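Package: neuromethyl
Title: Neural-Related Promoter Hypermethylation Analysis for Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls promoter hyper- and hypomethylated genes from Illumina
    450k-style beta-value matrices using empirical-Bayes moderated
    t-statistics on M-values, flags neural-related genes by substring
    matching of Gene Ontology term names, and quantifies the enrichment of
    neural-related genes among hypermethylated genes against the array
    background.  Includes the accompanying confounder analyses (tumor-purity
    robust regression, methylation-degree comparison, bivalent-chromatin
    cross-tabulation, cancer-hallmark enrichment), a differential-expression
    stage with optional precision weights for identifying neural
    differentiation-associated genes, overlap statistics linking
    hypermethylation to differentiation and downregulation, and a seeded
    synthetic-data generator with planted ground truth so every stage can be
    validated against a recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
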