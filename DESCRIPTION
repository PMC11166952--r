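Package: mbassoc
Title: Two-Stage Host Gene-Microbiome Association and Cross-Signature
    Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for associating host pseudo-bulk gene expression with
    microbial abundance profiles in small longitudinal cohorts. Implements a
    two-stage procedure (a LASSO screen over all microbial features of a
    taxonomic domain and rank, followed by per-pair random-intercept mixed
    models with a family-wise Bonferroni scheme), randomized-data null
    comparisons, per-cell-type association tallies and gene rankings,
    preranked gene-set enrichment with permutation or exact enumeration
    nulls, Fisher and hypergeometric set-overlap statistics, and a
    compound-gene interactome enrichment screen. A synthetic-cohort
    generator with planted gene-microbe effects, compounds and pathways
    makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    lme4,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
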