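Package: tsescore
Title: T-Cell-to-Stroma Enrichment Scoring for Immunotherapy Response
Version: 0.1.0
Authors@R: person("TSE", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computes the T-cell-to-stroma enrichment (TSE) score from
    normalized bulk RNA-seq expression and curated gene signatures, together
    with its protein-level analog from immunofluorescence marker
    quantifications, genomic covariate classifiers (tumor mutational burden,
    APOBEC enrichment class, clonal mutation fraction), T-cell receptor
    repertoire summaries (clonotype size classes, Hill diversity), and the
    evaluation statistics used to benchmark predictors of immune-checkpoint
    inhibitor response (midrank ROC/AUC, DeLong comparison of correlated
    AUCs, Fisher's exact test, rank tests, Benjamini-Hochberg adjustment,
    logistic regression, Kaplan-Meier/log-rank/Cox survival analysis). A
    synthetic cohort generator with planted three-group structure makes the
    full pipeline testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
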