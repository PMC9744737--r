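Package: csfseverity
Title: CSF Proteomic Models of Multiple Sclerosis Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for modeling multiple sclerosis (MS) severity
    from cerebrospinal fluid (CSF) aptamer proteomics (SomaScan-style relative
    fluorescence units). Implements healthy-volunteer-anchored age and sex
    adjustment of analyte panels via a two-tier screen against an external
    serum reference, an elastic-net proteomic aging clock with delta-age group
    contrasts, construction of a brain-volume-deficit severity outcome and
    one-way intraclass correlation of longitudinal severity, univariate
    Spearman/FDR severity screens with enrichment-ready ranked exports,
    pairwise ratio feature expansion with random-forest backward elimination
    by averaged node-impurity importance and an out-of-bag error cut,
    independent-cohort evaluation (Spearman, R-squared, Lin's concordance),
    and unsupervised heterogeneity analysis (protein modules and patient
    clusters). Includes a synthetic cohort generator with planted ground truth
    so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
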