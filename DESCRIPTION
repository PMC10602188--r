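Package: stabvar
Title: Protein Stability Change and Missense Variant Pathogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links predicted protein folding free-energy change (ddG) and relative
    solvent accessibility (RSA) to the pathogenicity of missense variants in
    monogenic disease genes. Provides curation of ClinVar-style variant tables
    (conflict exclusion, allele-frequency filter, per-gene 10 percent rule),
    physicochemical substitution annotation, threshold-calibrated evaluation
    (ROC/AUC by pairwise concordance, MCC-optimal cutoffs, balanced resampling),
    a two-feature regularized logistic classifier with repeated cross-validated
    hyperparameter selection, an in-silico saturation mutagenesis driver with a
    pluggable ddG scorer, and a synthetic-data generator with known ground truth
    so every stage is testable without external predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    optparse
Config/testthat/edition: 3
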