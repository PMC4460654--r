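Package: narrafact
Title: Matrix-Factorization Classification of Injury Narrative Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatically assigning external-cause and major-injury-factor
    codes to short free-text injury narratives, of the kind recorded at emergency
    department triage. Provides a narrative-specific preprocessing chain (punctuation
    stripping, abbreviation canonicalization, phrase protection, soundalike spelling
    correction, stop-word removal, Porter stemming), a two-component Gaussian-mixture
    EM cutoff for vocabulary pruning, truncated SVD and non-negative matrix
    factorization of the document-term matrix with out-of-sample projection,
    memory-based (cosine nearest-neighbour) and model-based latent-space classifiers,
    cross-code one-hot feature augmentation ("learning enhancement"), a medical-domain
    evaluation battery (per-class sensitivity, specificity, PPV, Cohen's kappa,
    one-vs-rest ROC AUC, stratified cross-validation), and a seeded generator of
    synthetic injury-narrative corpora for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
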