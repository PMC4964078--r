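Package: prognode
Title: Lymph-Node-Stratified Evaluation of Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: In-silico scoring and survival evaluation of breast-cancer
    prognostic gene signatures (a recurrence-score style weighted-group
    index, an intrinsic-subtype correlation risk-of-recurrence score, and a
    directional mean-Z index discovered by nearest shrunken centroids),
    stratified by lymph-node status. Includes cohort preparation
    (Z-standardization, HER2 mixture calls, ER+/HER2- filtering, probe
    collapse), Cox/concordance/Kaplan-Meier evaluation, a phenotype-permutation
    gene-set enrichment engine, and a synthetic ER+/HER2- cohort generator
    with lymph-node-dependent hazard effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
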