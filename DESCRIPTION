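Package: dysreg
Title: Gene Dysregulation Analysis for Prognostic and Therapeutic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for differential gene regulation (dysregulation)
    analysis from two-condition transcriptomes. Builds a motif-based
    reference regulatory network by scanning promoter sequences with
    position weight matrices and exact score p-values, prunes it per
    condition with random-forest shadow-feature selection, quantifies each
    link's regulatory intensity with de-biased sparse regression confidence
    intervals, calls dysregulations by integrating interval disjointness,
    target differential expression and direction consistency, screens their
    prognostic effect against randomized controls with Cox models, and
    greedily assembles a compact dysregulation signature that predicts
    survival and treatment benefit. Includes a synthetic-data generator
    with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    survival,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
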