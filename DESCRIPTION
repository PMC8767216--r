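Package: canalcrit
Title: Canalization and the Critical Dynamics of Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how canalization determines the dynamical
    regime of Boolean networks. Implements Boolean automata as look-up
    tables, wildcard-schema redescription (prime implicants) and the
    effective connectivity measure of canalization, construction of random
    Boolean network ensembles controlled by in-degree, output bias and
    binned effective connectivity, estimation of the Derrida parameter to
    label networks as ordered or chaotic, and logistic-regression fits of
    candidate criticality boundaries (structural versus canalization-based)
    with nested cross-validation, Matthews correlation, AUC and McFadden
    pseudo-R-squared scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
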