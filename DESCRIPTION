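Package: weni
Title: Construction, Abbreviation and Validation of Nutritional
    Empowerment Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building hierarchical binary-indicator composite
    indices of women's empowerment in nutrition (WENI-style indices),
    abbreviating them to a fixed number of indicators with penalized
    (lasso) regression under a theme-coverage constraint, and validating
    the abbreviated index against the full one and against nutritional
    outcomes.  Includes the 33-indicator index schema and its 20-indicator
    abridgement as packaged fixtures, a coordinate-descent lasso engine
    with cross-validation, information-criterion and rigorous plug-in
    penalty selection, exact-cardinality subset selection along the
    penalty path, Kendall rank-concordance and ROC/AUC validation,
    heteroskedasticity-robust outcome regressions, and a multi-site
    synthetic survey generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
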