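Package: scalemok
Title: Nonparametric Item Response Theory Scaling for Ordinal Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mokken scale analysis for short polytomous questionnaires under
    the monotone homogeneity model: Loevinger scalability coefficients at the
    item-pair, item and scale level with bootstrap standard errors, the
    automated item selection procedure with a lower-bound sweep and
    split-threshold search, manifest monotonicity checks of item step response
    functions over rest-score groups, manifest invariant item ordering with
    backward item elimination and the HT ordering-accuracy coefficient, level
    sum scoring with a 0-100 transform, composite-item construction, internal
    consistency reliability (Cronbach's alpha, Guttman's lambda-2), and a
    graded-response-model generator of synthetic questionnaire data with
    controlled monotonicity and item-ordering violations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
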