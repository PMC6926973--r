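Package: gbnwhatif
Title: General Bayesian Networks with Markov-Blanket Feature Selection and
    What-If Scenario Analysis for Categorical Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning discrete (general) Bayesian networks from
    categorical survey data, with exact inference by variable elimination,
    Markov-blanket feature selection for classification, sensitivity-to-findings
    reports (mutual information, entropy reduction, variance of beliefs),
    and what-if scenario analysis including a functional decomposition of a
    target expectation into main effects and interaction terms. Includes a
    preprocessing toolkit for adolescent BMI categorisation against the 2007
    Korean growth chart, a synthetic survey generator with known ground truth
    for end-to-end testing, and cross-validated classifier evaluation
    (accuracy, weighted F-measure, one-vs-rest AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
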