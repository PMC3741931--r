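Package: clinrules
Title: Class-Constrained Association Rule Mining for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines association rules between discretized clinicopathologic
    factors and survival strata in operation-centric oral squamous cell
    carcinoma cohorts. Implements the classic Apriori frequent-itemset
    algorithm with hash-tree candidate counting, rule generation with
    confidence, lift, leverage and conviction (standard and
    Laplace-corrected variants), univariate contingency analysis with
    Pearson chi-square tests, and a synthetic cohort generator with
    plantable multi-attribute associations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
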