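Package: nutricea
Title: Trial-Based Cost-Effectiveness Analysis of a Maternal Nutrition
    Education Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a trial-based economic evaluation of a maternal
    nutrition education intervention delivered in a cluster-randomized
    controlled trial in rural Uganda. Provides cost-ledger aggregation into
    per-category and per-child intervention costs, a synthetic
    cluster-trial data generator with village-level clustering and
    missing-completely-at-random attrition, estimation of the incremental
    cognitive composite score by a difference-in-differences linear mixed
    model, deterministic cost-effectiveness algebra (incremental
    cost-effectiveness ratio, net monetary benefit, quadrant
    classification, DALY-weight thresholds), one-way (tornado) sensitivity
    analysis, Monte Carlo probabilistic sensitivity analysis, and
    cost-effectiveness acceptability curves, plus a configurable pipeline
    that writes tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
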