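Package: sarcostage
Title: Staged Sarcopenia Risk Screening and Weighted Intervention Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community-level sarcopenia risk stratification built
    around a 12-item functional self-assessment questionnaire. Provides
    questionnaire scoring and four-band risk classification, reliability and
    sampling-adequacy statistics (Cronbach's alpha, KMO, Bartlett's test of
    sphericity), a symptom-behaviour exclusion funnel with a 9-point
    diagnostic threshold, a four-stage (A-D) behavioural progression model
    with socioeconomic-status grouping and triangulation against SARC-F and
    DXA-derived staging, an Analytic Hierarchy Process engine (reciprocal
    judgment matrix validation, principal-eigenvector priorities, consistency
    ratios, geometric-mean expert aggregation, hierarchical weight
    composition), stage-dependent dynamic weighting with composite indicator
    weights, mapping of severity ratings to three intervention grades, and a
    calibrated synthetic cohort generator so the whole pipeline is testable
    without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
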