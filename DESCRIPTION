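Package: cgmcea
Title: Cost-Effectiveness Analysis of Closed-Loop Insulin Initiation from
    CGM-Derived Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-based cost-effectiveness and cost-safety
    analysis of care models for closed-loop (automated insulin delivery)
    initiation in type 1 diabetes. Computes continuous glucose monitoring
    (CGM) band occupancy, time in range (TIR) and the Glycemia Risk Index
    (GRI) with A-E risk zones; prices care-pathway events against a tariff
    catalog by bottom-up micro-costing; derives incremental cost,
    effectiveness and safety with ICER/ICSR and dominance classification;
    propagates parameter uncertainty with a Monte Carlo probabilistic
    sensitivity analysis on the cost-effectiveness plane; and provides
    normality-gated group comparisons, age-class subgroup tables and
    inverse probability of treatment weighting. A seeded synthetic-cohort
    generator reproduces the statistical structure of a two-arm
    observational cohort so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
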