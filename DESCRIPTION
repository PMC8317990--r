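Package: listrct
Title: Analysis of Three-Arm Randomized Trials with Nested List Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-arm online randomized controlled
    trials that pair a bounded knowledge-score endpoint with a nested
    list-experiment (item-count) endpoint. Implements knowledge scoring
    with timeout recoding, split-half reliability, one-way ANOVA with
    Tukey HSD pairwise comparisons, and a total/attention/content effect
    decomposition against an attention placebo control with
    headroom-relative gains. For the list-experiment endpoint it provides
    the difference-in-means prevalence estimator, the saturated
    difference-in-difference OLS with interaction terms, and
    linear-combination inference for arm contrasts. A synthetic-trial
    generator reproduces the statistical structure of such trials
    (near-ceiling knowledge, per-arm sensitive-item prevalences, timeout
    missingness, attrition) so the full pipeline is testable without
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'trial-schema.R'
    'synthetic-trial.R'
    'knowledge.R'
    'list-experiment.R'
    'report.R'
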