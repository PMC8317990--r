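---
title: "Methods: three-arm trials with nested list experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-arm trials with nested list experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listrct)
```

## The design this package analyses

Participants in an online trial are randomized 1:1:1 to an intervention
video, an attention placebo control (APC) video matched on format and
duration but empty of intervention content, or to no video at all. Two
endpoints follow. First, 18 true/false knowledge items answered under a
30-second per-item limit; a timeout is recorded as a distinct code and
recoded to incorrect at scoring time. Second, five list experiments:
within each arm, participants are randomized 1:1 to a control list of 5
innocuous statements or to a treatment list that adds one sensitive
statement about behavioural intent; respondents report only *how many*
statements they agree with, never which ones.

The APC splits the intervention-vs-nothing contrast into an *attention*
component (watching any video) and a *content* component (the message
itself); the list experiment shields the intent questions from
social-desirability pressure, because a treatment-list count of 1–5 never
reveals whether the sensitive item was endorsed.

## Estimators and their assumptions

### Knowledge score

The score is the count of correct answers, so timeouts and wrong answers
are interchangeable at analysis time — the package stores them
distinctly and applies the recode in `score_knowledge()`, keeping the
rule explicit and testable. Arm comparisons use one-way ANOVA and Tukey
HSD (`stats::aov`, `stats::TukeyHSD`). The model equation is treated as a
standard one-way ANOVA with intercept; a literal single-dummy reading
cannot represent three arms and is taken as schematic. With roughly equal
arms of ~4,800 the Tukey–Kramer harmonic-mean adjustment for unequal
cells is the appropriate generalization and is what `TukeyHSD` computes.

Arm-mean confidence intervals use the normal approximation
mean ± z·SE; at thousands of observations per arm the difference from a
t interval is far below reporting precision. Effects are plain contrasts
of arm means, with standard errors from independent-arm variance
addition, and `content + attention = total` holds exactly by
construction. Because the score is bounded at 18, each effect is also
reported relative to its *headroom* (18 minus the comparator mean): a
0.09-point gain against a 1.14-point maximum is a 7.9% relative gain.
Published summaries of this design round the arm means before displaying
such ratios, which can make the printed percentage (7.6%) differ from
the ratio of the printed numerator and denominator (0.09/1.14 = 7.9%);
the package always reports the full-precision ratio of the means it was
actually given and leaves rounding to the caller.

Reliability is the Pearson correlation between odd-item and even-item
half scores. Whether a published "split-half coefficient" is the raw
correlation or its Spearman–Brown step-up is often unstated, so
`split_half_reliability()` returns both, clearly labelled. A zero-variance
half raises an error rather than returning a silent 0.

### Item-count prevalence

With control-list count C ∈ [0,5] and treatment-list count T ∈ [0,6],
the prevalence of the sensitive behaviour in arm *k*, experiment *i* is
(T̄ − C̄) × 100. Its validity rests on two standard assumptions: *no
design effect* (adding the sensitive item leaves control-item answering
unchanged) and *no liars* (counts are truthful). The standard error is
100·√(s²_T/n_T + s²_C/n_C) with a normal interval. Estimates are not
truncated: sampling noise can and does produce negative prevalences, and
reporting them as-is keeps the estimator unbiased.

Note the estimator's arithmetic on rounded inputs: a published example
computing (2.20 − 2.03) × 100 = 17.2 used unrounded means; from the
two-decimal means the result is exactly 17.0. The package computes, and
its tests assert, the exact arithmetic.

### Difference-in-difference OLS

Arm contrasts of prevalence are difference-in-differences. For one arm
pair the package fits `y ~ video * treat` by OLS; because the model is
saturated in the four design cells, the interaction coefficient is
*identically* the cell-mean difference-in-difference — a closed-form
identity the test suite enforces to 1e-10 on arbitrary datasets, the
strongest oracle available. Three-arm effects come from a single joint
fit with two arm dummies fully interacted with the list indicator
(`fit_did_joint`, used by `effect_decomposition()`); a printed equation
with a single VideoArm term cannot encode three arms and is again read
as schematic. Pairwise fits are exposed too and agree with the joint
fit's point estimates exactly.

Inference uses classical homoskedastic covariance with p-values from the
t distribution on the residual degrees of freedom; at cell sizes in the
thousands the t/normal distinction is negligible, and the source design
gives no indication robust errors were used. Linear combinations w′b use
SE = √(w′Σw). List counts are assumed always observed for completers;
the 30-second timeout mechanism applies only to knowledge items.

Complete-case analysis throughout: participants flagged as not having
completed the survey are dropped by `filter_complete()` before any
estimate, with counts logged, and no imputation is attempted.

## The synthetic-trial generator

`generate_trial()` exists so every pipeline stage is testable without
participant-level data. Its defaults are fixed study conditions, chosen
once:

- `n_per_cell = 2500`: six cells ≈ 15,000 randomized participants, the
  scale of the motivating trial.
- `attrition_rate = 0.033`: post-randomization loss of ~3.3%, matching
  the reported flow (493 of 14,992).
- `timeout_rate = 0.005`: the source does not report a timeout
  frequency; 0.5% of items is small enough that the easiest item's
  ~99.4% observed correct rate remains attainable, while still
  exercising the recode path.
- `knowledge_p`: per-arm item probabilities calibrated so expected
  scores are exactly 16.86 / 16.89 / 16.95 (do-nothing / APC /
  intervention). An 18-item anchor profile (most items above 0.9,
  hardest 0.72, easiest 0.999) is shifted per arm by closing a constant
  fraction of each item's remaining headroom, which preserves the
  near-ceiling shape and keeps all probabilities in [0,1].
- `sensitive_prevalence`: experiment 1 uses (0.217, 0.294, 0.172),
  back-derived from the published per-arm prevalences 17.2 and 29.4 and
  total effect −0.045. Prevalences for experiments 2–5 appear only in a
  figure in the source, so plausible values consistent with the reported
  contrast directions were fixed a priori: hand-washing (0.70, 0.71,
  0.73), dish-cleaning (0.55, 0.58, 0.62), surface-cleaning (0.58,
  0.60, 0.63), stockpiling (0.20, 0.18, 0.15).
- `control_item_p`: experiment 1's five control-item probabilities sum
  to 2.03, the published control-list mean; the other rows sum to
  1.97–2.05.
- Demographics are drawn from frozen marginal tables
  (`demographic_marginals()`) reproducing the completed sample's margins
  (58.8% UK, 26% US, 81.6% some college or higher, 84.9% English).

One root seed spawns a fixed substream per design cell, so identical
seed and configuration give byte-identical CSV output regardless of
generation order.

Two switches support robustness work. `design_violation` adds a constant
to every control-item probability on treatment lists only, breaking the
identifying assumption by a known amount (the estimator's bias is then
500·violation percentage points, which a test verifies).
`item_correlation` induces a shared latent agreement propensity across a
list's control items through a Gaussian copula; marginal probabilities —
and hence the estimator's validity — are unaffected, only count
variances grow, which is exactly what the independence-free
difference-in-means argument predicts and what the tests demonstrate.

### What the generator does *not* emulate

- **Person-level knowledge ability.** Items are independent Bernoulli
  draws within arm, so the split-half reliability of synthetic data is
  ≈ 0, not the 0.65 of real questionnaire data. Passing reliability
  tests therefore show the *computation* is right, not that synthetic
  data resemble real response consistency.
- **Joint demographic structure.** Demographics are independent
  marginals feeding only balance tables; no country-by-language
  coupling, and no demographic heterogeneity in outcomes.
- **Second moments of list counts.** The source reports only cell
  means, so count variances are whatever the independent-Bernoulli
  structure implies; calibration targets are means only.
- **Response times, item wording, country-level prevalence
  heterogeneity** (run per-country configurations if needed).

Consequently, full-data published values that depend on unavailable
participant-level structure (exact arm means to two decimals, the 0.65
reliability, baseline-table p-values, content effect −0.123) are not
reproduction targets; the pipeline's correctness is instead established
by closed-form identities, hand-computed fixtures, and parameter
recovery against the generator's known truth.

## Numerical and degenerate-input policy

- Saturated-OLS identity b₃ = DiD asserted at 1e-10 (floating-point
  accumulation only).
- `ptukey`-based hand checks at 1e-6, the documented accuracy of the
  studentized-range quadrature.
- Empty design cells, single-arm inputs, zero-variance halves, length
  mismatches and out-of-range enumerations raise immediate contract
  errors naming the offending cell, column or row; nothing degrades to
  NA silently.
- Stochastic assertions are made at 3·SE (binomial or analytic), with
  fixed seeds, never absolutely.

## Problem sizes used by the test suite

The suite establishes the estimator's guarantees at sizes chosen to make
Monte-Carlo error negligible relative to the assertion: parameter
recovery at 50,000 per cell (analytic SE ≈ 0.7 percentage points),
calibration and recovery checks at 4,000–20,000 per cell, the
saturated-model identity on 200 random datasets of 2–200 per cell, and
the type-I error of the content-effect test over 1,000 simulated trials
of 2,400 per cell (nominal 5%, binomial 3σ band 3.3–6.7%). The
acceptance script repeats a 500-trial version of the type-I study and a
full pipeline run at 2,500 per cell.

## Known limitations

- No maximum-likelihood or covariate-adjusted list-experiment
  estimators (e.g. Imai-style ML/NLS); difference-in-means/OLS only.
- No formal tests for design effects or untruthful responding beyond
  the generator's violation knob.
- Balance-table p-values use Pearson's chi-square of each demographic
  against the six design cells; the source does not state its test, so
  exact reproduction of published baseline p-values is not claimed.
- Classical OLS standard errors are the default, matching the source's
  analysis; an HC1 sandwich option (`robust = TRUE`) exists but for
  saturated cell-mean models at these cell sizes the difference is
  immaterial.
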