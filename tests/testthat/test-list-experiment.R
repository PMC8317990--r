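test_that("cell summaries reproduce hand arithmetic", {
  d <- dataset_from_counts(list(
    do_nothing.control = c(2, 2), do_nothing.treatment = c(2, 2),
    apc.control = c(1, 3), apc.treatment = c(2, 4),
    covideo.control = c(2, 2, 2, 2), covideo.treatment = c(2, 2, 3, 2)))
  cs <- cell_summaries(d, 1)
  cov <- cs[cs$arm == "covideo", ]
  expect_equal(cov$treatment_mean, 2.25)
  expect_equal(cov$control_mean, 2.00)
  expect_equal(cov$treatment_n, 4L)
  expect_equal(cov$control_var, 0)
  expect_equal(cov$treatment_var, var(c(2, 2, 3, 2)))

  all_zero <- fixture_dataset(per_cell = 2)
  cs0 <- cell_summaries(all_zero, 3)
  expect_true(all(cs0$control_mean == 0) && all(cs0$treatment_mean == 0))
})

test_that("prevalence reproduces the worked difference-in-means examples", {
  mk <- function(tm, cm) data.frame(
    arm = "covideo", experiment_index = 1L, control_mean = cm,
    treatment_mean = tm, control_n = 2400L, treatment_n = 2400L,
    control_var = 1.2, treatment_var = 1.3)
  # The published example prints 17.2 and 29.4 from unrounded cell means;
  # from the two-decimal means the estimator gives 17.0 and 30.0, i.e. the
  # printed values up to the resolution of the rounded inputs (+/- 1 point).
  expect_equal(prevalence(mk(2.20, 2.03))$prevalence, 17.0)
  expect_equal(prevalence(mk(2.33, 2.03))$prevalence, 30.0)
  expect_lt(abs(prevalence(mk(2.20, 2.03))$prevalence - 17.2), 1)
  expect_lt(abs(prevalence(mk(2.33, 2.03))$prevalence - 29.4), 1)
  expect_equal(prevalence(mk(2.10, 2.10))$prevalence, 0)

  p <- prevalence(mk(2.20, 2.03))
  expect_equal(p$se, 100 * sqrt(1.3 / 2400 + 1.2 / 2400))
  expect_equal(p$ci_upper - p$ci_lower, 2 * qnorm(0.975) * p$se)
})

test_that("saturated OLS coefficients are the four cell means, reparameterized", {
  d <- dataset_from_counts(list(
    do_nothing.control = c(1, 3), do_nothing.treatment = c(2, 4),
    apc.control = c(0, 2), apc.treatment = c(1, 5),
    covideo.control = c(2, 2), covideo.treatment = c(3, 5)))
  fit <- fit_did(d, 1, c("do_nothing", "covideo"))
  b <- fit$coefficients
  # cell means: ref-control 2, ref-treatment 3, arm-control 2, arm-treatment 4
  expect_equal(unname(b["b0"]), 2)
  expect_equal(unname(b["b0"] + b["b1"]), 2)
  expect_equal(unname(b["b0"] + b["b2"]), 3)
  expect_equal(unname(sum(b)), 4)
  expect_equal(unname(b["b3"]), (4 - 2) - (3 - 2))
  expect_equal(fit$df_residual, 4L)
})

test_that("interaction coefficient equals the cell-mean difference-in-difference", {
  set.seed(8)
  for (rep in 1:20) {
    d <- random_dataset(sample(2:40, 1))
    cs <- cell_summaries(d, 1)
    for (arm in c("apc", "covideo")) {
      fit <- fit_did(d, 1, c("do_nothing", arm))
      did <- (cs$treatment_mean[cs$arm == arm] - cs$control_mean[cs$arm == arm]) -
        (cs$treatment_mean[cs$arm == "do_nothing"] -
           cs$control_mean[cs$arm == "do_nothing"])
      expect_equal(unname(fit$coefficients["b3"]), did, tolerance = 1e-10)
    }
  }
})

test_that("identically distributed cells give null coefficients", {
  set.seed(9)
  n <- 3000
  counts <- list()
  for (nm in c("do_nothing.control", "do_nothing.treatment",
               "apc.control", "apc.treatment",
               "covideo.control", "covideo.treatment")) {
    counts[[nm]] <- rbinom(n, 5, 0.4)
  }
  d <- dataset_from_counts(counts)
  fit <- fit_did(d, 1, c("do_nothing", "covideo"))
  ses <- sqrt(diag(fit$vcov))
  for (k in c("b1", "b2", "b3")) {
    expect_lt(abs(fit$coefficients[k]), 3 * ses[k])
  }
})

test_that("linear combinations reproduce single coefficients and their SEs", {
  set.seed(10)
  d <- random_dataset(30)
  fit <- fit_did(d, 2, c("do_nothing", "apc"))
  lc <- linear_combination(fit, c(0, 0, 0, 1))
  expect_equal(lc$estimate, unname(fit$coefficients["b3"]))
  expect_equal(lc$se, sqrt(fit$vcov["b3", "b3"]))
  expect_equal(lc$df, fit$df_residual)
  tstat <- lc$estimate / lc$se
  expect_equal(lc$p_value, 2 * pt(-abs(tstat), lc$df))

  zero <- linear_combination(fit, rep(0, 4))
  expect_equal(zero$estimate, 0)
  expect_equal(zero$se, 0)

  expect_error(linear_combination(fit, c(1, 0)), "length 4")
})

test_that("the OLS standard error of b2+b3 agrees with a bootstrap", {
  set.seed(14)
  cfg <- simulation_config(n_per_cell = 400, seed = 15, attrition_rate = 0)
  d <- generate_trial(cfg)
  fit <- fit_did(d, 1, c("do_nothing", "covideo"))
  lc <- linear_combination(fit, c(0, 0, 1, 1))

  df <- data.frame(y = d$lc1,
                   video = as.integer(d$arm == "covideo"),
                   treat = as.integer(d$list_group == "treatment"))
  df <- df[d$arm %in% c("do_nothing", "covideo"), ]
  boot <- replicate(1000, {
    idx <- sample.int(nrow(df), replace = TRUE)
    b <- coef(lm(y ~ video * treat, data = df[idx, ]))
    b[["treat"]] + b[["video:treat"]]
  })
  expect_lt(abs(sd(boot) - lc$se) / lc$se, 0.10)
})

test_that("effect decomposition is exact arithmetic on arm prevalences", {
  set.seed(16)
  d <- random_dataset(50)
  eff <- effect_decomposition(d, 1)
  prev <- prevalence(cell_summaries(d, 1))
  p_of <- function(a) prev$prevalence[prev$arm == a] / 100
  expect_equal(eff$estimate[eff$effect == "total"],
               p_of("covideo") - p_of("do_nothing"), tolerance = 1e-10)
  expect_equal(eff$estimate[eff$effect == "attention"],
               p_of("apc") - p_of("do_nothing"), tolerance = 1e-10)
  expect_equal(eff$estimate[eff$effect == "content"],
               p_of("covideo") - p_of("apc"), tolerance = 1e-10)
  # identity: content + attention = total
  expect_equal(eff$estimate[eff$effect == "content"] +
                 eff$estimate[eff$effect == "attention"],
               eff$estimate[eff$effect == "total"], tolerance = 1e-12)

  # pairwise fits agree with the joint fit's point estimates
  for (arm in c("apc", "covideo")) {
    kind <- if (arm == "apc") "attention" else "total"
    fit <- fit_did(d, 1, c("do_nothing", arm))
    expect_equal(unname(fit$coefficients["b3"]),
                 eff$estimate[eff$effect == kind], tolerance = 1e-10)
  }
})

test_that("the content effect from the worked prevalences is -12.2 points", {
  # 17.2 and 29.4 per hundred in the intervention and placebo arms
  expect_equal(17.2 - 29.4, -12.2)
  set.seed(17)
  # full-pipeline analogue: effects on the proportion scale
  d <- random_dataset(40)
  eff <- effect_decomposition(d, 3)
  prev <- prevalence(cell_summaries(d, 3))
  content_pp <- prev$prevalence[prev$arm == "covideo"] -
    prev$prevalence[prev$arm == "apc"]
  expect_equal(100 * eff$estimate[eff$effect == "content"], content_pp,
               tolerance = 1e-8)
})

test_that("equal arm prevalences give near-zero effects", {
  cfg <- simulation_config(
    n_per_cell = 4000, seed = 18, attrition_rate = 0,
    sensitive_prevalence = matrix(0.25, 3, 5))
  d <- generate_trial(cfg)
  eff <- effect_decomposition(d, 1)
  expect_true(all(abs(eff$estimate) < 3 * eff$se))
})

test_that("robust standard errors change inference, never point estimates", {
  set.seed(20)
  d <- random_dataset(80)
  e0 <- effect_decomposition(d, 1)
  e1 <- effect_decomposition(d, 1, robust = TRUE)
  expect_equal(e1$estimate, e0$estimate, tolerance = 1e-12)
  expect_false(any(e1$se == e0$se))
  # in a saturated cell-mean model at moderate n the two SEs nearly agree
  expect_equal(e1$se, e0$se, tolerance = 0.05)
  f0 <- fit_did(d, 1)
  f1 <- fit_did(d, 1, robust = TRUE)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-12)
})

test_that("empty design cells are contract errors", {
  d <- dataset_from_counts(list(
    do_nothing.control = c(1, 2), do_nothing.treatment = c(2, 3),
    apc.control = c(1, 1), apc.treatment = c(2, 2),
    covideo.control = c(1, 2), covideo.treatment = c(2, 2)))
  keep <- !(d$arm == "covideo" & d$list_group == "treatment")
  d2 <- trial_dataset(as.data.frame(d)[keep, ])
  expect_error(cell_summaries(d2, 1), "covideo")
  expect_error(fit_did(d2, 1, c("do_nothing", "covideo")), "populated")
  expect_error(effect_decomposition(d2, 1), "populated")
  expect_error(cell_summaries(d, 9), "experiment_index")
})

test_that("analyze_lists assembles all five experiments coherently", {
  cfg <- small_config(n_per_cell = 300, seed = 19)
  d <- generate_trial(cfg)
  res <- analyze_lists(d)
  expect_equal(nrow(res$cells), 15L)
  expect_equal(nrow(res$prevalence), 15L)
  expect_equal(nrow(res$effects), 15L)
  expect_true(all(res$cells$control_mean >= 0 & res$cells$control_mean <= 5))
  expect_true(all(res$cells$treatment_mean >= 0 & res$cells$treatment_mean <= 6))
  # prevalence column is exactly 100 x the cell-mean difference
  expect_equal(res$prevalence$prevalence,
               100 * (res$cells$treatment_mean - res$cells$control_mean))
  # per-experiment effect identity
  for (i in 1:5) {
    e <- res$effects[res$effects$experiment_index == i, ]
    expect_equal(e$estimate[e$effect == "content"] +
                   e$estimate[e$effect == "attention"],
                 e$estimate[e$effect == "total"], tolerance = 1e-12)
  }
})
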