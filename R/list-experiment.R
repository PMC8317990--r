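# Helper: completer rows of one experiment's counts with design factors.
experiment_frame <- function(dataset, experiment_index) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!(experiment_index %in% seq_len(N_LIST_EXPERIMENTS))) {
    stop("experiment_index must be in 1..", N_LIST_EXPERIMENTS)
  }
  data.frame(
    y = dataset[[list_count_cols()[experiment_index]]],
    arm = factor(as.character(dataset$arm), levels = ARM_LEVELS),
    treat = as.integer(dataset$list_group == "treatment")
  )
}

#' Per-cell list-count summaries
#'
#' Computes, for one list experiment, the mean, sample variance and size of
#' the treatment-list and control-list counts within each trial arm - the
#' building blocks of the item-count prevalence estimator.
#'
#' @param dataset a complete-case [trial_dataset()] (incomplete rows are
#'   dropped automatically).
#' @param experiment_index which of the five list experiments (1..5).
#' @return A `list_cell_summary` data frame with one row per arm: columns
#'   `arm`, `experiment_index`, `control_mean`, `treatment_mean`,
#'   `control_n`, `treatment_n`, `control_var`, `treatment_var`.
#' @export
cell_summaries <- function(dataset, experiment_index) {
  dataset <- suppressMessages(filter_complete(dataset))
  df <- experiment_frame(dataset, experiment_index)
  out <- do.call(rbind, lapply(ARM_LEVELS, function(a) {
    yc <- df$y[df$arm == a & df$treat == 0L]
    yt <- df$y[df$arm == a & df$treat == 1L]
    if (length(yc) == 0L || length(yt) == 0L) {
      stop("empty cell: arm=", a, ", experiment ", experiment_index)
    }
    data.frame(arm = a, experiment_index = experiment_index,
               control_mean = mean(yc), treatment_mean = mean(yt),
               control_n = length(yc), treatment_n = length(yt),
               control_var = stats::var(yc), treatment_var = stats::var(yt),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("list_cell_summary", "data.frame")
  out
}

#' Item-count prevalence estimate
#'
#' The prevalence of endorsing the sensitive item, in percentage points, is
#' the treatment-list mean count minus the control-list mean count times
#' 100. The standard error combines the two cell variances,
#' `100 * sqrt(var_T / n_T + var_C / n_C)`, and the 95 percent interval is
#' normal. Negative estimates are possible under sampling noise and are
#' reported as-is.
#'
#' @param summary a `list_cell_summary` from [cell_summaries()] (any number
#'   of rows).
#' @param conf_level confidence level for the normal interval (default 0.95).
#' @return Data frame with one row per input row: `arm`,
#'   `experiment_index`, `prevalence`, `se`, `ci_lower`, `ci_upper`, all in
#'   percentage points.
#' @export
prevalence <- function(summary, conf_level = 0.95) {
  stopifnot(is.data.frame(summary))
  needed <- c("arm", "experiment_index", "control_mean", "treatment_mean",
              "control_n", "treatment_n", "control_var", "treatment_var")
  if (!all(needed %in% names(summary))) {
    stop("summary must contain columns: ", paste(needed, collapse = ", "))
  }
  est <- (summary$treatment_mean - summary$control_mean) * 100
  se <- 100 * sqrt(summary$treatment_var / summary$treatment_n +
                     summary$control_var / summary$control_n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(arm = summary$arm, experiment_index = summary$experiment_index,
             prevalence = est, se = se,
             ci_lower = est - z * se, ci_upper = est + z * se,
             stringsAsFactors = FALSE)
}

#' Difference-in-difference OLS for one arm contrast
#'
#' Fits, for one list experiment and one pair of arms, the saturated
#' ordinary least squares model
#' `y = b0 + b1 VideoArm + b2 TreatList + b3 (VideoArm x TreatList)`,
#' where `y` is the list count, `VideoArm` indicates the comparison arm
#' (versus the reference, first element of `arm_pair`) and `TreatList`
#' indicates the treatment list. Because the model is saturated in the four
#' design cells, `b3` equals the cell-mean difference-in-difference exactly,
#' i.e. the between-arm difference in estimated prevalence on the count
#' (proportion) scale. Classical homoskedastic standard errors are the
#' default; `robust = TRUE` switches the coefficient covariance to the
#' heteroskedasticity-consistent HC1 sandwich estimator.
#'
#' @param dataset a [trial_dataset()]; completers only are analysed.
#' @param experiment_index which list experiment (1..5).
#' @param arm_pair character vector `c(reference, comparison)` of arm names.
#' @param robust use HC1 sandwich standard errors instead of classical OLS
#'   ones (default `FALSE`).
#' @return A `did_fit` object: list with `coefficients` (named b0..b3),
#'   `vcov`, `df_residual`, `experiment_index`, `arms`.
#' @export
fit_did <- function(dataset, experiment_index,
                    arm_pair = c("do_nothing", "covideo"), robust = FALSE) {
  stopifnot(length(arm_pair) == 2L, all(arm_pair %in% ARM_LEVELS),
            arm_pair[1L] != arm_pair[2L])
  dataset <- suppressMessages(filter_complete(dataset))
  df <- experiment_frame(dataset, experiment_index)
  df <- df[df$arm %in% arm_pair, , drop = FALSE]
  df$video <- as.integer(as.character(df$arm) == arm_pair[2L])
  cells <- table(df$video, df$treat)
  if (!identical(dim(cells), c(2L, 2L)) || any(cells == 0L)) {
    stop("all four arm x list cells must be populated for arms ",
         paste(arm_pair, collapse = " vs "))
  }
  fit <- stats::lm(y ~ video * treat, data = df)
  b <- stats::coef(fit)
  names(b) <- c("b0", "b1", "b2", "b3")
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  dimnames(V) <- list(names(b), names(b))
  structure(list(coefficients = b, vcov = V,
                 df_residual = fit$df.residual,
                 experiment_index = experiment_index, arms = arm_pair),
            class = "did_fit")
}

#' Inference for a linear combination of OLS coefficients
#'
#' Computes `w' b` with standard error `sqrt(w' V w)`, a two-sided p-value
#' from the t distribution on the fit's residual degrees of freedom, and a
#' 95 percent confidence interval.
#'
#' @param fit a `did_fit` (or any list with `coefficients`, `vcov`,
#'   `df_residual`).
#' @param weights numeric vector, same length as the coefficient vector.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List with `estimate`, `se`, `ci_lower`, `ci_upper`, `p_value`,
#'   `df`.
#' @export
linear_combination <- function(fit, weights, conf_level = 0.95) {
  b <- fit$coefficients
  V <- fit$vcov
  if (length(weights) != length(b)) {
    stop("weights must have length ", length(b))
  }
  w <- as.numeric(weights)
  est <- sum(w * b)
  se <- sqrt(drop(t(w) %*% V %*% w))
  df <- fit$df_residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(est / se), df) else as.numeric(est == 0)
  list(estimate = est, se = se,
       ci_lower = est - tcrit * se, ci_upper = est + tcrit * se,
       p_value = p, df = df)
}

# Joint three-arm saturated OLS: two arm dummies (reference do_nothing),
# full interactions with the treatment-list indicator. The interaction
# coefficients are the arm-vs-reference prevalence differences on the
# proportion scale.
fit_did_joint <- function(dataset, experiment_index, robust = FALSE) {
  dataset <- suppressMessages(filter_complete(dataset))
  df <- experiment_frame(dataset, experiment_index)
  if (any(table(df$arm, df$treat) == 0L)) {
    stop("all six arm x list cells must be populated")
  }
  fit <- stats::lm(y ~ arm * treat, data = df)
  b <- stats::coef(fit)
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  structure(list(coefficients = b, vcov = V,
                 df_residual = fit$df.residual,
                 experiment_index = experiment_index,
                 arms = ARM_LEVELS),
            class = "did_fit")
}

#' Total, attention and content effects for one list experiment
#'
#' Decomposes the between-arm differences in sensitive-item prevalence via
#' a single saturated three-arm OLS (two arm dummies, reference the
#' do-nothing arm, fully interacted with the treatment-list indicator).
#' The total effect is the intervention-vs-do-nothing interaction, the
#' attention effect the placebo-vs-do-nothing interaction, and the content
#' effect their difference (intervention vs placebo); content + attention =
#' total exactly. Estimates are on the proportion scale (multiply by 100
#' for percentage points); standard errors, t-based p-values and 95 percent
#' intervals come from linear combinations of the OLS coefficients.
#'
#' @param dataset a [trial_dataset()].
#' @param experiment_index which list experiment (1..5).
#' @param conf_level confidence level for effect intervals (default 0.95).
#' @param robust use HC1 sandwich standard errors (default `FALSE`).
#' @return An `effect_estimates` data frame with rows total, attention,
#'   content: columns `experiment_index`, `effect`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
effect_decomposition <- function(dataset, experiment_index, conf_level = 0.95,
                                 robust = FALSE) {
  fit <- fit_did_joint(dataset, experiment_index, robust = robust)
  cn <- names(fit$coefficients)
  w_total <- as.numeric(cn == "armcovideo:treat")
  w_attention <- as.numeric(cn == "armapc:treat")
  w_content <- w_total - w_attention
  rows <- Map(function(kind, w) {
    lc <- linear_combination(fit, w, conf_level = conf_level)
    data.frame(experiment_index = experiment_index, effect = kind,
               estimate = lc$estimate, se = lc$se,
               ci_lower = lc$ci_lower, ci_upper = lc$ci_upper,
               p_value = lc$p_value, stringsAsFactors = FALSE)
  }, c("total", "attention", "content"),
     list(w_total, w_attention, w_content))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Full list-experiment analysis
#'
#' Runs the complete second-endpoint pipeline on the completers of a trial
#' dataset: per-cell count summaries, item-count prevalence estimates per
#' arm, and the total/attention/content effect decomposition, for each of
#' the five list experiments.
#'
#' @param dataset a [trial_dataset()].
#' @param conf_level confidence level used throughout (default 0.95).
#' @param robust use HC1 sandwich standard errors in the effect models
#'   (default `FALSE`).
#' @return A `list_experiment_result`: list with data frames `cells`
#'   (15 rows), `prevalence` (15 rows, percentage points) and `effects`
#'   (15 rows, proportion scale).
#' @export
analyze_lists <- function(dataset, conf_level = 0.95, robust = FALSE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dataset <- suppressMessages(filter_complete(dataset))
  assert_cells_populated(dataset)
  cells <- do.call(rbind, lapply(seq_len(N_LIST_EXPERIMENTS),
                                 function(i) cell_summaries(dataset, i)))
  prev <- prevalence(cells, conf_level = conf_level)
  effects <- do.call(rbind, lapply(seq_len(N_LIST_EXPERIMENTS),
                                   function(i) effect_decomposition(dataset, i, conf_level = conf_level,
                                                    robust = robust)))
  structure(list(cells = cells, prevalence = prev, effects = effects),
            class = "list_experiment_result")
}

#' @export
print.list_experiment_result <- function(x, ...) {
  cat("List-experiment endpoint\n\nPrevalence of sensitive-item endorsement (percentage points):\n")
  p <- x$prevalence
  p$prevalence <- round(p$prevalence, 1)
  p$se <- round(p$se, 2)
  p$ci_lower <- round(p$ci_lower, 1)
  p$ci_upper <- round(p$ci_upper, 1)
  print(p, row.names = FALSE)
  cat("\nArm contrasts (proportion scale):\n")
  e <- x$effects
  e$estimate <- round(e$estimate, 3)
  e$se <- round(e$se, 3)
  e$ci_lower <- round(e$ci_lower, 3)
  e$ci_upper <- round(e$ci_upper, 3)
  e$p_value <- signif(e$p_value, 3)
  print(e, row.names = FALSE)
  invisible(x)
}
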