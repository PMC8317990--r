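#' Score a participant's knowledge responses
#'
#' The knowledge score is the count of correct responses out of 18. An item
#' that timed out (the participant ran out of the 30-second answer window)
#' is recoded as incorrect and contributes 0, so scores always lie in
#' \code{[0, 18]}.
#'
#' @param responses 18 coded responses: the enumeration strings `correct`,
#'   `incorrect`, `timeout` (or a factor over them), or the platform integer
#'   codes 1/0/9.
#' @return Integer score in \code{[0, 18]}.
#' @export
score_knowledge <- function(responses) {
  if (is.numeric(responses)) responses <- decode_response(responses, "responses")
  responses <- as.character(responses)
  if (length(responses) != N_KNOWLEDGE_ITEMS) {
    stop("expected exactly ", N_KNOWLEDGE_ITEMS, " responses, got ",
         length(responses))
  }
  bad <- setdiff(responses, RESPONSE_LEVELS)
  if (length(bad) > 0L) stop("unknown response code: ", bad[1L])
  sum(responses == "correct")
}

# Per-participant scores for a whole dataset; returns an integer vector.
knowledge_scores <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  resp <- as.matrix(as.data.frame(lapply(dataset[knowledge_cols()], as.character),
                                  stringsAsFactors = FALSE))
  as.integer(rowSums(resp == "correct"))
}

# participants x 18 binary correctness matrix (timeout counted incorrect).
correctness_matrix <- function(dataset) {
  resp <- as.matrix(as.data.frame(lapply(dataset[knowledge_cols()], as.character),
                                  stringsAsFactors = FALSE))
  (resp == "correct") * 1L
}

#' Split-half reliability of the knowledge questionnaire
#'
#' Splits the 18 items into odd- and even-numbered halves, scores each half,
#' and returns the Pearson correlation of the half scores together with the
#' Spearman-Brown step-up value `2r / (1 + r)`, which projects the half-test
#' correlation to the reliability of the full-length test. Both are reported
#' because "split-half coefficient" is used for either in practice.
#'
#' @param score_matrix participants x 18 matrix of 0/1 correctness
#'   indicators (timeouts already counted as incorrect), e.g. from a
#'   [trial_dataset()].
#' @return List with elements `raw` (half-score correlation) and
#'   `spearman_brown` (step-up adjusted coefficient).
#' @export
split_half_reliability <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  if (ncol(score_matrix) != N_KNOWLEDGE_ITEMS) {
    stop("score matrix must have ", N_KNOWLEDGE_ITEMS, " columns")
  }
  if (nrow(score_matrix) < 3L) stop("need at least 3 participants")
  odd <- rowSums(score_matrix[, seq(1L, N_KNOWLEDGE_ITEMS, by = 2L), drop = FALSE])
  even <- rowSums(score_matrix[, seq(2L, N_KNOWLEDGE_ITEMS, by = 2L), drop = FALSE])
  if (stats::sd(odd) == 0 || stats::sd(even) == 0) {
    stop("zero variance in a half score; reliability is undefined")
  }
  r <- stats::cor(odd, even)
  list(raw = r, spearman_brown = 2 * r / (1 + r))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Tests for differences in mean knowledge score between the trial arms with
#' a one-way analysis of variance, followed by Tukey honestly-significant-
#' difference comparisons of all arm pairs. With unequal cell sizes the
#' Tukey-Kramer form (harmonic-mean cell size within each pair) is used, as
#' implemented by [stats::TukeyHSD()].
#'
#' @param scores numeric vector of per-participant knowledge scores.
#' @param arms arm label per participant (factor or character over the arm
#'   enumeration); at least two arms with at least two participants each.
#' @return List with `anova` (`f`, `df`, `p_value`) and `tukey`, a data
#'   frame of pairwise mean differences with 95 percent family-wise
#'   confidence bounds and adjusted p-values.
#' @export
anova_tukey <- function(scores, arms) {
  arms <- factor(as.character(arms), levels = intersect(ARM_LEVELS, unique(as.character(arms))))
  if (length(scores) != length(arms)) stop("scores and arms differ in length")
  if (nlevels(arms) < 2L) stop("need at least two arms")
  if (any(table(arms) < 2L)) stop("every arm needs at least two participants")

  df <- data.frame(score = as.numeric(scores), arm = arms)
  fit <- stats::aov(score ~ arm, data = df)
  av <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, "arm")$arm
  tukey <- data.frame(
    contrast = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    row.names = NULL
  )
  list(
    anova = list(f = av["arm", "F value"],
                 df = c(av["arm", "Df"], av["Residuals", "Df"]),
                 p_value = av["arm", "Pr(>F)"]),
    tukey = tukey
  )
}

#' Total, attention and content effects on the knowledge score
#'
#' Decomposes the intervention effect on a bounded score into the total
#' effect (intervention minus do-nothing), the attention effect (attention
#' placebo minus do-nothing) and the content effect (intervention minus
#' attention placebo); by construction content + attention = total. Because
#' scores sit near the 18-point ceiling, each comparison is also expressed
#' relative to its headroom, the maximum attainable gain `18 - comparator
#' mean`, as `effect / headroom`.
#'
#' @param means named numeric vector of arm means `c(do_nothing=, apc=,
#'   covideo=)`, each in \code{[0, 18]}.
#' @param ses optional named vector of standard errors of the arm means;
#'   contrast SEs are then formed by independent-arm variance addition.
#' @return List with `effects` (point estimates and, when `ses` is given,
#'   standard errors) and `headroom` (maximum gains and relative gains).
#' @export
knowledge_effects <- function(means, ses = NULL) {
  if (!all(ARM_LEVELS %in% names(means))) {
    stop("means must be named with: ", paste(ARM_LEVELS, collapse = ", "))
  }
  means <- means[ARM_LEVELS]
  if (any(means < 0 | means > N_KNOWLEDGE_ITEMS)) {
    stop("arm means must lie in [0, ", N_KNOWLEDGE_ITEMS, "]")
  }
  est <- c(total = unname(means["covideo"] - means["do_nothing"]),
           attention = unname(means["apc"] - means["do_nothing"]),
           content = unname(means["covideo"] - means["apc"]))
  out <- list(effects = list(estimate = est))
  if (!is.null(ses)) {
    ses <- ses[ARM_LEVELS]
    out$effects$se <- c(
      total = sqrt(sum(ses[c("covideo", "do_nothing")]^2)),
      attention = sqrt(sum(ses[c("apc", "do_nothing")]^2)),
      content = sqrt(sum(ses[c("covideo", "apc")]^2))
    )
  }
  headroom <- c(vs_do_nothing = unname(N_KNOWLEDGE_ITEMS - means["do_nothing"]),
                vs_apc = unname(N_KNOWLEDGE_ITEMS - means["apc"]))
  out$headroom <- list(
    max_gain = headroom,
    relative_gain = c(total = unname(est["total"] / headroom["vs_do_nothing"]),
                      attention = unname(est["attention"] / headroom["vs_do_nothing"]),
                      content = unname(est["content"] / headroom["vs_apc"]))
  )
  out
}

#' Per-item proportion correct by arm
#'
#' @param dataset a complete-case [trial_dataset()]; timeouts count as
#'   incorrect.
#' @return 18 x 3 matrix of proportions (items x arms).
#' @export
per_item_correct <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (any(table(dataset$arm) == 0L)) stop("every arm must be populated")
  cm <- correctness_matrix(dataset)
  out <- vapply(ARM_LEVELS, function(a) colMeans(cm[dataset$arm == a, , drop = FALSE]),
                numeric(N_KNOWLEDGE_ITEMS))
  rownames(out) <- knowledge_cols()
  out
}

#' Full knowledge-endpoint analysis
#'
#' Runs the complete first-endpoint pipeline on the completers of a trial
#' dataset: per-participant scoring with timeout recoding, per-arm means
#' with normal-approximation 95 percent confidence intervals, one-way ANOVA
#' with Tukey HSD, the total/attention/content decomposition with
#' headroom-relative gains, split-half reliability, and per-item proportions
#' correct.
#'
#' @param dataset a [trial_dataset()]; incomplete participants are dropped
#'   first.
#' @param conf_level confidence level for arm-mean intervals (default 0.95).
#' @return A `knowledge_summary` object: list with `per_arm`, `anova`,
#'   `tukey`, `effects`, `headroom`, `reliability`, `per_item`, `n_analyzed`.
#' @export
analyze_knowledge <- function(dataset, conf_level = 0.95) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dataset <- suppressMessages(filter_complete(dataset))
  assert_cells_populated(dataset)

  scores <- knowledge_scores(dataset)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_arm <- do.call(rbind, lapply(ARM_LEVELS, function(a) {
    s <- scores[dataset$arm == a]
    m <- mean(s)
    se <- stats::sd(s) / sqrt(length(s))
    data.frame(arm = a, n = length(s), mean = m, se = se,
               ci_lower = m - z * se, ci_upper = m + z * se,
               correct_rate = 100 * m / N_KNOWLEDGE_ITEMS,
               stringsAsFactors = FALSE)
  }))

  at <- anova_tukey(scores, dataset$arm)
  means <- stats::setNames(per_arm$mean, per_arm$arm)
  ses <- stats::setNames(per_arm$se, per_arm$arm)
  eff <- knowledge_effects(means, ses)
  rel <- split_half_reliability(correctness_matrix(dataset))

  structure(list(
    per_arm = per_arm,
    anova = at$anova,
    tukey = at$tukey,
    effects = eff$effects,
    headroom = eff$headroom,
    reliability = rel,
    per_item = per_item_correct(dataset),
    n_analyzed = nrow(dataset)
  ), class = "knowledge_summary")
}

#' @export
print.knowledge_summary <- function(x, ...) {
  cat(sprintf("Knowledge endpoint (n = %d completers)\n", x$n_analyzed))
  cat("\nPer-arm scores (max 18):\n")
  print(transform(x$per_arm,
                  mean = round(mean, 2), se = round(se, 4),
                  ci_lower = round(ci_lower, 2), ci_upper = round(ci_upper, 2),
                  correct_rate = round(correct_rate, 1)),
        row.names = FALSE)
  cat(sprintf("\nANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df[1], x$anova$df[2], x$anova$f, x$anova$p_value))
  cat("\nTukey HSD:\n")
  print(transform(x$tukey, diff = round(diff, 3), lwr = round(lwr, 3),
                  upr = round(upr, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  cat("\nEffects (points on the 18-item score):\n")
  for (k in names(x$effects$estimate)) {
    cat(sprintf("  %-9s %+0.3f (relative to headroom: %+.1f%%)\n", k,
                x$effects$estimate[k], 100 * x$headroom$relative_gain[k]))
  }
  cat(sprintf("\nSplit-half reliability: %.2f raw, %.2f Spearman-Brown\n",
              x$reliability$raw, x$reliability$spearman_brown))
  invisible(x)
}
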