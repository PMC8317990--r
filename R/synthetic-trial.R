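# Calibration anchors for the default configuration. Arm order is
# do_nothing, apc, covideo throughout.

# Expected knowledge scores by arm (out of 18) that the defaults reproduce.
DEFAULT_TARGET_SCORES <- c(do_nothing = 16.86, apc = 16.89, covideo = 16.95)

# Item-difficulty anchor profile: near-ceiling true/false items, the easiest
# (frequent hand washing) answered correctly by essentially everyone, a
# couple of harder items pulling the mean down.
KNOWLEDGE_ANCHOR <- c(0.999, 0.990, 0.985, 0.980, 0.975, 0.970, 0.965, 0.960,
                      0.955, 0.950, 0.945, 0.940, 0.930, 0.920, 0.910, 0.890,
                      0.850, 0.720)

# Per-arm sensitive-item endorsement probabilities (rows: arm; columns: the
# five list experiments - social distancing, washing hands, cleaning dishes,
# cleaning kitchen surfaces, stockpiling). Experiment 1 is anchored to the
# published arm prevalences (21.7 / 29.4 / 17.2 per hundred); the remaining
# columns are plausible intent levels consistent with the reported direction
# of the arm contrasts.
DEFAULT_SENSITIVE_PREVALENCE <- matrix(
  c(0.217, 0.70, 0.55, 0.58, 0.20,
    0.294, 0.71, 0.58, 0.60, 0.18,
    0.172, 0.73, 0.62, 0.63, 0.15),
  nrow = 3, byrow = TRUE,
  dimnames = list(ARM_LEVELS, paste0("exp", 1:5)))

# Endorsement probability of each innocuous control item (rows: experiment;
# columns: item). Row sums give the expected control-list count; experiment 1
# sums to 2.03, the published control-list mean.
DEFAULT_CONTROL_ITEM_P <- matrix(
  c(0.62, 0.50, 0.08, 0.45, 0.38,
    0.55, 0.45, 0.12, 0.40, 0.48,
    0.60, 0.42, 0.10, 0.50, 0.35,
    0.58, 0.44, 0.15, 0.42, 0.46,
    0.52, 0.40, 0.20, 0.47, 0.41),
  nrow = 5, byrow = TRUE,
  dimnames = list(paste0("exp", 1:5), paste0("item", 1:5)))

# Maps an anchor profile to per-arm item probabilities whose expected score
# (after timeouts) hits the target: the arm shift closes the same fraction of
# every item's remaining headroom, which keeps all probabilities in [0,1].
calibrate_knowledge_p <- function(target_scores, timeout_rate,
                                  anchor = KNOWLEDGE_ANCHOR) {
  required <- target_scores / (1 - timeout_rate)
  if (any(required > length(anchor))) stop("target scores unattainable")
  out <- t(vapply(required, function(s) {
    shift <- s - sum(anchor)
    if (shift < 0) stop("anchor profile exceeds target score")
    anchor + shift * (1 - anchor) / sum(1 - anchor)
  }, numeric(length(anchor))))
  rownames(out) <- names(target_scores)
  out
}

#' Simulation configuration for a synthetic three-arm trial
#'
#' Bundles every generative parameter of [generate_trial()]. The defaults
#' encode the study conditions the analysis pipeline targets: three arms of
#' equal size, a 1:1 control/treatment list split, near-ceiling knowledge
#' (expected scores 16.86 / 16.89 / 16.95 out of 18 for the do-nothing,
#' attention-placebo and intervention arms), a sensitive-item prevalence of
#' 21.7 / 29.4 / 17.2 per hundred in experiment 1, a 30-second timeout
#' affecting a small fraction of knowledge items, and pre-analysis attrition
#' of about 3.3 percent.
#'
#' @param n_per_cell participants randomized into each of the six
#'   arm-by-list cells. Default 2500 gives a trial of 15,000 randomized
#'   participants, matching the scale of the motivating study.
#' @param knowledge_p 3 x 18 matrix of per-arm probabilities that an item
#'   would be answered correctly absent a timeout (rows in arm order
#'   do_nothing, apc, covideo). The default is calibrated so the expected
#'   score per arm equals `16.86 / 16.89 / 16.95`.
#' @param timeout_rate probability that any knowledge item times out (the
#'   participant then scores 0 on it). Default 0.005.
#' @param sensitive_prevalence 3 x 5 matrix of true endorsement
#'   probabilities of the sensitive item, by arm (rows) and list experiment
#'   (columns).
#' @param control_item_p 5 x 5 matrix of endorsement probabilities of the
#'   innocuous control items, by experiment (rows) and item (columns);
#'   shared across arms.
#' @param attrition_rate probability a randomized participant fails to
#'   complete and is excluded from analysis. Default 0.033.
#' @param design_violation additive shift applied to every control-item
#'   probability on treatment lists only; 0 (the default) encodes the
#'   identifying "no design effect" assumption of the item-count technique,
#'   nonzero values let tests probe sensitivity to its failure.
#' @param item_correlation Gaussian-copula correlation inducing a shared
#'   latent agreement propensity across the control items of a list;
#'   0 (the default) draws items independently. Marginal endorsement
#'   probabilities are preserved for any value.
#' @param seed integer root seed; one root seed spawns a fixed substream per
#'   design cell, so output is reproducible and independent of generation
#'   order.
#' @return A validated `simulation_config` object (a list).
#' @export
simulation_config <- function(n_per_cell = 2500L,
                              knowledge_p = NULL,
                              timeout_rate = 0.005,
                              sensitive_prevalence = DEFAULT_SENSITIVE_PREVALENCE,
                              control_item_p = DEFAULT_CONTROL_ITEM_P,
                              attrition_rate = 0.033,
                              design_violation = 0,
                              item_correlation = 0,
                              seed = 20200513L) {
  if (!is.numeric(timeout_rate) || is.na(timeout_rate) ||
      timeout_rate < 0 || timeout_rate > 1) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (is.null(knowledge_p)) {
    knowledge_p <- calibrate_knowledge_p(DEFAULT_TARGET_SCORES, timeout_rate)
  }
  knowledge_p <- as.matrix(knowledge_p)
  sensitive_prevalence <- as.matrix(sensitive_prevalence)
  control_item_p <- as.matrix(control_item_p)
  if (identical(dim(knowledge_p), c(3L, N_KNOWLEDGE_ITEMS))) {
    dimnames(knowledge_p) <- list(ARM_LEVELS, knowledge_cols())
  }
  if (identical(dim(sensitive_prevalence), c(3L, N_LIST_EXPERIMENTS))) {
    dimnames(sensitive_prevalence) <- list(ARM_LEVELS, paste0("exp", 1:5))
  }
  if (identical(dim(control_item_p), c(N_LIST_EXPERIMENTS, N_CONTROL_ITEMS))) {
    dimnames(control_item_p) <- list(paste0("exp", 1:5), paste0("item", 1:5))
  }
  cfg <- structure(list(
    n_per_cell = as.integer(n_per_cell),
    knowledge_p = as.matrix(knowledge_p),
    timeout_rate = timeout_rate,
    sensitive_prevalence = as.matrix(sensitive_prevalence),
    control_item_p = as.matrix(control_item_p),
    attrition_rate = attrition_rate,
    design_violation = design_violation,
    item_correlation = item_correlation,
    seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.na(cfg$n_per_cell) || cfg$n_per_cell < 1L) {
    stop("n_per_cell must be a positive integer")
  }
  if (!identical(dim(cfg$knowledge_p), c(3L, N_KNOWLEDGE_ITEMS))) {
    stop("knowledge_p must be a 3 x 18 matrix (arms x items)")
  }
  if (!identical(dim(cfg$sensitive_prevalence), c(3L, N_LIST_EXPERIMENTS))) {
    stop("sensitive_prevalence must be a 3 x 5 matrix (arms x experiments)")
  }
  if (!identical(dim(cfg$control_item_p), c(N_LIST_EXPERIMENTS, N_CONTROL_ITEMS))) {
    stop("control_item_p must be a 5 x 5 matrix (experiments x items)")
  }
  probs <- c(cfg$knowledge_p, cfg$sensitive_prevalence, cfg$control_item_p,
             cfg$timeout_rate, cfg$attrition_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$item_correlation < 0 || cfg$item_correlation >= 1) {
    stop("item_correlation must lie in [0, 1)")
  }
  if (is.na(cfg$seed)) stop("seed must be an integer")
  invisible(cfg)
}

#' Read a simulation configuration from JSON
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [simulation_config()] (matrices as nested arrays, row-major by arm or
#'   experiment). Omitted fields take their defaults.
#' @return A validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (m in c("knowledge_p", "sensitive_prevalence", "control_item_p")) {
    if (!is.null(raw[[m]])) raw[[m]] <- as.matrix(raw[[m]])
  }
  do.call(simulation_config, raw)
}

#' Demographic sampling frequencies
#'
#' The frozen marginal frequency tables from which [generate_trial()] draws
#' demographics: participant counts by age band, gender, country of
#' residence, education and first language from a completed five-country
#' online sample of 14,482 adults (58.8 percent resident in the UK, 26
#' percent in the US, 81.6 percent with at least some college education).
#' Demographics are sampled independently of arm, list group and outcomes:
#' they enter the pipeline only through balance tables.
#'
#' @return Named list of probability vectors (one per demographic), each
#'   summing to 1.
#' @export
demographic_marginals <- function() {
  counts <- list(
    age_band = c("18-24" = 3975, "25-34" = 5257, "35-44" = 2866,
                 "45-54" = 1735, "55-59" = 649),
    gender = c(female = 7852, male = 6537, other = 93),
    country = c(DE = 755, MX = 702, ES = 741, UK = 8519, US = 3765),
    education = c(primary = 453, high_school = 2217,
                  bachelor_some_college = 9180, masters_phd = 2632),
    first_language = c(German = 750, English = 12288,
                       Spanish_MX = 743, Spanish = 701)
  )
  lapply(counts, function(x) x / sum(x))
}

#' Generate a synthetic trial dataset
#'
#' Simulates a three-arm randomized trial with a nested list experiment in
#' every arm. Each of the six arm-by-list cells receives exactly
#' `n_per_cell` participants. Knowledge item j in arm k is answered
#' correctly with probability `knowledge_p[k, j] * (1 - timeout_rate)` and
#' times out with probability `timeout_rate`. A control-list count is the
#' sum of five independent (or latently correlated, see `item_correlation`)
#' endorsement draws; a treatment-list count adds an independent endorsement
#' of the sensitive item with the arm- and experiment-specific prevalence,
#' leaving the control items untouched unless `design_violation` is nonzero.
#' Demographics come from [demographic_marginals()]; attrition flags
#' participants as incomplete independently of everything else.
#'
#' @param config a [simulation_config()].
#' @return A [trial_dataset()] of `6 * n_per_cell` records whose provenance
#'   string records the seed.
#' @export
generate_trial <- function(config) {
  validate_simulation_config(config)
  n <- config$n_per_cell

  # One fixed substream seed per design cell, derived once from the root
  # seed, so each cell's draws are reproducible in isolation.
  cell_grid <- expand.grid(list_group = LIST_GROUP_LEVELS, arm = ARM_LEVELS,
                           stringsAsFactors = FALSE)[, c("arm", "list_group")]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cell_grid))

  marg <- demographic_marginals()
  cells <- vector("list", nrow(cell_grid))
  for (ci in seq_len(nrow(cell_grid))) {
    arm <- cell_grid$arm[ci]
    grp <- cell_grid$list_group[ci]
    set.seed(cell_seeds[ci])

    # Knowledge responses: timeout first, then correctness.
    p_arm <- config$knowledge_p[arm, ]
    timed_out <- matrix(stats::runif(n * N_KNOWLEDGE_ITEMS) < config$timeout_rate,
                        nrow = n)
    correct <- matrix(stats::runif(n * N_KNOWLEDGE_ITEMS), nrow = n) <
      matrix(p_arm, nrow = n, ncol = N_KNOWLEDGE_ITEMS, byrow = TRUE)
    resp <- matrix("incorrect", nrow = n, ncol = N_KNOWLEDGE_ITEMS)
    resp[correct] <- "correct"
    resp[timed_out] <- "timeout"

    # List-experiment counts.
    counts <- matrix(0L, nrow = n, ncol = N_LIST_EXPERIMENTS)
    for (i in seq_len(N_LIST_EXPERIMENTS)) {
      p_items <- config$control_item_p[i, ]
      if (grp == "treatment") {
        p_items <- pmin(pmax(p_items + config$design_violation, 0), 1)
      }
      counts[, i] <- draw_count(n, p_items, config$item_correlation)
      if (grp == "treatment") {
        s <- config$sensitive_prevalence[arm, i]
        counts[, i] <- counts[, i] + stats::rbinom(n, 1L, s)
      }
    }

    demo <- lapply(marg, function(p) sample(names(p), n, replace = TRUE, prob = p))
    completed <- stats::runif(n) >= config$attrition_rate

    df <- data.frame(
      participant_id = sprintf("%s_%s_%05d", arm, grp, seq_len(n)),
      arm = arm, list_group = grp,
      stringsAsFactors = FALSE
    )
    colnames(resp) <- knowledge_cols()
    colnames(counts) <- list_count_cols()
    df <- cbind(df, as.data.frame(resp, stringsAsFactors = FALSE),
                as.data.frame(counts))
    df$age_band <- demo$age_band
    df$gender <- demo$gender
    df$country <- demo$country
    df$education <- demo$education
    df$first_language <- demo$first_language
    df$completed <- completed
    cells[[ci]] <- df
  }

  records <- do.call(rbind, cells)
  trial_dataset(records,
                provenance = sprintf("synthetic seed=%d n_per_cell=%d",
                                     config$seed, config$n_per_cell))
}

# Sum of Bernoulli endorsements with optional shared latent propensity
# (Gaussian copula; marginal probabilities are exact for any correlation).
draw_count <- function(n, p_items, rho) {
  k <- length(p_items)
  if (rho == 0) {
    endorsed <- matrix(stats::runif(n * k), nrow = n) <
      matrix(p_items, nrow = n, ncol = k, byrow = TRUE)
  } else {
    z <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * k), nrow = n)
    u <- sqrt(rho) * z + sqrt(1 - rho) * e
    endorsed <- u < matrix(stats::qnorm(p_items), nrow = n, ncol = k, byrow = TRUE)
  }
  as.integer(rowSums(endorsed))
}
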