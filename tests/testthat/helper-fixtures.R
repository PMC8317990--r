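# Builders for small, fully deterministic trial datasets used across tests.

ARMS <- c("do_nothing", "apc", "covideo")
GROUPS <- c("control", "treatment")

# One participant row as a plain list; override any field.
participant_row <- function(id, arm, list_group,
                            responses = rep("correct", 18),
                            counts = rep(0L, 5),
                            completed = TRUE) {
  row <- c(list(participant_id = id, arm = arm, list_group = list_group),
           stats::setNames(as.list(responses), sprintf("k%02d", 1:18)),
           stats::setNames(as.list(as.integer(counts)), sprintf("lc%d", 1:5)),
           list(age_band = "25-34", gender = "female", country = "UK",
                education = "bachelor_some_college", first_language = "English",
                completed = completed))
  as.data.frame(row, stringsAsFactors = FALSE)
}

# n identical participants per arm x list cell.
fixture_dataset <- function(per_cell = 1, responses = rep("correct", 18),
                            counts = rep(0L, 5), completed = TRUE) {
  rows <- list()
  for (arm in ARMS) for (grp in GROUPS) for (j in seq_len(per_cell)) {
    rows[[length(rows) + 1L]] <- participant_row(
      sprintf("%s_%s_%03d", arm, grp, j), arm, grp,
      responses = responses, counts = counts, completed = completed)
  }
  trial_dataset(do.call(rbind, rows), provenance = "fixture")
}

# Dataset whose experiment-1 counts are given per cell; other experiments 0.
# `cells` is a named list like list(do_nothing.control = c(2, 2), ...).
dataset_from_counts <- function(cells) {
  rows <- list()
  for (nm in names(cells)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    y <- cells[[nm]]
    for (j in seq_along(y)) {
      rows[[length(rows) + 1L]] <- participant_row(
        sprintf("%s_%03d", nm, j), parts[1L], parts[2L],
        counts = c(y[j], 0L, 0L, 0L, 0L))
    }
  }
  trial_dataset(do.call(rbind, rows), provenance = "fixture")
}

# Random valid dataset: counts uniform on the legal range per cell, random
# knowledge responses, everything complete. Size n per cell (vectorized so
# property tests over many datasets stay fast).
random_dataset <- function(n_per_cell) {
  n <- 6L * n_per_cell
  arm <- rep(ARMS, each = 2L * n_per_cell)
  grp <- rep(rep(GROUPS, each = n_per_cell), times = 3L)
  cmax <- ifelse(grp == "treatment", 6L, 5L)
  df <- data.frame(participant_id = sprintf("p%05d", seq_len(n)),
                   arm = arm, list_group = grp, stringsAsFactors = FALSE)
  for (col in sprintf("k%02d", 1:18)) {
    df[[col]] <- sample(c("correct", "incorrect", "timeout"), n,
                        replace = TRUE, prob = c(0.9, 0.07, 0.03))
  }
  for (col in sprintf("lc%d", 1:5)) {
    df[[col]] <- as.integer(floor(stats::runif(n) * (cmax + 1L)))
  }
  df$age_band <- "25-34"; df$gender <- "female"; df$country <- "UK"
  df$education <- "bachelor_some_college"; df$first_language <- "English"
  df$completed <- TRUE
  trial_dataset(df, provenance = "fixture")
}

# Small simulation config for fast end-to-end tests.
small_config <- function(n_per_cell = 150, seed = 42, ...) {
  simulation_config(n_per_cell = n_per_cell, seed = seed, ...)
}
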