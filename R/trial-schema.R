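# Enumerations shared across the package. Levels are ordered as they appear
# in analysis output (reference arm first).
ARM_LEVELS <- c("do_nothing", "apc", "covideo")
LIST_GROUP_LEVELS <- c("control", "treatment")
RESPONSE_LEVELS <- c("correct", "incorrect", "timeout")
AGE_LEVELS <- c("18-24", "25-34", "35-44", "45-54", "55-59")
GENDER_LEVELS <- c("female", "male", "other")
COUNTRY_LEVELS <- c("DE", "MX", "ES", "UK", "US")
EDUCATION_LEVELS <- c("primary", "high_school", "bachelor_some_college", "masters_phd")
LANGUAGE_LEVELS <- c("German", "English", "Spanish_MX", "Spanish")

N_KNOWLEDGE_ITEMS <- 18L
N_LIST_EXPERIMENTS <- 5L
N_CONTROL_ITEMS <- 5L

knowledge_cols <- function() sprintf("k%02d", seq_len(N_KNOWLEDGE_ITEMS))
list_count_cols <- function() sprintf("lc%d", seq_len(N_LIST_EXPERIMENTS))

# Column contract of the trial CSV, in file order.
trial_columns <- function() {
  c("participant_id", "arm", "list_group",
    knowledge_cols(), list_count_cols(),
    "age_band", "gender", "country", "education", "first_language",
    "completed")
}

#' Construct a validated trial dataset
#'
#' A `trial_dataset` is a data frame with one row per participant and the
#' fixed column contract used throughout the package: identifier, arm
#' (`do_nothing`, `apc`, `covideo`), list-group assignment (`control`,
#' `treatment`), 18 coded knowledge responses `k01`..`k18` (each `correct`,
#' `incorrect` or `timeout`), five list-experiment counts `lc1`..`lc5`,
#' demographics, and a `completed` flag. Incomplete participants are kept in
#' the dataset; analysis functions drop them via [filter_complete()].
#'
#' @param records data frame with the columns of the trial contract.
#'   Knowledge responses may be given either as the enumeration strings or as
#'   the platform integer codes (1 = correct, 0 = incorrect, 9 = timeout);
#'   integer codes are mapped to the enumeration.
#' @param provenance free-text label recording where the records came from
#'   (e.g. a file path, or seed and configuration of a synthetic run).
#' @return A `trial_dataset` object (a data frame).
#' @export
trial_dataset <- function(records, provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  missing_cols <- setdiff(trial_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("trial dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra_cols <- setdiff(names(records), trial_columns())
  if (length(extra_cols) > 0L) {
    stop("trial dataset has unknown column(s): ", paste(extra_cols, collapse = ", "))
  }
  records <- records[, trial_columns()]

  records$participant_id <- as.character(records$participant_id)
  if (anyDuplicated(records$participant_id)) {
    stop("participant_id values must be unique")
  }

  records$arm <- validate_enum(records$arm, ARM_LEVELS, "arm")
  records$list_group <- validate_enum(records$list_group, LIST_GROUP_LEVELS, "list_group")
  for (col in knowledge_cols()) {
    records[[col]] <- decode_response(records[[col]], col)
  }
  for (i in seq_len(N_LIST_EXPERIMENTS)) {
    col <- list_count_cols()[i]
    v <- records[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != as.integer(v))) {
      stop("column ", col, " must contain non-missing integers")
    }
    v <- as.integer(v)
    max_allowed <- ifelse(records$list_group == "treatment",
                          N_CONTROL_ITEMS + 1L, N_CONTROL_ITEMS)
    bad <- which(v < 0L | v > max_allowed)
    if (length(bad) > 0L) {
      stop("column ", col, ", row ", bad[1L], ": count ", v[bad[1L]],
           " outside [0,", max_allowed[bad[1L]], "] for list_group=",
           records$list_group[bad[1L]])
    }
    records[[col]] <- v
  }
  records$age_band <- validate_enum(records$age_band, AGE_LEVELS, "age_band")
  records$gender <- validate_enum(records$gender, GENDER_LEVELS, "gender")
  records$country <- validate_enum(records$country, COUNTRY_LEVELS, "country")
  records$education <- validate_enum(records$education, EDUCATION_LEVELS, "education")
  records$first_language <- validate_enum(records$first_language, LANGUAGE_LEVELS,
                                          "first_language")

  if (!is.logical(records$completed)) {
    if (all(records$completed %in% c(0, 1))) {
      records$completed <- as.logical(as.integer(records$completed))
    } else {
      stop("column completed must be logical (or 0/1)")
    }
  }
  if (any(is.na(records$completed))) stop("column completed must be non-missing")

  rownames(records) <- NULL
  structure(records,
            provenance = as.character(provenance)[1L],
            class = c("trial_dataset", "data.frame"))
}

validate_enum <- function(x, levels, name) {
  x <- as.character(x)
  bad <- which(!(x %in% levels))
  if (length(bad) > 0L) {
    stop("column ", name, ", row ", bad[1L], ": value '", x[bad[1L]],
         "' not one of {", paste(levels, collapse = ", "), "}")
  }
  factor(x, levels = levels)
}

# Accepts enumeration strings or the source platform codes 1/0/9.
decode_response <- function(x, col) {
  if (is.numeric(x)) {
    bad <- which(!(x %in% c(0, 1, 9)))
    if (length(bad) > 0L) {
      stop("column ", col, ", row ", bad[1L], ": knowledge code ", x[bad[1L]],
           " is not one of {0, 1, 9}")
    }
    out <- character(length(x))
    out[x == 1] <- "correct"
    out[x == 0] <- "incorrect"
    out[x == 9] <- "timeout"
    return(factor(out, levels = RESPONSE_LEVELS))
  }
  validate_enum(x, RESPONSE_LEVELS, col)
}

encode_response <- function(f) {
  codes <- c(correct = 1L, incorrect = 0L, timeout = 9L)
  unname(codes[as.character(f)])
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d participants (%d complete), provenance: %s\n",
              nrow(x), sum(x$completed), attr(x, "provenance")))
  if (nrow(x) > 0L) {
    tab <- table(arm = x$arm, list_group = x$list_group)
    print(tab)
  }
  invisible(x)
}

#' Read a participant-level trial CSV
#'
#' Reads the trial interchange CSV (UTF-8, comma separated, header row, one
#' row per participant). Knowledge responses are stored in the file using the
#' source-platform codes 1 = correct, 0 = incorrect, 9 = timed out; the code
#' 9 is mapped to the distinct `timeout` level at read time so the
#' timeout-to-incorrect recode remains an explicit scoring step.
#'
#' @param path path to a CSV file following the trial column contract.
#' @return A [trial_dataset()] with provenance set to the file path.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(trial_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra_cols <- setdiff(names(raw), trial_columns())
  if (length(extra_cols) > 0L) {
    stop("CSV has unexpected column(s): ", paste(extra_cols, collapse = ", "))
  }
  for (col in c(knowledge_cols(), list_count_cols())) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v))) {
      stop("column ", col, ", row ", which(is.na(v))[1L], ": not numeric")
    }
    raw[[col]] <- v
  }
  raw$completed <- parse_logical(raw$completed, "completed")
  trial_dataset(raw, provenance = path)
}

parse_logical <- function(x, name) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  if (any(is.na(out))) {
    stop("column ", name, ", row ", which(is.na(out))[1L],
         ": value '", x[which(is.na(out))[1L]], "' is not a logical")
  }
  out
}

#' Write a trial dataset to the interchange CSV
#'
#' Rows are sorted by participant identifier and columns follow the fixed
#' contract, so writing the same dataset twice yields byte-identical files
#' and `read_trial_csv(write_trial_csv(x))` is the identity.
#'
#' @param dataset a [trial_dataset()].
#' @param path output file path.
#' @return The output path, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  out <- as.data.frame(dataset)
  out <- out[order(out$participant_id), , drop = FALSE]
  for (col in knowledge_cols()) out[[col]] <- encode_response(out[[col]])
  for (col in c("arm", "list_group", "age_band", "gender", "country",
                "education", "first_language")) {
    out[[col]] <- as.character(out[[col]])
  }
  out$completed <- ifelse(out$completed, "true", "false")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Restrict a dataset to trial completers
#'
#' Drops participants flagged as not having completed the survey;
#' all analyses are complete-case. The number removed is reported as a
#' message so pipeline logs mirror the trial's flow accounting.
#'
#' @param dataset a [trial_dataset()].
#' @return A `trial_dataset` containing only completers, otherwise unchanged.
#' @export
filter_complete <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  n0 <- nrow(dataset)
  keep <- dataset$completed
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("filter_complete: dropped %d of %d participants (%.1f%%)",
                  n0 - nrow(out), n0, if (n0 > 0) 100 * (n0 - nrow(out)) / n0 else 0))
  structure(out,
            provenance = attr(dataset, "provenance"),
            class = c("trial_dataset", "data.frame"))
}

# Requires at least one completer in every arm x list_group cell; used as the
# precondition of the analysis entry points.
assert_cells_populated <- function(dataset) {
  tab <- table(dataset$arm, dataset$list_group)
  if (any(tab == 0L)) {
    idx <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: arm=", rownames(tab)[idx[1L]],
         ", list_group=", colnames(tab)[idx[2L]])
  }
  invisible(TRUE)
}
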