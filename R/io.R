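trial_log_columns <- c("subject_id", "group_label", "session", "trial_index",
                       "trial_type", "left_stim", "right_stim", "chosen_stim",
                       "chosen_side", "reinforced")

# row-level validation shared by the reader and the fitter
check_trial_log <- function(trials, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  miss <- setdiff(trial_log_columns, names(trials))
  if (length(miss)) {
    abort(sprintf("trial log%s lacks column(s): %s", where,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(trials) == 0) return(invisible(trials))
  report <- function(bad, what) {
    if (any(bad)) {
      rows <- utils::head(which(bad), 5)
      abort(sprintf("%s at row(s) %s%s%s", what,
                    paste(rows, collapse = ", "),
                    if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else "",
                    where))
    }
  }
  report(!trials$reinforced %in% c(0L, 1L), "`reinforced` not 0/1")
  report(!trials$chosen_side %in% c("L", "R"), "`chosen_side` not L/R")
  report(!(trials$chosen_stim == trials$left_stim |
             trials$chosen_stim == trials$right_stim),
         "chosen stimulus not among those presented")
  report(!((trials$chosen_stim == trials$left_stim &
              trials$chosen_side == "L") |
             (trials$chosen_stim == trials$right_stim &
                trials$chosen_side == "R")),
         "chosen_side inconsistent with chosen stimulus position")
  report(!trials$trial_type %in% c("standard", "pos_probe", "neg_probe"),
         "unknown trial_type")
  invisible(trials)
}

#' Read and validate a trial log
#'
#' Comma-separated, UTF-8, header mandatory. Every row is validated against
#' the trial-record invariants (choice among the presented stimuli, side
#' consistent with the choice, reinforcement 0/1); violations are rejected
#' with row numbers.
#'
#' @param path CSV file path.
#' @return A validated trial-log tibble.
#' @export
read_trial_log <- function(path) {
  trials <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group_label = readr::col_character(),
      session = readr::col_integer(),
      trial_index = readr::col_integer(),
      trial_type = readr::col_character(),
      left_stim = readr::col_character(),
      right_stim = readr::col_character(),
      chosen_stim = readr::col_character(),
      chosen_side = readr::col_character(),
      reinforced = readr::col_integer(),
      .default = readr::col_guess()
    )))
  pb <- readr::problems(trials)
  if (nrow(pb)) {
    abort(sprintf("malformed value in %s: row %d, column %s (%s)", path,
                  pb$row[1], pb$col[1], pb$expected[1]))
  }
  check_trial_log(trials, file = path)
  if (nrow(trials) == 0) warn(sprintf("empty trial log: %s", path))
  trials
}

#' Write a trial log as CSV
#'
#' @param trials A trial-log tibble (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  check_trial_log(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}
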