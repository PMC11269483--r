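# one-tailed binomial cutoffs at chance p = 0.5 for a window of n trials:
# largest k with P(X <= k) < alpha (below chance) and smallest k with
# P(X >= k) < alpha (above chance); for n = 30, alpha = 0.05 these are 10
# and 20 (both tail probabilities 0.0494)
binomial_cutoffs <- function(window, alpha = 0.05) {
  ks <- 0:window
  below <- ks[pbinom(ks, window, 0.5) < alpha]
  above <- ks[pbinom(ks - 1, window, 0.5, lower.tail = FALSE) < alpha]
  c(below = if (length(below)) max(below) else -1L,
    above = if (length(above)) min(above) else window + 1L)
}

#' Code post-reversal trials as perseverative, random, or learning
#'
#' Rolling windows of `window` trials over the concatenated standard-trial
#' outcome sequence are tested against chance with one-tailed binomial
#' cutoffs (for a 30-trial window at alpha = 0.05: <= 10 correct is below
#' chance, >= 20 is above). Each trial is labelled by the first window ending
#' at it, under the monotone phase order perseverative -> random ->
#' learning: once performance is no longer below chance the perseverative
#' phase is closed, and the first above-chance window opens the learning
#' phase permanently. Trials before the first complete window inherit its
#' label. Sequences shorter than the window are labelled random with a
#' warning.
#'
#' @param correct Logical/0-1 vector of standard-trial outcomes, in trial
#'   order (sessions concatenated).
#' @param window Rolling window length (default 30).
#' @param alpha One-tailed significance level for the binomial cutoffs.
#' @return A tibble (`trial_index`, `correct`, `phase`) with attributes
#'   `boundaries` (first trial of the random and learning phases, NA if the
#'   phase never starts) and `cutoffs`.
#' @export
label_phases <- function(correct, window = 30, alpha = 0.05) {
  if (window < 1) abort("`window` must be >= 1")
  correct <- as.logical(correct)
  n <- length(correct)
  lev <- c("perseverative", "random", "learning")
  if (n < window) {
    warn(sprintf("sequence shorter than %d trials: labelled random", window))
    out <- tibble(trial_index = seq_len(n), correct = correct,
                  phase = factor(rep("random", n), levels = lev))
    attr(out, "boundaries") <- tibble(random_start = NA_integer_,
                                      learning_start = NA_integer_)
    return(out)
  }
  cut <- binomial_cutoffs(window, alpha)
  cs <- cumsum(correct)
  k <- cs[window:n] - c(0, cs)[1:(n - window + 1)]
  t_end <- window:n
  not_below <- t_end[k > cut["below"]]
  above <- t_end[k >= cut["above"]]
  random_start <- if (length(not_below)) not_below[1] else Inf
  learning_start <- if (length(above)) above[1] else Inf
  lab <- function(t) {
    if (t < random_start) "perseverative"
    else if (t < learning_start) "random"
    else "learning"
  }
  phase <- vapply(seq_len(n), function(t) lab(max(t, window)), character(1))
  out <- tibble(trial_index = seq_len(n), correct = correct,
                phase = factor(phase, levels = lev))
  attr(out, "boundaries") <- tibble(
    random_start = if (is.finite(random_start)) as.integer(random_start) else NA_integer_,
    learning_start = if (is.finite(learning_start)) as.integer(learning_start) else NA_integer_)
  attr(out, "cutoffs") <- cut
  out
}

#' Errors to criterion on the standard trials
#'
#' Counts incorrect responses from the start of the sequence up to and
#' including the end of the first disjoint block of `block_size` trials with
#' at least `criterion` correct (default 24/30). If the criterion is never
#' reached, all errors are counted and the `criterion_reached` marker is
#' `FALSE`. Trailing partial blocks cannot qualify.
#'
#' @param correct Logical/0-1 outcome vector in trial order.
#' @param criterion Correct responses required within a block (default 24).
#' @param block_size Block length (default 30).
#' @return One-row tibble: `errors`, `criterion_reached`, `criterion_trial`
#'   (last trial of the qualifying block, NA if never reached).
#' @export
errors_to_criterion <- function(correct, criterion = 24, block_size = 30) {
  correct <- as.logical(correct)
  n <- length(correct)
  n_blocks <- n %/% block_size
  if (n_blocks > 0) {
    sums <- vapply(seq_len(n_blocks), function(b) {
      sum(correct[((b - 1) * block_size + 1):(b * block_size)])
    }, numeric(1))
    qual <- which(sums >= criterion)
    if (length(qual)) {
      end <- qual[1] * block_size
      return(tibble(errors = sum(!correct[seq_len(end)]),
                    criterion_reached = TRUE,
                    criterion_trial = as.integer(end)))
    }
  }
  tibble(errors = sum(!correct), criterion_reached = FALSE,
         criterion_trial = NA_integer_)
}

#' Pre-criterion errors split by behavioural phase
#'
#' Truncates the outcome sequence at the criterion point of
#' [errors_to_criterion()] (or uses it all if the criterion is never
#' reached), labels the truncated sequence with [label_phases()], and counts
#' errors within each phase. The three counts sum to the total pre-criterion
#' error count.
#'
#' @inheritParams label_phases
#' @inheritParams errors_to_criterion
#' @return A tibble with one row per phase (`phase`, `errors`).
#' @export
errors_per_phase <- function(correct, window = 30, criterion = 24,
                             block_size = 30, alpha = 0.05) {
  etc <- errors_to_criterion(correct, criterion, block_size)
  upto <- if (etc$criterion_reached) etc$criterion_trial else length(correct)
  lp <- suppressWarnings(label_phases(correct[seq_len(upto)], window, alpha))
  counts <- table(lp$phase[!lp$correct])
  tibble(phase = names(counts), errors = as.integer(counts))
}

# current reward roles per trial row: rows in the reversal phase use the
# reversed contingency of the supplied (discrimination-phase) stimulus set
row_roles <- function(trials, stimulus_set) {
  base <- stimulus_roles(stimulus_set)
  rev <- stimulus_roles(apply_reversal(stimulus_set))
  reversed <- if ("phase" %in% names(trials)) {
    trials$phase == "reversal"
  } else {
    rep(FALSE, nrow(trials))
  }
  list(rewarded = ifelse(reversed, rev["rewarded"], base["rewarded"]),
       punished = ifelse(reversed, rev["punished"], base["punished"]),
       probe = base["probe"])
}

#' Per-session percent-correct and percent-optimal-choice measures
#'
#' Standard trials: percent choosing the currently rewarded stimulus.
#' Positive probes (current A vs C): percent choosing A. Negative probes
#' (current B vs C): percent choosing C. The highest reward-probability
#' option defines "optimal". Sessions with no trials of a type yield `NA`,
#' not 0.
#'
#' @param trials Trial-log tibble. If a `phase` column is present, rows in
#'   the `"reversal"` phase are scored under the reversed contingency.
#' @param stimulus_set The discrimination-phase [stimulus_set()].
#' @return Tibble per subject x session: `pct_correct_standard`,
#'   `pct_optimal_pos_probe`, `pct_optimal_neg_probe`.
#' @export
percent_measures <- function(trials, stimulus_set = vpvdrl::stimulus_set()) {
  check_stimulus_set(stimulus_set)
  roles <- row_roles(trials, stimulus_set)
  probe <- stimulus_roles(stimulus_set)[["probe"]]
  df <- dplyr::mutate(
    trials,
    optimal_stim = dplyr::case_when(
      .data$trial_type == "neg_probe" ~ probe,
      TRUE ~ roles$rewarded
    ),
    optimal = .data$chosen_stim == .data$optimal_stim
  )
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(df, .data$subject_id, .data$group_label,
                      .data$session, .data$trial_type),
      pct = 100 * mean(.data$optimal), .groups = "drop"),
    names_from = "trial_type", values_from = "pct")
  for (col in c("standard", "pos_probe", "neg_probe")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  dplyr::rename(wide,
                pct_correct_standard = "standard",
                pct_optimal_pos_probe = "pos_probe",
                pct_optimal_neg_probe = "neg_probe")
}

#' Win-stay / lose-shift proportions
#'
#' Over consecutive-trial pairs within a session where the previously chosen
#' stimulus is available again: `win_stay` is the probability of repeating
#' the previous choice after reinforcement, `lose_shift` the probability of
#' switching after non-reinforcement. Subjects with no eligible pairs of a
#' kind get `NA`.
#'
#' @param trials Trial-log tibble.
#' @return Tibble per subject: `win_stay`, `lose_shift`, `n_win`, `n_lose`.
#' @export
win_stay_lose_shift <- function(trials) {
  df <- dplyr::mutate(
    dplyr::group_by(
      dplyr::arrange(trials, .data$subject_id, .data$session,
                     .data$trial_index),
      .data$subject_id, .data$session),
    prev_stim = dplyr::lag(.data$chosen_stim),
    prev_r = dplyr::lag(.data$reinforced),
    eligible = !is.na(.data$prev_stim) &
      (.data$prev_stim == .data$left_stim |
         .data$prev_stim == .data$right_stim),
    stay = .data$chosen_stim == .data$prev_stim
  )
  res <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(df), .data$subject_id),
    n_win = sum(.data$eligible & .data$prev_r == 1, na.rm = TRUE),
    n_lose = sum(.data$eligible & .data$prev_r == 0, na.rm = TRUE),
    win_stay = mean(.data$stay[.data$eligible & .data$prev_r == 1]),
    lose_shift = mean(!.data$stay[.data$eligible & .data$prev_r == 0]),
    .groups = "drop")
  dplyr::mutate(res,
                win_stay = ifelse(is.nan(.data$win_stay), NA_real_, .data$win_stay),
                lose_shift = ifelse(is.nan(.data$lose_shift), NA_real_, .data$lose_shift))
}

#' Conventional behavioural metrics of a trial log
#'
#' Umbrella analysis: per-session percent measures for all phases, and
#' per-subject reversal metrics (errors to criterion with the 24/30 rule,
#' errors per perseverative/random/learning phase, win-stay/lose-shift).
#' Phase coding and errors-to-criterion use the standard trials of the
#' reversal phase, concatenated across sessions; probe trials are excluded
#' from both.
#'
#' @param trials Trial-log tibble (with a `phase` column if it contains
#'   discrimination sessions).
#' @param stimulus_set The discrimination-phase [stimulus_set()].
#' @param window,criterion,block_size,alpha Phase-coding and criterion
#'   settings (defaults 30, 24, 30, 0.05).
#' @return List of class `vpvd_metrics` with tibbles `session` and
#'   `subject`.
#' @export
vpvd_metrics <- function(trials, stimulus_set = vpvdrl::stimulus_set(),
                         window = 30, criterion = 24, block_size = 30,
                         alpha = 0.05) {
  check_stimulus_set(stimulus_set)
  session_tbl <- percent_measures(trials, stimulus_set)
  rev_trials <- if ("phase" %in% names(trials)) {
    dplyr::filter(trials, .data$phase == "reversal")
  } else {
    trials
  }
  std <- dplyr::filter(rev_trials, .data$trial_type == "standard")
  roles_std <- row_roles(std, stimulus_set)
  std <- dplyr::arrange(
    dplyr::mutate(std, correct = .data$chosen_stim == roles_std$rewarded),
    .data$subject_id, .data$session, .data$trial_index)
  subject_tbl <- purrr::map_dfr(split(std, std$subject_id), function(d) {
    etc <- errors_to_criterion(d$correct, criterion, block_size)
    epp <- errors_per_phase(d$correct, window, criterion, block_size, alpha)
    epp_wide <- setNames(as.list(epp$errors), paste0("errors_", epp$phase))
    dplyr::bind_cols(
      tibble(subject_id = d$subject_id[1], group_label = d$group_label[1]),
      etc, as_tibble(epp_wide))
  })
  wsls <- win_stay_lose_shift(rev_trials)
  subject_tbl <- dplyr::left_join(subject_tbl, wsls, by = "subject_id")
  structure(list(session = session_tbl, subject = subject_tbl),
            class = "vpvd_metrics")
}

#' @export
print.vpvd_metrics <- function(x, ...) {
  cat(sprintf("<vpvd_metrics> %d subjects, %d subject-sessions\n",
              nrow(x$subject), nrow(x$session)))
  print(x$subject, n = 5)
  invisible(x)
}
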