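#' Define the three-stimulus set of a VPVD experiment
#'
#' The valence-probe visual discrimination (VPVD) task uses three stimuli:
#' `a` is reinforced on every choice ("A+"), `b` is never reinforced ("B-"),
#' and the probe stimulus `c` is reinforced on 50% of choices. A reversal
#' swaps the roles of `a` and `b`; the probe is unaffected.
#'
#' @param a,b,c Stimulus identifiers (distinct character scalars).
#' @param reversed Logical; has the A/B contingency been reversed?
#' @return An object of class `vpvd_stimulus_set`.
#' @examples
#' ss <- stimulus_set()
#' apply_reversal(ss)
#' @export
stimulus_set <- function(a = "A", b = "B", c = "C", reversed = FALSE) {
  ids <- c(a, b, c)
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("stimulus identifiers must be three distinct non-empty strings")
  }
  structure(
    list(a = a, b = b, c = c, reversed = isTRUE(reversed)),
    class = "vpvd_stimulus_set"
  )
}

#' @export
print.vpvd_stimulus_set <- function(x, ...) {
  roles <- stimulus_roles(x)
  cat("<vpvd_stimulus_set>",
      sprintf("rewarded: %s  punished: %s  probe(50%%): %s%s",
              roles["rewarded"], roles["punished"], roles["probe"],
              if (x$reversed) "  [reversed]" else ""),
      sep = "\n")
  invisible(x)
}

#' Swap the A/B reward contingencies
#'
#' Applying a reversal twice restores the original contingency (involution).
#'
#' @param stimulus_set A [stimulus_set()].
#' @return The stimulus set with the `reversed` flag toggled.
#' @export
apply_reversal <- function(stimulus_set) {
  check_stimulus_set(stimulus_set)
  stimulus_set$reversed <- !stimulus_set$reversed
  stimulus_set
}

# current reward roles, honouring the reversed flag
stimulus_roles <- function(stimulus_set) {
  if (stimulus_set$reversed) {
    c(rewarded = stimulus_set$b, punished = stimulus_set$a,
      probe = stimulus_set$c)
  } else {
    c(rewarded = stimulus_set$a, punished = stimulus_set$b,
      probe = stimulus_set$c)
  }
}

# per-stimulus reward probabilities under the current contingency,
# named by stimulus identifier
reward_probs <- function(stimulus_set) {
  roles <- stimulus_roles(stimulus_set)
  setNames(c(1, 0, 0.5), roles[c("rewarded", "punished", "probe")])
}

check_stimulus_set <- function(x) {
  if (!inherits(x, "vpvd_stimulus_set")) {
    abort("`stimulus_set` must be created with stimulus_set()")
  }
  invisible(x)
}

#' Generate one VPVD session schedule
#'
#' Builds the trial list for a single session: within every disjoint 8-trial
#' bin one positive probe (A vs C) and one negative probe (B vs C) are placed
#' at random positions 2..8 of the bin (never the first trial of a bin); all
#' other trials are standard A-vs-B trials. Left/right placement of the two
#' stimuli is an independent fair coin per trial. If `max_trials` is not a
#' multiple of `bin_size`, the trailing partial bin contains only standard
#' trials.
#'
#' @param max_trials Number of trials in the session (>= `bin_size`).
#' @param seed Optional integer seed; the schedule is deterministic for a
#'   fixed seed. If `NULL`, the current RNG stream is used.
#' @param stimulus_set A [stimulus_set()]; only the identities are used (the
#'   schedule is contingency-agnostic).
#' @param bin_size Probe bin length (default 8).
#' @return A tibble with columns `trial_index`, `trial_type`
#'   (`"standard"`, `"pos_probe"`, `"neg_probe"`), `left_stim`, `right_stim`.
#' @examples
#' sched <- generate_schedule(200, seed = 1)
#' table(sched$trial_type)
#' @export
generate_schedule <- function(max_trials = 200, seed = NULL,
                              stimulus_set = vpvdrl::stimulus_set(),
                              bin_size = 8) {
  check_stimulus_set(stimulus_set)
  if (!is.numeric(max_trials) || max_trials < bin_size) {
    abort(sprintf(
      "`max_trials` must be at least %d (one full probe bin); got %s",
      bin_size, format(max_trials)))
  }
  if (!is.null(seed)) set.seed(seed)
  max_trials <- as.integer(max_trials)
  n_bins <- max_trials %/% bin_size

  trial_type <- rep("standard", max_trials)
  for (b in seq_len(n_bins)) {
    pos <- sample(2:bin_size, 2L) # never position 1 of the bin
    trial_type[(b - 1L) * bin_size + pos] <- sample(c("pos_probe", "neg_probe"))
  }

  roles <- stimulus_roles(stimulus_set)
  pair <- list(
    standard  = unname(roles[c("rewarded", "punished")]),
    pos_probe = unname(roles[c("rewarded", "probe")]),
    neg_probe = unname(roles[c("punished", "probe")])
  )
  first_left <- runif(max_trials) < 0.5
  s1 <- vapply(pair[trial_type], `[`, character(1), 1L)
  s2 <- vapply(pair[trial_type], `[`, character(1), 2L)

  tibble(
    trial_index = seq_len(max_trials),
    trial_type = trial_type,
    left_stim = ifelse(first_left, s1, s2),
    right_stim = ifelse(first_left, s2, s1)
  )
}

#' Independently validate a session schedule
#'
#' Re-checks the schedule invariants from first principles: one positive and
#' one negative probe per complete bin, neither on the first trial of a bin,
#' correct stimulus pairings per trial type, distinct sides, and length.
#'
#' @param schedule A schedule tibble as returned by [generate_schedule()].
#' @param stimulus_set The [stimulus_set()] the schedule was built for.
#' @param bin_size Probe bin length (default 8).
#' @param max_trials Maximum admissible session length (default 200).
#' @return `TRUE` if valid, otherwise `FALSE` with a `problems` attribute
#'   listing the violated invariants.
#' @export
validate_schedule <- function(schedule,
                              stimulus_set = vpvdrl::stimulus_set(),
                              bin_size = 8, max_trials = 200) {
  check_stimulus_set(stimulus_set)
  problems <- character()
  n <- nrow(schedule)
  if (n > max_trials) problems <- c(problems, "session longer than max_trials")
  if (!identical(schedule$trial_index, seq_len(n))) {
    problems <- c(problems, "trial_index is not 1..n")
  }
  pair_ok <- switch_pair_check(schedule, stimulus_set)
  if (!all(pair_ok)) {
    problems <- c(problems, sprintf("wrong stimulus pair on %d trial(s)",
                                    sum(!pair_ok)))
  }
  if (any(schedule$left_stim == schedule$right_stim)) {
    problems <- c(problems, "left and right stimulus identical on some trial")
  }
  bin <- (schedule$trial_index - 1L) %/% bin_size + 1L
  pos_in_bin <- (schedule$trial_index - 1L) %% bin_size + 1L
  complete <- bin <= n %/% bin_size
  for (b in unique(bin[complete])) {
    tt <- schedule$trial_type[bin == b]
    if (sum(tt == "pos_probe") != 1L || sum(tt == "neg_probe") != 1L) {
      problems <- c(problems, sprintf("bin %d lacks exactly one probe of each type", b))
    }
  }
  if (any(schedule$trial_type != "standard" & pos_in_bin == 1L)) {
    problems <- c(problems, "probe on the first trial of a bin")
  }
  if (any(schedule$trial_type[!complete] != "standard")) {
    problems <- c(problems, "probe in the trailing partial bin")
  }
  if (length(problems) > 0) {
    return(structure(FALSE, problems = problems))
  }
  TRUE
}

switch_pair_check <- function(schedule, stimulus_set) {
  roles <- stimulus_roles(stimulus_set)
  want <- list(
    standard  = sort(unname(roles[c("rewarded", "punished")])),
    pos_probe = sort(unname(roles[c("rewarded", "probe")])),
    neg_probe = sort(unname(roles[c("punished", "probe")]))
  )
  mapply(function(tt, l, r) identical(sort(c(l, r)), want[[tt]]),
         schedule$trial_type, schedule$left_stim, schedule$right_stim)
}

#' Reinforcement outcome of a single choice
#'
#' Choosing the currently rewarded stimulus yields 1, the punished stimulus 0,
#' and the probe stimulus 1 with probability 0.5 (decided by the supplied
#' uniform draw `u`).
#'
#' @param trial A one-row schedule (list or tibble row) with `left_stim` and
#'   `right_stim`.
#' @param chosen_stim The chosen stimulus; must be presented on the trial.
#' @param stimulus_set The current [stimulus_set()] (reversal-aware).
#' @param u A uniform(0,1) draw used only for the probe stimulus.
#' @return Integer 0 or 1.
#' @export
reward_outcome <- function(trial, chosen_stim, stimulus_set,
                           u = runif(1)) {
  check_stimulus_set(stimulus_set)
  if (!chosen_stim %in% c(trial$left_stim, trial$right_stim)) {
    abort(sprintf("chosen stimulus '%s' was not presented on this trial (%s vs %s)",
                  chosen_stim, trial$left_stim, trial$right_stim))
  }
  p <- reward_probs(stimulus_set)[[chosen_stim]]
  as.integer(u < p)
}
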