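# small cohorts and hand-built logs shared across test files

tiny_cohort <- function(seed = 7, model = 9, effects = "null",
                        n_per_group = 2, sessions_pre = 1,
                        sessions_post = 2, max_trials = 48) {
  generate_cohort(cohort_config(
    n_per_group = n_per_group, sessions_pre = sessions_pre,
    sessions_post = sessions_post, max_trials = max_trials,
    model = model, effects = effects, seed = seed))
}

# build a one-subject trial log from explicit choices on standard trials
hand_log <- function(chosen, reinforced, left = NULL, right = NULL,
                     session = 1) {
  n <- length(chosen)
  if (is.null(left)) left <- rep("A", n)
  if (is.null(right)) right <- rep("B", n)
  tibble::tibble(
    subject_id = "s01", group_label = "vehicle", session = session,
    trial_index = seq_len(n), trial_type = "standard",
    left_stim = left, right_stim = right, chosen_stim = chosen,
    chosen_side = ifelse(chosen == left, "L", "R"),
    reinforced = as.integer(reinforced))
}

# random single-subject session log with valid structure
random_session <- function(n = 40, seed = 1, session = 1) {
  set.seed(seed)
  sched <- generate_schedule(n)
  pick_left <- runif(n) < 0.5
  tibble::tibble(
    subject_id = "s01", group_label = "vehicle", session = session,
    trial_index = sched$trial_index, trial_type = sched$trial_type,
    left_stim = sched$left_stim, right_stim = sched$right_stim,
    chosen_stim = ifelse(pick_left, sched$left_stim, sched$right_stim),
    chosen_side = ifelse(pick_left, "L", "R"),
    reinforced = rbinom(n, 1, 0.5))
}

# independent brute-force phase classifier used as the oracle:
# classifies every complete window, then applies the monotone phase order
brute_force_phases <- function(correct, window = 30, alpha = 0.05) {
  n <- length(correct)
  lev <- c("perseverative", "random", "learning")
  if (n < window) return(factor(rep("random", n), levels = lev))
  cdf_lo <- max(c(-1, (0:window)[pbinom(0:window, window, 0.5) < alpha]))
  sf <- pbinom((0:window) - 1, window, 0.5, lower.tail = FALSE)
  cut_hi <- min(c(window + 1, (0:window)[sf < alpha]))
  cls <- sapply(window:n, function(t) {
    k <- sum(correct[(t - window + 1):t])
    if (k <= cdf_lo) "below" else if (k >= cut_hi) "above" else "chance"
  })
  phase <- character(n)
  state <- "perseverative"
  for (t in window:n) {
    c_t <- cls[t - window + 1]
    if (state == "perseverative" && c_t != "below") state <- "random"
    if (c_t == "above") state <- "learning"
    phase[t] <- state
  }
  phase[1:(window - 1)] <- phase[window]
  factor(phase, levels = lev)
}
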