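test_that("binomial cutoffs for 30-trial windows are 10 and 20", {
  cut <- vpvdrl:::binomial_cutoffs(30, 0.05)
  expect_equal(unname(cut["below"]), 10)
  expect_equal(unname(cut["above"]), 20)
  # the tail probabilities actually fall below 0.05 at those counts
  expect_lt(pbinom(10, 30, 0.5), 0.05)
  expect_gt(pbinom(11, 30, 0.5), 0.05)
  expect_lt(pbinom(19, 30, 0.5, lower.tail = FALSE), 0.05)
  expect_gt(pbinom(18, 30, 0.5, lower.tail = FALSE), 0.05)
})

test_that("hand-built sequences yield the expected phase labels", {
  # 60 consecutive errors: all perseverative
  lp <- label_phases(rep(FALSE, 60))
  expect_true(all(lp$phase == "perseverative"))
  # strict alternation (15/30 in every window): all random
  lp2 <- label_phases(rep(c(TRUE, FALSE), 30))
  expect_true(all(lp2$phase == "random"))
  # 30 errors then 60 correct: ordered perseverative -> random -> learning
  lp3 <- label_phases(c(rep(FALSE, 30), rep(TRUE, 60)))
  expect_equal(as.character(lp3$phase[1]), "perseverative")
  expect_equal(as.character(lp3$phase[90]), "learning")
  runs <- rle(as.character(lp3$phase))
  expect_equal(runs$values, c("perseverative", "random", "learning"))
  b <- attr(lp3, "boundaries")
  # first window not below chance ends at trial 41 (11 correct of last 30);
  # first window above chance ends at trial 50 (20 correct of last 30)
  expect_equal(b$random_start, 41L)
  expect_equal(b$learning_start, 50L)
})

test_that("phases are monotone and match the brute-force classifier", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(30:120, 1)
    p <- runif(1, 0.2, 0.8)
    x <- runif(n) < p
    got <- label_phases(x)$phase
    want <- brute_force_phases(x)
    expect_identical(got, want)
    expect_true(all(diff(as.integer(got)) >= 0))
  }
})

test_that("short sequences are labelled random with a warning", {
  expect_warning(lp <- label_phases(rep(TRUE, 10)), "shorter")
  expect_true(all(lp$phase == "random"))
})

test_that("errors to criterion match hand counts under the 24/30 rule", {
  # all correct: criterion in block 1, zero errors
  e1 <- errors_to_criterion(rep(TRUE, 60))
  expect_equal(e1$errors, 0L)
  expect_true(e1$criterion_reached)
  expect_equal(e1$criterion_trial, 30L)
  # 30 errors then all correct: block 2 qualifies, 30 errors
  e2 <- errors_to_criterion(c(rep(FALSE, 30), rep(TRUE, 60)))
  expect_equal(e2$errors, 30L)
  expect_equal(e2$criterion_trial, 60L)
  # 25/30 then 20/30: only block 1 qualifies
  x <- c(rep(TRUE, 25), rep(FALSE, 5), rep(TRUE, 20), rep(FALSE, 10))
  e3 <- errors_to_criterion(x)
  expect_equal(e3$criterion_trial, 30L)
  expect_equal(e3$errors, 5L)
  # never above chance: marker set, all errors counted
  e4 <- errors_to_criterion(rep(c(TRUE, FALSE), 30))
  expect_false(e4$criterion_reached)
  expect_equal(e4$errors, 30L)
})

test_that("per-phase errors sum to the pre-criterion total", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(sample(40:150, 1)) < runif(1, 0.3, 0.9)
    epp <- errors_per_phase(x)
    etc <- errors_to_criterion(x)
    upto <- if (etc$criterion_reached) etc$criterion_trial else length(x)
    expect_equal(sum(epp$errors), sum(!x[seq_len(upto)]))
  }
})

test_that("percent measures score optimal choice per trial type", {
  coh <- tiny_cohort(seed = 3)
  ss <- coh$config$stimulus_set
  pm <- percent_measures(coh$trials, ss)
  expect_true(all(pm$pct_correct_standard >= 0 &
                    pm$pct_correct_standard <= 100, na.rm = TRUE))
  # a perfect agent scores 100 on all three measures
  sched <- dplyr::mutate(generate_schedule(40, seed = 2), session = 1)
  opt <- ifelse(sched$trial_type == "neg_probe", "C", "A")
  perfect <- tibble::tibble(
    subject_id = "s", group_label = "g", session = 1,
    trial_index = sched$trial_index, trial_type = sched$trial_type,
    left_stim = sched$left_stim, right_stim = sched$right_stim,
    chosen_stim = opt, chosen_side = ifelse(opt == sched$left_stim, "L", "R"),
    reinforced = 1L)
  pp <- percent_measures(perfect, stimulus_set())
  expect_equal(pp$pct_correct_standard, 100)
  expect_equal(pp$pct_optimal_pos_probe, 100)
  expect_equal(pp$pct_optimal_neg_probe, 100)
  # uniformly random choices sit near 50 on each measure
  set.seed(11)
  big <- dplyr::mutate(generate_schedule(800, seed = 12, bin_size = 8),
                       session = 1)
  pick_left <- runif(800) < 0.5
  rand <- dplyr::mutate(big,
    subject_id = "s", group_label = "g",
    chosen_stim = ifelse(pick_left, .data$left_stim, .data$right_stim),
    chosen_side = ifelse(pick_left, "L", "R"), reinforced = 0L)
  pr <- percent_measures(rand, stimulus_set())
  expect_lt(abs(pr$pct_correct_standard - 50), 3 * 100 * sqrt(0.25 / 600))
  expect_lt(abs(pr$pct_optimal_pos_probe - 50), 3 * 100 * sqrt(0.25 / 100))
})

test_that("reversal-phase rows are scored under the reversed contingency", {
  # an agent that always picks stimulus B is wrong pre-reversal and
  # correct post-reversal on standard trials
  mk <- function(phase, session) {
    sched <- dplyr::mutate(
      generate_schedule(40, seed = session,
                        stimulus_set = if (phase == "reversal")
                          apply_reversal(stimulus_set()) else stimulus_set()),
      session = session, phase = phase)
    std <- sched
    chooses <- ifelse(std$left_stim == "B" | std$right_stim == "B", "B",
                      std$left_stim)
    dplyr::mutate(std, subject_id = "s", group_label = "g",
                  chosen_stim = chooses,
                  chosen_side = ifelse(chooses == .data$left_stim, "L", "R"),
                  reinforced = 0L)
  }
  log <- dplyr::bind_rows(mk("discrimination", 1), mk("reversal", 2))
  pm <- percent_measures(log, stimulus_set())
  expect_equal(pm$pct_correct_standard[pm$session == 1], 0)
  expect_equal(pm$pct_correct_standard[pm$session == 2], 100)
})

test_that("win-stay/lose-shift matches hand counts and limits", {
  # always-repeat agent: win_stay 1, lose_shift 0
  rep_log <- hand_log(rep("A", 10), c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1))
  w <- win_stay_lose_shift(rep_log)
  expect_equal(w$win_stay, 1)
  expect_equal(w$lose_shift, 0)
  # always-alternate agent: win_stay 0, lose_shift 1
  alt <- hand_log(rep(c("A", "B"), 5), rep(c(1, 0), 5))
  wa <- win_stay_lose_shift(alt)
  expect_equal(wa$win_stay, 0)
  expect_equal(wa$lose_shift, 1)
  # hand-built 6-trial log: pairs (A1->A), (A1->B), (B0->B), (B0->A), (A1->A)
  h <- hand_log(c("A", "A", "B", "B", "A", "A"), c(1, 1, 0, 0, 1, 1))
  wh <- win_stay_lose_shift(h)
  expect_equal(wh$n_win, 3L)
  expect_equal(wh$n_lose, 2L)
  expect_equal(wh$win_stay, 2 / 3)
  expect_equal(wh$lose_shift, 1 / 2)
})

test_that("metrics are invariant to relabelling screen sides", {
  coh <- tiny_cohort(seed = 19)
  ss <- coh$config$stimulus_set
  m1 <- vpvd_metrics(coh$trials, ss)
  flipped <- dplyr::mutate(coh$trials,
    tmp = .data$left_stim, left_stim = .data$right_stim,
    right_stim = .data$tmp, tmp = NULL,
    chosen_side = ifelse(.data$chosen_side == "L", "R", "L"))
  m2 <- vpvd_metrics(flipped, ss)
  expect_equal(m1$session, m2$session)
  expect_equal(m1$subject, m2$subject)
})
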