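test_that("cohort size follows the configuration arithmetic", {
  cfg <- cohort_config(n_per_group = 2, sessions_pre = 0, sessions_post = 3,
                       max_trials = 40, seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$trials), 3 * 2 * 3 * 40)
  expect_equal(length(unique(coh$trials$subject_id)), 6)
  # truth and trial log name the same subjects
  expect_setequal(unique(coh$truth$subject_id), unique(coh$trials$subject_id))
})

test_that("cohorts are deterministic in the seed", {
  cfg <- cohort_config(n_per_group = 1, sessions_pre = 1, sessions_post = 1,
                       max_trials = 24, seed = 9)
  expect_identical(generate_cohort(cfg)$trials, generate_cohort(cfg)$trials)
})

test_that("generated schedules pass the independent validator", {
  coh <- tiny_cohort(seed = 13)
  ss <- coh$config$stimulus_set
  per <- split(coh$trials, interaction(coh$trials$subject_id,
                                       coh$trials$session, drop = TRUE))
  for (d in per) {
    set_d <- if (d$phase[1] == "reversal") apply_reversal(ss) else ss
    sch <- dplyr::select(d, "trial_index", "trial_type", "left_stim",
                         "right_stim")
    expect_true(validate_schedule(sch, set_d, max_trials = 48))
  }
})

test_that("subject draws follow the group-level distribution", {
  # degenerate SDs: every subject equals the group mean
  cfg0 <- cohort_config(n_per_group = 3, group_sds = c(
    alpha_rew = 1e-12, alpha_pun = 1e-12, beta = 1e-12, kappa_side = 1e-12,
    kappa_stim = 1e-12, rho = 1e-12), seed = 2)
  set.seed(1)
  a <- sample_subject_params(cfg0, "vehicle")$transformed
  b <- sample_subject_params(cfg0, "vehicle")$transformed
  expect_equal(a, b, tolerance = 1e-6)
  expect_equal(unname(a["beta"]), log(4), tolerance = 1e-6)
  # logit-mean 0 maps to natural-scale mean about 0.5
  cfg1 <- cohort_config(group_means = c(alpha_rew = 0),
                        group_sds = c(alpha_rew = 1e-12), seed = 3)
  set.seed(2)
  d <- sample_subject_params(cfg1, "vehicle")$natural
  expect_equal(d$alpha_rew, 0.5, tolerance = 1e-6)
})

test_that("effect presets shift only the targeted group means", {
  cfg <- cohort_config(effects = "2a-low", seed = 1)
  tm <- true_group_means(cfg)
  veh <- tm[tm$group == "vehicle", ]
  low <- tm[tm$group == "low", ]
  gap <- low$mean_transformed - veh$mean_transformed
  names(gap) <- low$parameter
  expect_equal(unname(gap["alpha_pun"]), -0.8)
  expect_equal(unname(gap["beta"]), -0.4)
  expect_equal(unname(gap["kappa_side"]), 0.4)
  expect_equal(unname(gap["kappa_stim"]), 0.4)
  expect_equal(unname(gap["alpha_rew"]), 0)
  high <- tm[tm$group == "high", ]
  expect_equal(high$mean_transformed, veh$mean_transformed)
  # presets referring to absent parameters are rejected
  expect_error(cohort_config(model = 7, effects = "2a-low"), "absent")
})

test_that("higher reinforcement sensitivity speeds learning", {
  base <- cohort_config(n_per_group = 4, sessions_pre = 0, sessions_post = 2,
                        max_trials = 104, model = 1, seed = 5,
                        group_means = c(beta = log(0.5)),
                        group_sds = c(beta = 0.05))
  sharp <- cohort_config(n_per_group = 4, sessions_pre = 0, sessions_post = 2,
                         max_trials = 104, model = 1, seed = 5,
                         group_means = c(beta = log(5)),
                         group_sds = c(beta = 0.05))
  pct <- function(cfg) {
    coh <- generate_cohort(cfg)
    m <- vpvd_metrics(coh$trials, cfg$stimulus_set)
    mean(m$session$pct_correct_standard[m$session$session == 2])
  }
  expect_gt(pct(sharp), pct(base))
})

test_that("vehicle-group accuracy rises across post-reversal sessions", {
  cfg <- cohort_config(n_per_group = 6, sessions_pre = 0, sessions_post = 4,
                       max_trials = 104, model = 9, seed = 8)
  coh <- generate_cohort(cfg)
  m <- vpvd_metrics(coh$trials, cfg$stimulus_set)
  veh <- m$session[m$session$group_label == "vehicle", ]
  by_session <- tapply(veh$pct_correct_standard, veh$session, mean)
  expect_gt(by_session[length(by_session)], by_session[1])
})
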