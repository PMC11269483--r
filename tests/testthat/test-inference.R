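test_that("hdi matches closed-form normal quantiles", {
  set.seed(1)
  h <- hdi(rnorm(1e6), 0.95)
  expect_equal(unname(h[1]), -1.96, tolerance = 0.01)
  expect_equal(unname(h[2]), 1.96, tolerance = 0.01)
})

test_that("hdi is the shortest interval (brute force agreement, skewed case)", {
  brute_hdi <- function(x, mass) {
    xs <- sort(x)
    n <- length(xs)
    k <- ceiling(mass * n)
    best <- Inf
    lo <- NA
    for (i in 1:(n - k + 1)) {
      w <- xs[i + k - 1] - xs[i]
      if (w < best) {
        best <- w
        lo <- i
      }
    }
    c(xs[lo], xs[lo + k - 1])
  }
  set.seed(2)
  for (i in 1:20) {
    x <- rexp(500)
    for (mass in c(0.75, 0.95)) {
      expect_equal(unname(hdi(x, mass)), brute_hdi(x, mass))
    }
  }
  # exponential draws: shortest interval hugs the mode at zero
  x <- rexp(1e5)
  h <- hdi(x, 0.95)
  expect_lt(unname(h[1]), 0.01)
})

test_that("hdi handles degenerate and invalid input", {
  expect_equal(unname(hdi(rep(3.5, 10), 0.95)), c(3.5, 3.5))
  expect_error(hdi(rnorm(10), 1.2), "in \\(0, 1\\)")
  expect_error(hdi(2, 0.5), "at least 2")
})

test_that("contrast flags follow the HDI evidence rule", {
  flag <- function(d) vpvdrl:::hdi_flag(d)$flag
  set.seed(3)
  # exchangeable draws around zero: no evidence
  expect_equal(flag(rnorm(4000)), "NONE")
  # all-negative difference draws: strong evidence
  expect_equal(flag(-abs(rnorm(4000)) - 0.1), "STRONG")
  # shifted so 0 is outside the 75% HDI (half-width ~1.15) but inside the
  # 95% HDI (half-width ~1.96)
  expect_equal(flag(rnorm(4000, mean = 1.5)), "MODERATE")
})

test_that("a fitted null cohort recovers truth and flags no effects", {
  # small cohort, no injected effect, model 1 for speed
  cfg <- cohort_config(n_per_group = 4, sessions_pre = 0, sessions_post = 2,
                       max_trials = 80, model = 1, effects = "null", seed = 31,
                       group_sds = c(alpha = 0.2, beta = 0.2))
  coh <- generate_cohort(cfg)
  fit <- fit_vpvd(coh$trials, model = 1, chains = 2, iter_warmup = 600,
                  iter_sample = 600, seed = 4)
  expect_true(fit$converged)
  td <- tidy(fit, scale = "transformed")
  truth <- true_group_means(cfg)
  j <- dplyr::left_join(td, truth, by = c("parameter", "group"))
  # group means near truth (generous bound; small data)
  expect_true(all(abs(j$estimate - j$mean_transformed) < 1))
  ct <- contrast_table(fit)
  expect_true(all(ct$flag %in% c("NONE", "MODERATE", "STRONG")))
  # degenerate contrast of a group with itself is exactly zero
  gd <- group_difference(fit, "beta", "low", "low")
  expect_equal(gd$estimate, 0)
  expect_equal(gd$flag, "NONE")
  expect_error(group_difference(fit, "rho", "low"), "not in model")
  expect_error(group_difference(fit, "beta", "placebo"), "unknown group")
  # hdi95 contains hdi75 on every contrast
  expect_true(all(ct$hdi95_lower <= ct$hdi75_lower))
  expect_true(all(ct$hdi95_upper >= ct$hdi75_upper))
})

test_that("posterior predictive simulation is seed-deterministic and sane", {
  cfg <- cohort_config(n_per_group = 3, sessions_pre = 0, sessions_post = 2,
                       max_trials = 80, model = 1, effects = "null", seed = 37)
  coh <- generate_cohort(cfg)
  fit <- suppressWarnings(
    fit_vpvd(coh$trials, model = 1, chains = 2, iter_warmup = 300,
             iter_sample = 300, seed = 6))
  p1 <- suppressWarnings(
    posterior_predictive_simulate(fit, n_per_group = 2, sessions_post = 2,
                                  max_trials = 80, seed = 9))
  p2 <- suppressWarnings(
    posterior_predictive_simulate(fit, n_per_group = 2, sessions_post = 2,
                                  max_trials = 80, seed = 9))
  expect_identical(p1$metrics$session, p2$metrics$session)
  # simulated accuracy rises across sessions (model captures learning)
  veh <- p1$metrics$session
  by_s <- tapply(veh$pct_correct_standard, veh$session, mean)
  expect_gt(by_s[2], by_s[1] - 5)
})

test_that("larger side stickiness produces more side repeats in simulation", {
  ss <- stimulus_set()
  sched <- dplyr::mutate(generate_schedule(200, seed = 4), session = 1)
  side_rep <- function(k) {
    log <- simulate_agent(sched, agent_params(alpha = 0.2, beta = 1,
                                              kappa_side = k),
                          model_spec(3), ss, seed = 5)
    mean(log$chosen_side[-1] == log$chosen_side[-nrow(log)])
  }
  expect_gt(side_rep(3), side_rep(0) + 0.1)
})
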