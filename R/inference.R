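#' Highest density interval of a sample
#'
#' The shortest interval containing the requested posterior mass, found by an
#' exhaustive scan over sorted draws.
#'
#' @param x Numeric vector of draws (at least 2 finite values).
#' @param mass Probability mass in (0, 1).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4), 0.95)
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    abort("`mass` must be a single number in (0, 1)")
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) abort("need at least 2 finite draws")
  xs <- sort(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  i <- which.min(xs[k:n] - xs[1:(n - k + 1)])
  c(lower = xs[i], upper = xs[i + k - 1])
}

hdi_flag <- function(draws) {
  h95 <- hdi(draws, 0.95)
  h75 <- hdi(draws, 0.75)
  flag <- if (h95[1] > 0 || h95[2] < 0) "STRONG"
  else if (h75[1] > 0 || h75[2] < 0) "MODERATE"
  else "NONE"
  list(flag = flag, hdi75 = h75, hdi95 = h95)
}

#' Posterior contrast between two dose groups
#'
#' Per posterior draw, the difference in group-level mean (treated minus
#' control) of one parameter, summarised by 75% and 95% HDIs and an evidence
#' flag: `STRONG` if 0 lies outside the 95% HDI, `MODERATE` if outside the
#' 75% HDI only, otherwise `NONE`.
#'
#' @param fit A [fit_vpvd()] object.
#' @param parameter A parameter of the fitted model.
#' @param group Treated group label.
#' @param control Control group label (default the first group of the fit).
#' @param scale `"natural"` (default; contrasts of back-transformed group
#'   means, as plotted in this literature) or `"transformed"`.
#' @return A one-row tibble (`parameter`, `group`, `control`, `estimate`,
#'   HDI bounds, `flag`) with the contrast draws in attribute `"draws"`.
#' @export
group_difference <- function(fit, parameter, group,
                             control = fit$groups[1],
                             scale = "natural") {
  d <- mu_draws(fit, parameter, group, scale) -
    mu_draws(fit, parameter, control, scale)
  f <- hdi_flag(d)
  out <- tibble(
    parameter = parameter, group = group, control = control,
    estimate = mean(d),
    hdi75_lower = f$hdi75[1], hdi75_upper = f$hdi75[2],
    hdi95_lower = f$hdi95[1], hdi95_upper = f$hdi95[2],
    flag = f$flag
  )
  attr(out, "draws") <- d
  out
}

#' Evidence table of all dose-group contrasts
#'
#' [group_difference()] for every model parameter and every non-control
#' group, with a qualitative direction column (`"up"`/`"down"` when the flag
#' is at least `MODERATE`, `"-"` otherwise).
#'
#' @inheritParams group_difference
#' @return A tibble, one row per parameter x treated group.
#' @export
contrast_table <- function(fit, control = fit$groups[1], scale = "natural") {
  treated <- setdiff(fit$groups, control)
  out <- purrr::map_dfr(fit$params, function(p) {
    purrr::map_dfr(treated, function(g) {
      group_difference(fit, p, g, control, scale)
    })
  })
  dplyr::mutate(out, direction = dplyr::case_when(
    flag == "NONE" ~ "-",
    estimate > 0 ~ "up",
    TRUE ~ "down"
  ))
}

#' Simulate behaviour from the fitted posterior group means
#'
#' Parameterises one agent per subject by its group's posterior mean
#' parameters (natural scale) from the winning model, simulates fresh
#' sessions of the task, and summarises the simulated log with the
#' conventional behavioural metrics, to check that the model reproduces the
#' behavioural observations.
#'
#' @param fit A converged [fit_vpvd()] object.
#' @param n_per_group Simulated subjects per group.
#' @param sessions_pre,sessions_post,max_trials Session design (defaults: no
#'   discrimination sessions, 6 reversal sessions of 200 trials).
#' @param stimulus_set The discrimination-phase [stimulus_set()].
#' @param seed Integer seed; the metric table is deterministic per seed.
#' @return A list with `trials` (simulated log) and `metrics`
#'   (see [vpvd_metrics()]).
#' @export
posterior_predictive_simulate <- function(fit, n_per_group = 12,
                                          sessions_pre = 0,
                                          sessions_post = 6,
                                          max_trials = 200,
                                          stimulus_set = vpvdrl::stimulus_set(),
                                          seed = 1) {
  if (!fit$converged) {
    warn("posterior predictive simulation from a non-converged fit")
  }
  set.seed(seed)
  n_sessions <- sessions_pre + sessions_post
  group_pars <- lapply(fit$groups, function(g) {
    vals <- vapply(fit$params, function(p) mean(mu_draws(fit, p, g, "natural")),
                   numeric(1))
    neutralise(do.call(agent_params, as.list(vals)), fit$spec)
  })
  names(group_pars) <- fit$groups
  trials <- purrr::map_dfr(fit$groups, function(g) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      scheds <- purrr::map_dfr(seq_len(n_sessions), function(s) {
        ph <- if (s <= sessions_pre) "discrimination" else "reversal"
        set_s <- if (ph == "reversal") apply_reversal(stimulus_set)
                 else stimulus_set
        dplyr::mutate(generate_schedule(max_trials, stimulus_set = set_s),
                      session = s, phase = ph)
      })
      simulate_agent(scheds, group_pars[[g]], fit$spec, stimulus_set,
                     subject_id = sprintf("ppc_%s_%02d", g, i),
                     group_label = g, q0 = fit$q0, rho_mode = fit$rho_mode)
    })
  })
  list(trials = trials,
       metrics = vpvd_metrics(trials, stimulus_set = stimulus_set))
}
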