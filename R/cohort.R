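# Default group-level means and SDs of the generating distribution,
# on the transformed (sampling) scale: logit for learning rates and rho,
# log for beta, identity for stickiness. Natural-scale means: alpha_rew 0.20,
# alpha_pun 0.15, beta 4, kappa_side = kappa_stim = 0.2, rho 0.95.
default_generating_means <- function() {
  c(alpha = qlogis(0.20), alpha_rew = qlogis(0.20), alpha_pun = qlogis(0.15),
    beta = log(4), kappa_side = 0.2, kappa_stim = 0.2, rho = qlogis(0.95))
}

default_generating_sds <- function() {
  c(alpha = 0.4, alpha_rew = 0.4, alpha_pun = 0.4,
    beta = 0.3, kappa_side = 0.2, kappa_stim = 0.2, rho = 0.3)
}

#' Qualitative dose-effect presets
#'
#' Named presets encode the direction of the reported dose effects as shifts
#' of the group-level means on the transformed scale: the 5-HT2A-antagonist
#' low dose lowers the punishment learning rate and reinforcement
#' sensitivity and raises both stickiness parameters; the high dose lowers
#' the punishment learning rate and raises side stickiness; the
#' 5-HT2C-antagonist doses lower side stickiness (plus reinforcement
#' sensitivity at the high dose). Shift magnitudes (0.8 on logit learning
#' rates, 0.4 on log beta and on stickiness) are the package's declared
#' moderate effect sizes.
#'
#' @param preset One of `"2a-low"`, `"2a-high"`, `"2c-low"`, `"2c-high"`,
#'   `"2a"`, `"2c"`, `"null"` (no effect).
#' @return A tibble with columns `parameter`, `group`, `shift`.
#' @export
effect_preset <- function(preset = c("null", "2a-low", "2a-high", "2a",
                                     "2c-low", "2c-high", "2c")) {
  preset <- match.arg(preset)
  low  <- function(par, d) tibble(parameter = par, group = "low", shift = d)
  high <- function(par, d) tibble(parameter = par, group = "high", shift = d)
  switch(preset,
    "null" = tibble(parameter = character(), group = character(),
                    shift = numeric()),
    "2a-low" = dplyr::bind_rows(low("alpha_pun", -0.8), low("beta", -0.4),
                                low("kappa_side", 0.4), low("kappa_stim", 0.4)),
    "2a-high" = dplyr::bind_rows(high("alpha_pun", -0.8),
                                 high("kappa_side", 0.4)),
    "2a" = dplyr::bind_rows(effect_preset("2a-low"), effect_preset("2a-high")),
    "2c-low" = low("kappa_side", -0.4),
    "2c-high" = dplyr::bind_rows(high("beta", -0.4), high("kappa_side", -0.4)),
    "2c" = dplyr::bind_rows(effect_preset("2c-low"), effect_preset("2c-high"))
  )
}

#' Configuration of a synthetic VPVD cohort
#'
#' Describes the study design: three dose groups of `n_per_group` subjects,
#' `sessions_pre` discrimination sessions followed by a between-session
#' reversal and `sessions_post` reversal sessions of up to `max_trials`
#' trials, with behaviour generated from the given model with group-shifted
#' parameters.
#'
#' @param n_per_group Subjects per group (default 12; three groups of 12
#'   mirror a 36-rat, three-dose design).
#' @param groups Group labels; first label is the control group.
#' @param sessions_pre,sessions_post Sessions before/after the reversal.
#' @param max_trials Trials per session (default 200).
#' @param model Generating [model_spec()] or id (default 9).
#' @param group_means Named vector of transformed-scale means for the active
#'   parameters (defaults above).
#' @param group_sds Named vector of transformed-scale between-subject SDs.
#' @param effects An [effect_preset()] name or tibble of mean shifts.
#' @param seed Integer seed for the whole cohort.
#' @param stimulus_set The discrimination-phase [stimulus_set()].
#' @param q0,rho_mode Value initialisation and forgetting variant.
#' @return A list of class `vpvd_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 12,
                          groups = c("vehicle", "low", "high"),
                          sessions_pre = 2, sessions_post = 14,
                          max_trials = 200, model = 9,
                          group_means = NULL, group_sds = NULL,
                          effects = "null", seed = 1,
                          stimulus_set = vpvdrl::stimulus_set(),
                          q0 = 0.5, rho_mode = "initial") {
  spec <- as_model_spec(model)
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  means <- default_generating_means()[spec$params]
  sds <- default_generating_sds()[spec$params]
  if (!is.null(group_means)) means[names(group_means)] <- group_means
  if (!is.null(group_sds)) sds[names(group_sds)] <- group_sds
  if (any(sds <= 0)) abort("group SDs must be positive")
  if (is.character(effects)) effects <- effect_preset(effects)
  if (!all(effects$parameter %in% spec$params)) {
    abort("effect preset refers to a parameter absent from the generating model")
  }
  if (!all(effects$group %in% groups)) {
    abort("effect preset refers to an unknown group")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         sessions_pre = as.integer(sessions_pre),
         sessions_post = as.integer(sessions_post),
         max_trials = as.integer(max_trials), spec = spec,
         group_means = means, group_sds = sds, effects = effects,
         seed = as.integer(seed), stimulus_set = stimulus_set,
         q0 = q0, rho_mode = rho_mode),
    class = "vpvd_cohort_config"
  )
}

# transformed-scale mean vector for one group (base means + injected shifts)
group_mean_vector <- function(config, group) {
  m <- config$group_means
  eff <- config$effects[config$effects$group == group, ]
  if (nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      m[eff$parameter[i]] <- m[eff$parameter[i]] + eff$shift[i]
    }
  }
  m
}

#' True group-level means of a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return Tibble with `group`, `parameter`, `mean_transformed`,
#'   `mean_natural`.
#' @export
true_group_means <- function(config) {
  purrr::map_dfr(config$groups, function(g) {
    m <- group_mean_vector(config, g)
    tibble(group = g, parameter = names(m), mean_transformed = unname(m),
           mean_natural = purrr::map2_dbl(names(m), m, to_natural))
  })
}

#' Draw one subject's parameters from the group-level distribution
#'
#' Parameters are drawn from normal distributions on the transformed scale
#' (logit for learning rates and `rho`, log for `beta`, identity for
#' stickiness) and mapped back to their natural bounds, matching the
#' hierarchical structure assumed by the fitting model.
#'
#' @param config A [cohort_config()].
#' @param group Group label.
#' @return A list with `natural` ([agent_params()]) and `transformed`
#'   (named vector of active parameters).
#' @export
sample_subject_params <- function(config, group) {
  m <- group_mean_vector(config, group)
  z <- rnorm(length(m), m, config$group_sds[names(m)])
  names(z) <- names(m)
  nat <- purrr::map2_dbl(names(z), z, to_natural)
  names(nat) <- names(z)
  full <- neutralise(do.call(agent_params, as.list(
    if ("alpha" %in% names(nat)) {
      c(list(alpha = nat[["alpha"]]),
        as.list(nat[setdiff(names(nat), "alpha")]))
    } else {
      as.list(nat)
    })), config$spec)
  list(natural = full, transformed = z)
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each subject: session schedules from [generate_schedule()]
#' (discrimination phase, then a between-session reversal, then reversal
#' sessions), behaviour from [simulate_agent()], and the generating
#' parameters recorded as ground truth. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `vpvd_cohort` with `trials` (trial-log tibble) and
#'   `truth` (long tibble: `subject_id`, `group_label`, `parameter`,
#'   `value_natural`, `value_transformed`), plus the `config`.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, sessions_pre = 0, sessions_post = 1,
#'                      max_trials = 40, seed = 42)
#' coh <- generate_cohort(cfg)
#' dplyr::count(coh$trials, group_label)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "vpvd_cohort_config"))
  set.seed(config$seed)
  n_sessions <- config$sessions_pre + config$sessions_post
  trials <- vector("list", length(config$groups) * config$n_per_group)
  truth <- vector("list", length(trials))
  k <- 0
  for (g in config$groups) {
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", g, i)
      pars <- sample_subject_params(config, g)
      scheds <- purrr::map_dfr(seq_len(n_sessions), function(s) {
        ph <- if (s <= config$sessions_pre) "discrimination" else "reversal"
        # probe labels follow the current contingency, so reversal-phase
        # schedules are generated under the reversed set
        set_s <- if (ph == "reversal") apply_reversal(config$stimulus_set)
                 else config$stimulus_set
        dplyr::mutate(generate_schedule(config$max_trials, stimulus_set = set_s),
                      session = s, phase = ph)
      })
      trials[[k]] <- simulate_agent(
        scheds, pars$natural, config$spec, config$stimulus_set,
        subject_id = sid, group_label = g, q0 = config$q0,
        rho_mode = config$rho_mode
      )
      truth[[k]] <- tibble(
        subject_id = sid, group_label = g,
        parameter = names(pars$transformed),
        value_transformed = unname(pars$transformed),
        value_natural = purrr::map2_dbl(names(pars$transformed),
                                        pars$transformed, to_natural)
      )
    }
  }
  structure(
    list(trials = dplyr::bind_rows(trials), truth = dplyr::bind_rows(truth),
         config = config),
    class = "vpvd_cohort"
  )
}

#' @export
print.vpvd_cohort <- function(x, ...) {
  cat(sprintf(
    "<vpvd_cohort> %d subjects in %d groups, %d trials (model %d, seed %d)\n",
    length(unique(x$trials$subject_id)), length(x$config$groups),
    nrow(x$trials), x$config$spec$model_id, x$config$seed))
  invisible(x)
}
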