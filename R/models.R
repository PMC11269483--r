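#' The nine-member Q-learning model family
#'
#' Each model is a combination of: shared vs split (reward/punishment)
#' learning rates, stimulus stickiness `kappa_stim`, side stickiness
#' `kappa_side`, and the value-forgetting factor `rho`. Reinforcement
#' sensitivity `beta` is always present.
#'
#' @param model_id Integer 1..9.
#' @return A `vpvd_model_spec`: list with `model_id`, `split_alpha`,
#'   `use_kappa_stim`, `use_kappa_side`, `use_rho`, the active parameter
#'   names `params`, and a display `label`.
#' @examples
#' model_spec(9)
#' list_models()
#' @export
model_spec <- function(model_id) {
  if (length(model_id) != 1 || !model_id %in% 1:9) {
    abort("`model_id` must be a single integer in 1..9")
  }
  flags <- list(
    list(split = FALSE, kstim = FALSE, kside = FALSE, rho = FALSE),
    list(split = FALSE, kstim = TRUE,  kside = FALSE, rho = FALSE),
    list(split = FALSE, kstim = FALSE, kside = TRUE,  rho = FALSE),
    list(split = FALSE, kstim = TRUE,  kside = TRUE,  rho = FALSE),
    list(split = TRUE,  kstim = FALSE, kside = FALSE, rho = FALSE),
    list(split = TRUE,  kstim = TRUE,  kside = FALSE, rho = FALSE),
    list(split = TRUE,  kstim = FALSE, kside = TRUE,  rho = FALSE),
    list(split = TRUE,  kstim = TRUE,  kside = TRUE,  rho = FALSE),
    list(split = TRUE,  kstim = TRUE,  kside = TRUE,  rho = TRUE)
  )[[model_id]]
  params <- c(
    if (flags$split) c("alpha_rew", "alpha_pun") else "alpha",
    "beta",
    if (flags$kside) "kappa_side",
    if (flags$kstim) "kappa_stim",
    if (flags$rho) "rho"
  )
  structure(
    list(model_id = as.integer(model_id), split_alpha = flags$split,
         use_kappa_stim = flags$kstim, use_kappa_side = flags$kside,
         use_rho = flags$rho, params = params,
         label = paste(params, collapse = ", ")),
    class = "vpvd_model_spec"
  )
}

#' @export
print.vpvd_model_spec <- function(x, ...) {
  cat(sprintf("<vpvd_model_spec> model %d: %s\n", x$model_id, x$label))
  invisible(x)
}

#' @rdname model_spec
#' @export
list_models <- function() {
  specs <- lapply(1:9, model_spec)
  tibble(
    model_id = 1:9,
    parameters = vapply(specs, `[[`, character(1), "label"),
    n_params = vapply(specs, function(s) length(s$params), integer(1))
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "vpvd_model_spec")) return(model)
  model_spec(model)
}

#' Agent parameters on the natural scale
#'
#' Bundles the full six-parameter vector of the richest model. For smaller
#' models the excluded parameters take their neutral values (shared alpha,
#' `kappa = 0`, `rho = 1`), under which the richer model reproduces the
#' smaller one exactly.
#'
#' @param alpha_rew,alpha_pun Learning rates in \[0,1\] for rewarded and
#'   punished outcomes. Supply `alpha` instead for shared-rate models.
#' @param beta Reinforcement sensitivity (softmax inverse temperature), >= 0.
#' @param kappa_side,kappa_stim Side and stimulus stickiness (any real).
#' @param rho Forgetting factor in \[0,1\]; 1 = no forgetting.
#' @param alpha Optional shared learning rate (sets both `alpha_rew` and
#'   `alpha_pun`).
#' @return A named list of class `vpvd_agent_params`.
#' @export
agent_params <- function(alpha_rew = 0.2, alpha_pun = 0.2, beta = 4,
                         kappa_side = 0, kappa_stim = 0, rho = 1,
                         alpha = NULL) {
  if (!is.null(alpha)) alpha_rew <- alpha_pun <- alpha
  p <- list(alpha_rew = alpha_rew, alpha_pun = alpha_pun, beta = beta,
            kappa_side = kappa_side, kappa_stim = kappa_stim, rho = rho)
  if (p$alpha_rew < 0 || p$alpha_rew > 1 || p$alpha_pun < 0 || p$alpha_pun > 1) {
    abort("learning rates must lie in [0, 1]")
  }
  if (p$beta < 0) abort("`beta` must be non-negative")
  if (p$rho < 0 || p$rho > 1) abort("`rho` must lie in [0, 1]")
  structure(p, class = "vpvd_agent_params")
}

as_agent_params <- function(p) {
  if (inherits(p, "vpvd_agent_params")) return(p)
  do.call(agent_params, as.list(p))
}

# six-element natural-scale vector in kernel order
params_vector <- function(p) {
  p <- as_agent_params(p)
  c(p$alpha_rew, p$alpha_pun, p$beta, p$kappa_side, p$kappa_stim, p$rho)
}

# ---- transformed (sampling) scale <-> natural scale -------------------------

par_scale <- function(name) {
  base <- sub("_(rew|pun|side|stim)$", "", name)
  switch(base,
         alpha = "logit", rho = "logit", beta = "log", kappa = "identity",
         abort(sprintf("unknown parameter '%s'", name)))
}

to_natural <- function(name, x) {
  switch(par_scale(name), logit = plogis(x), log = exp(x), identity = x)
}

to_transformed <- function(name, x) {
  switch(par_scale(name), logit = qlogis(x), log = log(x), identity = x)
}

# precompiled fast version of expand_natural for hot loops: resolves the
# column mapping once instead of per call
make_expander <- function(spec) {
  spec <- as_model_spec(spec)
  i_ar <- match("alpha_rew", spec$params)
  i_ap <- match("alpha_pun", spec$params)
  i_a <- match("alpha", spec$params)
  i_b <- match("beta", spec$params)
  i_ks <- match("kappa_side", spec$params)
  i_kt <- match("kappa_stim", spec$params)
  i_r <- match("rho", spec$params)
  split <- spec$split_alpha
  function(theta) {
    if (split) {
      a_rew <- plogis(theta[, i_ar])
      a_pun <- plogis(theta[, i_ap])
    } else {
      a_rew <- a_pun <- plogis(theta[, i_a])
    }
    cbind(a_rew, a_pun, exp(theta[, i_b]),
          if (is.na(i_ks)) 0 else theta[, i_ks],
          if (is.na(i_kt)) 0 else theta[, i_kt],
          if (is.na(i_r)) 1 else plogis(theta[, i_r]))
  }
}

# expand an S x P matrix of active transformed parameters into the
# S x 6 natural-scale matrix the C++ kernel expects
expand_natural <- function(theta_t, spec) {
  spec <- as_model_spec(spec)
  S <- nrow(theta_t)
  get <- function(name, neutral) {
    if (name %in% colnames(theta_t)) to_natural(name, theta_t[, name])
    else rep(neutral, S)
  }
  if (spec$split_alpha) {
    a_rew <- get("alpha_rew", NA_real_)
    a_pun <- get("alpha_pun", NA_real_)
  } else {
    a_rew <- a_pun <- to_natural("alpha", theta_t[, "alpha"])
  }
  cbind(a_rew, a_pun,
        beta = to_natural("beta", theta_t[, "beta"]),
        kappa_side = get("kappa_side", 0),
        kappa_stim = get("kappa_stim", 0),
        rho = get("rho", 1))
}

# ---- pure-R reference implementation (oracle path) --------------------------

#' Initialise a Q-value state
#'
#' @param stimulus_set A [stimulus_set()].
#' @param q0 Initial Q-value for all three stimuli (default 0.5, the midpoint
#'   of the 0/1 reinforcement scale).
#' @return A list with `q` (named values), `last_stim`, `last_side`.
#' @export
q_state <- function(stimulus_set = vpvdrl::stimulus_set(), q0 = 0.5) {
  check_stimulus_set(stimulus_set)
  list(q = setNames(rep(q0, 3), c(stimulus_set$a, stimulus_set$b, stimulus_set$c)),
       last_stim = NA_character_, last_side = NA_character_, q0 = q0)
}

#' Update Q-values after one trial
#'
#' Delta-rule update of the chosen stimulus,
#' `Q <- Q + alpha * (r - Q)`, with `alpha = alpha_rew` after reward and
#' `alpha_pun` after non-reward. Under models with forgetting, every
#' non-chosen stimulus decays: `Q <- rho * Q + (1 - rho) * Q0`
#' (`rho_mode = "initial"`, the default, decay toward the initial value) or
#' `Q <- rho * Q` (`rho_mode = "decay"`).
#'
#' @param state A [q_state()].
#' @param chosen_stim The chosen stimulus identifier.
#' @param reinforced 0 or 1.
#' @param params [agent_params()].
#' @param spec A [model_spec()] (or id); controls which terms are active.
#' @param rho_mode `"initial"` or `"decay"`.
#' @return The updated state.
#' @export
update_values <- function(state, chosen_stim, reinforced, params,
                          spec = model_spec(9), rho_mode = "initial") {
  spec <- as_model_spec(spec)
  params <- as_agent_params(params)
  if (!reinforced %in% c(0, 1)) abort("`reinforced` must be 0 or 1")
  if (!chosen_stim %in% names(state$q)) {
    abort(sprintf("'%s' is not in the Q-state", chosen_stim))
  }
  alpha <- if (spec$split_alpha) {
    if (reinforced == 1) params$alpha_rew else params$alpha_pun
  } else {
    params$alpha_rew # shared: alpha_rew == alpha_pun
  }
  state$q[chosen_stim] <- state$q[chosen_stim] +
    alpha * (reinforced - state$q[chosen_stim])
  if (spec$use_rho && params$rho < 1) {
    others <- setdiff(names(state$q), chosen_stim)
    state$q[others] <- if (rho_mode == "initial") {
      params$rho * state$q[others] + (1 - params$rho) * state$q0
    } else {
      params$rho * state$q[others]
    }
  }
  state$last_stim <- chosen_stim
  state$last_side <- NA_character_ # caller sets side
  state
}

#' Probability of choosing the left option
#'
#' Softmax over the two presented options with additive logits:
#' `beta * Q + kappa_stim * I(stimulus repeated) + kappa_side * I(side
#' repeated)`. On the first trial of a session both indicators are zero.
#'
#' @inheritParams update_values
#' @param trial One schedule row with `left_stim` and `right_stim`.
#' @return P(choose left); P(left) + P(right) = 1.
#' @export
choice_probability <- function(state, trial, params, spec = model_spec(9)) {
  spec <- as_model_spec(spec)
  params <- as_agent_params(params)
  stopifnot(all(c(trial$left_stim, trial$right_stim) %in% names(state$q)))
  kst <- if (spec$use_kappa_stim) params$kappa_stim else 0
  ksd <- if (spec$use_kappa_side) params$kappa_side else 0
  xl <- params$beta * state$q[[trial$left_stim]]
  xr <- params$beta * state$q[[trial$right_stim]]
  if (!is.na(state$last_stim)) {
    if (trial$left_stim == state$last_stim) xl <- xl + kst
    if (trial$right_stim == state$last_stim) xr <- xr + kst
  }
  if (!is.na(state$last_side)) {
    if (state$last_side == "L") xl <- xl + ksd else xr <- xr + ksd
  }
  m <- max(xl, xr)
  exp(xl - m) / (exp(xl - m) + exp(xr - m))
}

#' Log-likelihood of one subject's choices
#'
#' Accumulates `log P(observed choice)` trial by trial, evolving Q-values
#' through [update_values()]. Q-values carry across sessions; the stickiness
#' indicators reset at each session boundary. The observed reinforcement
#' column is taken as ground truth, so the model never needs to know the
#' reversal status.
#'
#' @param records A trial-log tibble for one subject (columns `session`,
#'   `trial_index`, `left_stim`, `right_stim`, `chosen_stim`, `chosen_side`,
#'   `reinforced`), sorted by session then trial index.
#' @param params [agent_params()].
#' @param spec A [model_spec()] or model id.
#' @param state Optional starting [q_state()] for cross-session carrying;
#'   fresh if `NULL`.
#' @param q0 Initial Q-value.
#' @param rho_mode Forgetting variant, see [update_values()].
#' @param engine `"cpp"` (fast kernel) or `"r"` (naive per-trial reference).
#'   Both produce identical results; the R path exists as the transparent
#'   reference implementation.
#' @return A list with `loglik` (nats) and the final `state`.
#' @export
session_log_likelihood <- function(records, params, spec = model_spec(9),
                                   state = NULL, q0 = 0.5,
                                   rho_mode = "initial",
                                   engine = c("r", "cpp")) {
  engine <- match.arg(engine)
  spec <- as_model_spec(spec)
  params <- as_agent_params(params)
  validate_records(records)
  stims <- sort(unique(c(records$left_stim, records$right_stim)))
  if (is.null(state)) {
    state <- list(q = setNames(rep(q0, length(stims)), stims),
                  last_stim = NA_character_, last_side = NA_character_,
                  q0 = q0)
  }
  if (engine == "cpp") {
    enc <- encode_trials(records, levels = names(state$q))
    theta <- matrix(rep(params_vector(neutralise(params, spec)), 1),
                    nrow = 1, byrow = TRUE)
    ll <- cpp_loglik(enc$subj_start, enc$session, enc$left, enc$right,
                     enc$chosen, enc$side, enc$reinforced, theta,
                     q0, rho_mode_code(rho_mode))
    # final state is not returned by the batch kernel; recompute lazily
    return(list(loglik = as.numeric(ll), state = NULL))
  }
  ll <- 0
  cur_session <- NA_integer_
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    if (!identical(cur_session, row$session)) {
      cur_session <- row$session
      state$last_stim <- NA_character_
      state$last_side <- NA_character_
    }
    pl <- choice_probability(state, row, params, spec)
    p <- if (row$chosen_side == "L") pl else 1 - pl
    ll <- ll + log(max(p, 1e-300))
    last_side <- row$chosen_side
    state <- update_values(state, row$chosen_stim, row$reinforced, params,
                           spec, rho_mode)
    state$last_side <- last_side
  }
  list(loglik = ll, state = state)
}

# impose neutral values for parameters the model excludes
neutralise <- function(params, spec) {
  spec <- as_model_spec(spec)
  p <- as_agent_params(params)
  if (!spec$split_alpha) p$alpha_pun <- p$alpha_rew
  if (!spec$use_kappa_side) p$kappa_side <- 0
  if (!spec$use_kappa_stim) p$kappa_stim <- 0
  if (!spec$use_rho) p$rho <- 1
  p
}

rho_mode_code <- function(rho_mode) {
  match(match.arg(rho_mode, c("initial", "decay")), c("initial", "decay")) - 1L
}

validate_records <- function(records) {
  need <- c("session", "trial_index", "left_stim", "right_stim",
            "chosen_stim", "chosen_side", "reinforced")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("trial records lack column(s): ", paste(miss, collapse = ", ")))
  }
  ord <- order(records$session, records$trial_index)
  if (!identical(ord, seq_len(nrow(records)))) {
    abort("trial records must be sorted by session then trial_index")
  }
  bad <- which(!(records$chosen_stim == records$left_stim &
                   records$chosen_side == "L") &
                 !(records$chosen_stim == records$right_stim &
                     records$chosen_side == "R"))
  if (length(bad)) {
    abort(sprintf("inconsistent choice/side at row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!all(records$reinforced %in% c(0, 1))) {
    abort("`reinforced` must be 0 or 1")
  }
  invisible(records)
}

#' Simulate an agent on a set of session schedules
#'
#' Choices are sampled from [choice_probability()], outcomes from the task's
#' reinforcement rule (A always, B never, C on 50% of choices, honouring the
#' reversal state of each phase), and values are updated each trial. Q-values
#' carry across sessions; stickiness indicators reset each session.
#'
#' @param schedules A tibble of schedules with columns `session`,
#'   `trial_index`, `trial_type`, `left_stim`, `right_stim`, and optionally
#'   `phase` (`"discrimination"` rows use `stimulus_set` as given,
#'   `"reversal"` rows use the reversed contingency).
#' @param params [agent_params()].
#' @param spec [model_spec()] or id.
#' @param stimulus_set The discrimination-phase [stimulus_set()].
#' @param seed Optional integer seed (deterministic log for a fixed seed).
#' @param subject_id,group_label Identifiers copied into the output.
#' @param q0,rho_mode See [update_values()].
#' @return A trial-log tibble (one row per trial) with the schedule columns
#'   plus `subject_id`, `group_label`, `chosen_stim`, `chosen_side`,
#'   `reinforced`.
#' @export
simulate_agent <- function(schedules, params, spec = model_spec(9),
                           stimulus_set = vpvdrl::stimulus_set(),
                           seed = NULL, subject_id = "s01",
                           group_label = "vehicle", q0 = 0.5,
                           rho_mode = "initial") {
  check_stimulus_set(stimulus_set)
  spec <- as_model_spec(spec)
  params <- neutralise(params, spec)
  if (!is.null(seed)) set.seed(seed)
  schedules <- dplyr::arrange(schedules, .data$session, .data$trial_index)
  if (!"phase" %in% names(schedules)) schedules$phase <- "reversal"
  levels <- c(stimulus_set$a, stimulus_set$b, stimulus_set$c)
  qv <- rep(q0, 3)
  out <- vector("list", 2)
  k <- 0
  for (ph in unique(schedules$phase)) {
    blk <- schedules[schedules$phase == ph, ]
    set_ph <- if (ph == "reversal" && !stimulus_set$reversed) {
      apply_reversal(stimulus_set)
    } else {
      stimulus_set
    }
    rp <- reward_probs(set_ph)[levels]
    sim <- cpp_simulate(as.integer(blk$session),
                        match(blk$left_stim, levels),
                        match(blk$right_stim, levels),
                        params_vector(params), as.numeric(rp),
                        qv, q0, rho_mode_code(rho_mode))
    qv <- sim$q_final
    k <- k + 1
    out[[k]] <- dplyr::mutate(
      blk,
      chosen_stim = levels[sim$chosen],
      chosen_side = c("L", "R")[sim$side],
      reinforced = as.integer(sim$reinforced)
    )
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  dplyr::select(
    dplyr::mutate(res, subject_id = subject_id, group_label = group_label),
    "subject_id", "group_label", "phase", "session", "trial_index",
    "trial_type", "left_stim", "right_stim", "chosen_stim", "chosen_side",
    "reinforced"
  )
}

# ---- internal encoding for the C++ kernel -----------------------------------

# trials must already be sorted by subject, session, trial_index
encode_trials <- function(trials, levels, subjects = NULL) {
  if (is.null(subjects)) {
    subjects <- if ("subject_id" %in% names(trials)) {
      unique(trials$subject_id)
    } else "s01"
  }
  sid <- if ("subject_id" %in% names(trials)) {
    match(trials$subject_id, subjects)
  } else {
    rep(1L, nrow(trials))
  }
  n_per <- tabulate(sid, nbins = length(subjects))
  list(
    subj_start = c(0L, cumsum(n_per)),
    session = as.integer(trials$session),
    left = match(trials$left_stim, levels),
    right = match(trials$right_stim, levels),
    chosen = match(trials$chosen_stim, levels),
    side = match(trials$chosen_side, c("L", "R")),
    reinforced = as.integer(trials$reinforced),
    subjects = subjects,
    levels = levels
  )
}
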