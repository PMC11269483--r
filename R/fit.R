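#' Priors for the hierarchical model
#'
#' Weakly informative defaults on the transformed scales: group-level means
#' Normal(`mu_mean`, `mu_sd`) and between-subject SDs half-Normal(0,
#' `sigma_scale`), applied to logit learning rates and forgetting, log
#' reinforcement sensitivity, and raw stickiness.
#'
#' @param mu_mean,mu_sd Normal prior on group-level means (default 0, 1).
#' @param sigma_scale Scale of the half-normal prior on group SDs (default 1).
#' @return A list of class `vpvd_priors`.
#' @export
vpvd_priors <- function(mu_mean = 0, mu_sd = 1, sigma_scale = 1) {
  if (mu_sd <= 0 || sigma_scale <= 0) abort("prior scales must be positive")
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_scale = sigma_scale), class = "vpvd_priors")
}

#' Fit a hierarchical Bayesian RL model to a cohort trial log
#'
#' One joint fit covering all dose groups: each subject's transformed
#' parameters are normal around their group's mean (group-indexed means,
#' shared between-subject SDs), and the trial-level likelihood is the model's
#' sequential choice probability (identical to [session_log_likelihood()]).
#' Sampling is adaptive Metropolis-within-Gibbs: per-parameter random-walk
#' updates of subject parameters (likelihood in compiled code), conjugate
#' Gibbs draws for group means, and a log-scale random-walk for the SDs.
#' Proposal scales adapt during warmup only.
#'
#' Convergence is summarised by split-Rhat and effective sample size on the
#' group-level parameters; a warning is raised if any split-Rhat exceeds
#' `rhat_threshold`.
#'
#' @param trials A trial-log tibble (see [read_trial_log()] for the columns).
#' @param model A [model_spec()] or model id 1..9.
#' @param priors A [vpvd_priors()].
#' @param chains,iter_warmup,iter_sample MCMC settings (defaults 4 chains of
#'   1000 + 1000).
#' @param seed Integer seed; fits are reproducible for fixed settings.
#' @param q0 Initial Q-value (default 0.5).
#' @param rho_mode Forgetting variant, see [update_values()].
#' @param adapt_every Warmup sweeps between proposal-scale adaptations.
#' @param rhat_threshold Split-Rhat above which a convergence warning is
#'   raised (default 1.05).
#' @return An object of class `vpvd_fit`; see [tidy.vpvd_fit()],
#'   [glance.vpvd_fit()], [group_difference()], [log_marginal_likelihood()].
#' @export
fit_vpvd <- function(trials, model = 9, priors = vpvd_priors(), chains = 4,
                     iter_warmup = 1000, iter_sample = 1000, seed = 1,
                     q0 = 0.5, rho_mode = "initial", adapt_every = 25,
                     rhat_threshold = 1.05) {
  spec <- as_model_spec(model)
  stopifnot(inherits(priors, "vpvd_priors"))
  t0 <- Sys.time()

  grp_levels <- unique(trials$group_label)
  trials <- dplyr::arrange(trials, .data$subject_id, .data$session,
                           .data$trial_index)
  check_trial_log(trials)
  subjects <- unique(trials$subject_id)
  subj_group <- trials$group_label[match(subjects, trials$subject_id)]
  gidx <- match(subj_group, grp_levels)
  levels <- sort(unique(c(trials$left_stim, trials$right_stim)))
  enc <- encode_trials(trials, levels, subjects)

  novar <- vapply(seq_along(subjects), function(s) {
    rows <- (enc$subj_start[s] + 1):enc$subj_start[s + 1]
    length(unique(enc$chosen[rows])) == 1L
  }, logical(1))
  if (any(novar)) {
    warn(sprintf("subject(s) with no variation in choice: %s (fitted anyway)",
                 paste(subjects[novar], collapse = ", ")))
  }

  P <- length(spec$params)
  S <- length(subjects)
  G <- length(grp_levels)
  rc <- rho_mode_code(rho_mode)

  expander <- make_expander(spec)
  ll_fun <- function(theta) {
    cpp_loglik(enc$subj_start, enc$session, enc$left, enc$right, enc$chosen,
               enc$side, enc$reinforced, expander(theta), q0, rc)
  }

  run_chain <- function(chain_id) {
    set.seed(seed + 7919L * chain_id)
    mu <- matrix(rnorm(P * G, 0, 0.1), P, G)
    sigma <- rep(0.5, P)
    theta <- matrix(0, S, P, dimnames = list(subjects, spec$params))
    for (p in seq_len(P)) theta[, p] <- mu[p, gidx] + rnorm(S, 0, 0.1)
    ll_cur <- ll_fun(theta)
    # per-subject block proposals: scaled empirical-covariance random walk
    # (Haario-style), adapted during warmup only
    Rs <- replicate(S, diag(0.15, P), simplify = FALSE)
    bscale <- rep(1, S)
    acc_n <- rep(0, S)
    sig_prop <- rep(0.5, P)
    sig_acc <- rep(0, P)
    nc_mu_scale <- matrix(0.2, P, G)
    nc_sig_scale <- rep(0.5, P)
    nc_mu_acc <- matrix(0, P, G)
    nc_sig_acc <- rep(0, P)
    hist_keep <- min(iter_warmup, 600L)
    hist_arr <- array(NA_real_, c(hist_keep, S, P))
    hist_n <- 0L

    n_iter <- iter_warmup + iter_sample
    mu_s <- array(NA_real_, c(iter_sample, P, G))
    sigma_s <- matrix(NA_real_, iter_sample, P)
    theta_s <- array(NA_real_, c(iter_sample, S, P))
    ll_s <- numeric(iter_sample)

    MU <- function() t(mu[, gidx, drop = FALSE])
    SDm <- matrix(sigma, S, P, byrow = TRUE)

    for (it in seq_len(n_iter)) {
      # subject-level parameters: joint block proposal per subject
      z <- matrix(rnorm(S * P), S, P)
      step <- t(vapply(seq_len(S),
                       function(s) drop(z[s, , drop = FALSE] %*% Rs[[s]]) * bscale[s],
                       numeric(P)))
      if (P == 1) step <- matrix(step, S, 1)
      prop <- theta + step
      ll_prop <- ll_fun(prop)
      SDm <- matrix(sigma, S, P, byrow = TRUE)
      pr_cur <- rowSums(dnorm(theta, MU(), SDm, log = TRUE))
      pr_prop <- rowSums(dnorm(prop, MU(), SDm, log = TRUE))
      acc <- log(runif(S)) < (ll_prop + pr_prop) - (ll_cur + pr_cur)
      if (any(acc)) {
        theta[acc, ] <- prop[acc, ]
        ll_cur[acc] <- ll_prop[acc]
        acc_n[acc] <- acc_n[acc] + 1
      }
      if (it <= iter_warmup) {
        j <- (it - 1L) %% hist_keep + 1L
        hist_arr[j, , ] <- theta
        hist_n <- min(hist_n + 1L, hist_keep)
      }
      # group means: conjugate normal draw
      for (p in seq_len(P)) {
        for (g in seq_len(G)) {
          sg <- gidx == g
          prec <- 1 / priors$mu_sd^2 + sum(sg) / sigma[p]^2
          m <- (priors$mu_mean / priors$mu_sd^2 +
                  sum(theta[sg, p]) / sigma[p]^2) / prec
          mu[p, g] <- rnorm(1, m, sqrt(1 / prec))
        }
      }
      # group SDs: random walk on log(sigma), half-normal prior + Jacobian;
      # likelihood-free conditional, so several cheap repeats per sweep
      for (rep_sig in 1:5) {
        for (p in seq_len(P)) {
          cur <- sigma[p]
          cand <- exp(log(cur) + rnorm(1) * sig_prop[p])
          lt <- function(s) {
            dnorm(s, 0, priors$sigma_scale, log = TRUE) + log(s) +
              sum(dnorm(theta[, p], mu[p, gidx], s, log = TRUE))
          }
          if (log(runif(1)) < lt(cand) - lt(cur)) {
            sigma[p] <- cand
            sig_acc[p] <- sig_acc[p] + 0.2
          }
        }
      }
      # interweaved non-centered moves: translate each group mean (its
      # subjects riding along) and rescale each SD, breaking the
      # mean/SD-vs-subject funnel of the centered parameterisation
      for (p in seq_len(P)) {
        z <- (theta[, p] - mu[p, gidx]) / sigma[p]
        mu_prop <- mu[p, ] + rnorm(G) * nc_mu_scale[p, ]
        prop <- theta
        prop[, p] <- mu_prop[gidx] + sigma[p] * z
        ll_prop <- ll_fun(prop)
        for (g in seq_len(G)) {
          sg <- gidx == g
          la <- dnorm(mu_prop[g], priors$mu_mean, priors$mu_sd, log = TRUE) -
            dnorm(mu[p, g], priors$mu_mean, priors$mu_sd, log = TRUE) +
            sum(ll_prop[sg]) - sum(ll_cur[sg])
          if (log(runif(1)) < la) {
            mu[p, g] <- mu_prop[g]
            theta[sg, p] <- prop[sg, p]
            ll_cur[sg] <- ll_prop[sg]
            nc_mu_acc[p, g] <- nc_mu_acc[p, g] + 1
          }
        }
        for (rep_nc in 1:2) {
          z <- (theta[, p] - mu[p, gidx]) / sigma[p]
          cand <- exp(log(sigma[p]) + rnorm(1) * nc_sig_scale[p])
          prop <- theta
          prop[, p] <- mu[p, gidx] + cand * z
          ll_prop <- ll_fun(prop)
          la <- dnorm(cand, 0, priors$sigma_scale, log = TRUE) + log(cand) -
            dnorm(sigma[p], 0, priors$sigma_scale, log = TRUE) - log(sigma[p]) +
            sum(ll_prop) - sum(ll_cur)
          if (log(runif(1)) < la) {
            sigma[p] <- cand
            theta[, p] <- prop[, p]
            ll_cur <- ll_prop
            nc_sig_acc[p] <- nc_sig_acc[p] + 0.5
          }
        }
      }
      # warmup-only adaptation
      if (it <= iter_warmup && it %% adapt_every == 0) {
        rate <- acc_n / adapt_every
        bscale <- pmin(pmax(bscale * exp(rate - 0.25), 1e-3), 10)
        acc_n[] <- 0
        if (hist_n >= max(100L, 10L * P) && it %% (4L * adapt_every) == 0) {
          for (s in seq_len(S)) {
            cv <- stats::cov(hist_arr[seq_len(hist_n), s, , drop = TRUE])
            if (P == 1) cv <- matrix(cv, 1, 1)
            cv <- cv + diag(1e-8 + 1e-4 * mean(diag(cv)), P)
            Rs[[s]] <- chol(cv) * (2.38 / sqrt(P))
          }
        }
        srate <- sig_acc / adapt_every
        sig_prop <- pmin(pmax(sig_prop * exp(srate - 0.44), 1e-3), 10)
        sig_acc[] <- 0
        nc_mu_scale <- pmin(pmax(nc_mu_scale * exp(nc_mu_acc / adapt_every - 0.35), 1e-3), 10)
        nc_mu_acc[] <- 0
        nc_sig_scale <- pmin(pmax(nc_sig_scale * exp(nc_sig_acc / adapt_every - 0.44), 1e-3), 10)
        nc_sig_acc[] <- 0
      }
      if (it > iter_warmup) {
        j <- it - iter_warmup
        mu_s[j, , ] <- mu
        sigma_s[j, ] <- sigma
        theta_s[j, , ] <- theta
        ll_s[j] <- sum(ll_cur)
      }
    }
    list(mu = mu_s, sigma = sigma_s, theta = theta_s, loglik = ll_s)
  }

  draws <- lapply(seq_len(chains), run_chain)

  diagnostics <- group_diagnostics(draws, spec$params, grp_levels)
  converged <- all(diagnostics$rhat <= rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warn(sprintf(
      "convergence warning: max split-Rhat %.3f exceeds %.2f; do not trust summaries",
      max(diagnostics$rhat, na.rm = TRUE), rhat_threshold))
  }

  structure(
    list(draws = draws, spec = spec, priors = priors, params = spec$params,
         groups = grp_levels, subjects = subjects, subj_group = subj_group,
         gidx = gidx, enc = enc, q0 = q0, rho_mode = rho_mode,
         settings = list(chains = chains, iter_warmup = iter_warmup,
                         iter_sample = iter_sample, seed = seed),
         diagnostics = diagnostics, converged = converged,
         n_trials = nrow(trials),
         runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "vpvd_fit"
  )
}

# split-Rhat (chains halved) for an iter x chain matrix
split_rhat <- function(mat) {
  n <- nrow(mat) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(n), j], mat[n + seq_len(n), j])
  }))
  w <- mean(apply(halves, 2, var))
  if (!is.finite(w) || w == 0) return(1)
  b <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_sum <- function(mat) {
  sum(apply(mat, 2, function(v) coda::effectiveSize(coda::mcmc(v))))
}

group_diagnostics <- function(draws, params, groups) {
  P <- length(params)
  G <- length(groups)
  rows <- list()
  for (p in seq_len(P)) {
    for (g in seq_len(G)) {
      m <- vapply(draws, function(d) d$mu[, p, g], numeric(nrow(draws[[1]]$mu)))
      rows[[length(rows) + 1]] <- tibble(
        term = sprintf("mu[%s,%s]", params[p], groups[g]),
        parameter = params[p], group = groups[g],
        rhat = split_rhat(m), ess = ess_sum(m))
    }
    s <- vapply(draws, function(d) d$sigma[, p], numeric(nrow(draws[[1]]$sigma)))
    rows[[length(rows) + 1]] <- tibble(
      term = sprintf("sigma[%s]", params[p]), parameter = params[p],
      group = NA_character_, rhat = split_rhat(s), ess = ess_sum(s))
  }
  dplyr::bind_rows(rows)
}

# pooled draws (all chains) of one group-level mean
mu_draws <- function(fit, parameter, group, scale = "natural") {
  p <- match(parameter, fit$params)
  g <- match(group, fit$groups)
  if (is.na(p)) abort(sprintf("parameter '%s' not in model %d (%s)",
                              parameter, fit$spec$model_id, fit$spec$label))
  if (is.na(g)) abort(sprintf("unknown group '%s'", group))
  x <- unlist(lapply(fit$draws, function(d) d$mu[, p, g]))
  if (scale == "natural") to_natural(parameter, x) else x
}

sigma_draws <- function(fit, parameter) {
  p <- match(parameter, fit$params)
  unlist(lapply(fit$draws, function(d) d$sigma[, p]))
}

theta_draws <- function(fit, parameter, subject, scale = "natural") {
  p <- match(parameter, fit$params)
  s <- match(subject, fit$subjects)
  x <- unlist(lapply(fit$draws, function(d) d$theta[, s, p]))
  if (scale == "natural") to_natural(parameter, x) else x
}

#' @export
print.vpvd_fit <- function(x, ...) {
  cat(sprintf(
    "<vpvd_fit> model %d (%s)\n%d subjects in %d groups, %d trials\n%d chains x %d draws (+%d warmup), %.1f s\nmax split-Rhat %.3f%s\n",
    x$spec$model_id, x$spec$label, length(x$subjects), length(x$groups),
    x$n_trials, x$settings$chains, x$settings$iter_sample,
    x$settings$iter_warmup, x$runtime, max(x$diagnostics$rhat),
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A [fit_vpvd()] object.
#' @param scale `"natural"` (parameters mapped back to their bounds) or
#'   `"transformed"` (the sampling scale).
#' @param what `"group"` for group-level means (one row per parameter x
#'   group, with split-Rhat and ESS) or `"subject"` for subject-level
#'   posterior means.
#' @param ... Unused.
#' @return A tibble with posterior mean, SD, and 75%/95% HDIs per term.
#' @export
tidy.vpvd_fit <- function(x, scale = c("natural", "transformed"),
                          what = c("group", "subject"), ...) {
  scale <- match.arg(scale)
  what <- match.arg(what)
  if (what == "group") {
    grid <- expand.grid(parameter = x$params, group = x$groups,
                        stringsAsFactors = FALSE)
    purrr::pmap_dfr(grid, function(parameter, group) {
      d <- mu_draws(x, parameter, group, scale)
      h75 <- hdi(d, 0.75)
      h95 <- hdi(d, 0.95)
      diag <- x$diagnostics[x$diagnostics$term ==
                              sprintf("mu[%s,%s]", parameter, group), ]
      tibble(parameter = parameter, group = group, estimate = mean(d),
             std.error = sd(d), hdi75_lower = h75[1], hdi75_upper = h75[2],
             hdi95_lower = h95[1], hdi95_upper = h95[2],
             rhat = diag$rhat, ess = diag$ess)
    })
  } else {
    grid <- expand.grid(parameter = x$params, subject = x$subjects,
                        stringsAsFactors = FALSE)
    purrr::pmap_dfr(grid, function(parameter, subject) {
      d <- theta_draws(x, parameter, subject, scale)
      tibble(subject_id = subject,
             group = x$subj_group[match(subject, x$subjects)],
             parameter = parameter, estimate = mean(d), std.error = sd(d))
    })
  }
}

#' One-line summary of a fitted model
#'
#' @param x A [fit_vpvd()] object.
#' @param ... Unused.
#' @return A one-row tibble: model id, data size, sampler settings,
#'   diagnostics, mean total log-likelihood.
#' @export
glance.vpvd_fit <- function(x, ...) {
  tibble(
    model_id = x$spec$model_id, n_subjects = length(x$subjects),
    n_groups = length(x$groups), n_trials = x$n_trials,
    chains = x$settings$chains, iter_sample = x$settings$iter_sample,
    max_rhat = max(x$diagnostics$rhat), min_ess = min(x$diagnostics$ess),
    converged = x$converged,
    mean_loglik = mean(unlist(lapply(x$draws, `[[`, "loglik")))
  )
}
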