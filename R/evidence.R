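logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bridge-sampling estimate of a log normalising constant
#'
#' Iterative optimal-bridge estimator with a moment-matched multivariate
#' normal proposal. The first half of the posterior draws fits the proposal;
#' the second half enters the bridge identity together with fresh proposal
#' draws. The reported standard error uses the independent-draw
#' approximation.
#'
#' @param post_draws Matrix of posterior draws (rows = draws, columns =
#'   unconstrained parameters).
#' @param log_q Function taking a matrix of points (same columns) and
#'   returning the log unnormalised posterior density of each row.
#' @param n_proposal Number of proposal draws (default: as many as the
#'   second half of `post_draws`).
#' @param seed Optional seed for the proposal draws.
#' @param max_iter,tol Iteration control.
#' @return List with `log_ml`, `se`, `n_iter`, `converged`.
#' @export
bridge_sample <- function(post_draws, log_q, n_proposal = NULL, seed = NULL,
                          max_iter = 1000, tol = 1e-8) {
  post_draws <- as.matrix(post_draws)
  n <- nrow(post_draws)
  d <- ncol(post_draws)
  if (n < 10) abort("need at least 10 posterior draws")
  if (!is.null(seed)) set.seed(seed)
  n1 <- n %/% 2
  fit_half <- post_draws[seq_len(n1), , drop = FALSE]
  eval_half <- post_draws[(n1 + 1):n, , drop = FALSE]
  if (is.null(n_proposal)) n_proposal <- nrow(eval_half)

  m <- colMeans(fit_half)
  Sg <- stats::cov(fit_half)
  Sg <- Sg + diag(1e-8 * (mean(diag(Sg)) + 1e-12), d)
  U <- chol(Sg)
  log_g <- function(X) {
    xc <- sweep(X, 2, m)
    y <- backsolve(U, t(xc), transpose = TRUE)
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(y^2))
  }
  prop <- matrix(rnorm(n_proposal * d), n_proposal, d) %*% U +
    matrix(m, n_proposal, d, byrow = TRUE)

  l1 <- log_q(eval_half) - log_g(eval_half)
  l2 <- log_q(prop) - log_g(prop)
  if (any(!is.finite(l1))) {
    bad <- !is.finite(l1)
    if (mean(bad) > 0.5) abort("bridge sampling: log density non-finite at posterior draws")
    l1 <- l1[!bad]
  }
  keep2 <- is.finite(l2) | l2 == -Inf
  l2 <- l2[keep2]
  n1e <- length(l1)
  n2e <- length(l2)
  s1 <- n1e / (n1e + n2e)
  s2 <- n2e / (n1e + n2e)

  lstar <- median(l1)
  l1s <- l1 - lstar
  l2s <- l2 - lstar
  r <- 1
  converged <- FALSE
  it <- 0
  f1 <- f2 <- NULL
  while (it < max_iter) {
    it <- it + 1
    f2 <- 1 / (s1 + s2 * r * exp(-l2s))        # proposal-side terms
    f1 <- 1 / (s1 * exp(l1s) + s2 * r)         # posterior-side terms
    r_new <- mean(f2) / mean(f1)
    if (!is.finite(r_new) || r_new <= 0) {
      abort("bridge sampling estimator diverged (non-finite ratio)")
    }
    if (abs(log(r_new) - log(r)) < tol) {
      r <- r_new
      converged <- TRUE
      break
    }
    # geometric damping: same fixed point, suppresses the period-2
    # oscillation the plain iteration shows under weak overlap
    r <- sqrt(r * r_new)
  }
  log_ml <- log(r) + lstar
  re2 <- var(f2) / (n2e * mean(f2)^2) + var(f1) / (n1e * mean(f1)^2)
  list(log_ml = log_ml, se = sqrt(re2), n_iter = it, converged = converged)
}

# flatten posterior draws of a fit into the unconstrained matrix used for
# evidence estimation: group means, log group SDs, subject parameters
fit_draw_matrix <- function(fit) {
  P <- length(fit$params)
  G <- length(fit$groups)
  S <- length(fit$subjects)
  do.call(rbind, lapply(fit$draws, function(d) {
    n <- nrow(d$sigma)
    cbind(matrix(d$mu, n, P * G), log(d$sigma),
          matrix(d$theta, n, S * P))
  }))
}

# log unnormalised posterior on the unconstrained scale (includes the
# log-sigma Jacobian), vectorised over rows
fit_log_q <- function(fit) {
  P <- length(fit$params)
  G <- length(fit$groups)
  S <- length(fit$subjects)
  pr <- fit$priors
  enc <- fit$enc
  spec <- fit$spec
  gidx <- fit$gidx
  rc <- rho_mode_code(fit$rho_mode)
  expander <- make_expander(spec)
  function(X) {
    apply(X, 1, function(x) {
      mu <- matrix(x[seq_len(P * G)], P, G)
      logsig <- x[P * G + seq_len(P)]
      sig <- exp(logsig)
      theta <- matrix(x[P * G + P + seq_len(S * P)], S, P,
                      dimnames = list(NULL, fit$params))
      lp <- sum(dnorm(mu, pr$mu_mean, pr$mu_sd, log = TRUE)) +
        sum(log(2) + dnorm(sig, 0, pr$sigma_scale, log = TRUE) + logsig)
      for (p in seq_len(P)) {
        lp <- lp + sum(dnorm(theta[, p], mu[p, gidx], sig[p], log = TRUE))
      }
      ll <- cpp_loglik(enc$subj_start, enc$session, enc$left, enc$right,
                       enc$chosen, enc$side, enc$reinforced,
                       expander(theta), fit$q0, rc)
      lp + sum(ll)
    })
  }
}

#' Log marginal likelihood of a fitted model
#'
#' Bridge-sampling estimate of the model evidence (the likelihood integrated
#' over the hierarchical prior), computed from the stored posterior draws on
#' the unconstrained scale.
#'
#' @param fit A [fit_vpvd()] object.
#' @param seed Seed for the proposal draws.
#' @param n_proposal Number of proposal draws (default matched to the
#'   posterior evaluation half).
#' @return A one-row tibble: `model_id`, `log_ml`, `se`, `converged` (the
#'   fit's convergence gate), `bridge_converged`.
#' @export
log_marginal_likelihood <- function(fit, seed = 1, n_proposal = NULL) {
  br <- bridge_sample(fit_draw_matrix(fit), fit_log_q(fit),
                      n_proposal = n_proposal, seed = seed)
  tibble(model_id = fit$spec$model_id, parameters = fit$spec$label,
         log_ml = br$log_ml, se = br$se, converged = fit$converged,
         bridge_converged = br$converged)
}

#' Posterior model probabilities under equiprobable priors
#'
#' With all models equiprobable a priori, the log posterior probability of
#' model m is its log marginal likelihood minus the log-sum-exp of all
#' models' log marginal likelihoods.
#'
#' @param log_ml Numeric vector (length >= 2) of log marginal likelihoods in
#'   nats.
#' @return Vector of log posterior model probabilities (all <= 0; their
#'   exponentials sum to 1).
#' @examples
#' posterior_model_probabilities(c(-10, -10)) # both log(0.5)
#' @export
posterior_model_probabilities <- function(log_ml) {
  if (length(log_ml) < 2) abort("need at least two models")
  if (any(!is.finite(log_ml))) abort("log marginal likelihoods must be finite")
  log_ml - logsumexp(log_ml)
}

#' Ranked model-comparison table
#'
#' Ranks models by log marginal likelihood (rank 1 = largest; ties broken by
#' smaller model id) and appends log posterior model probabilities under
#' equiprobable model priors. Models flagged as non-converged are excluded
#' from ranking and probabilities and carry `NA` markers instead.
#'
#' @param evidence A tibble with columns `model_id`, `log_ml`, and optionally
#'   `parameters` and `converged` (default `TRUE`).
#' @return The table sorted by rank, with `rank` and `log_posterior_p` added.
#' @export
comparison_table <- function(evidence) {
  if (anyDuplicated(evidence$model_id)) abort("duplicate model ids")
  if (!"converged" %in% names(evidence)) evidence$converged <- TRUE
  if (!"parameters" %in% names(evidence)) {
    evidence$parameters <- list_models()$parameters[evidence$model_id]
  }
  ok <- evidence$converged & is.finite(evidence$log_ml)
  evidence$rank <- NA_integer_
  evidence$log_posterior_p <- NA_real_
  if (sum(ok) >= 1) {
    sub <- evidence[ok, ]
    ord <- order(-sub$log_ml, sub$model_id)
    evidence$rank[ok][ord] <- seq_len(sum(ok))
    if (sum(ok) >= 2) {
      evidence$log_posterior_p[ok] <-
        posterior_model_probabilities(sub$log_ml)
    }
  }
  dplyr::arrange(evidence, is.na(.data$rank), .data$rank)
}

#' Fit and compare several models on one trial log
#'
#' Fits each requested model with [fit_vpvd()], estimates its evidence with
#' [log_marginal_likelihood()], and returns the ranked [comparison_table()].
#'
#' @param trials Trial-log tibble.
#' @param models Integer vector of model ids (default 1:9).
#' @param ... Passed to [fit_vpvd()] (chains, iterations, seed, priors...).
#' @param bridge_seed Seed for the bridge-sampling proposals.
#' @return A ranked evidence tibble (see [comparison_table()]).
#' @export
compare_models <- function(trials, models = 1:9, ..., bridge_seed = 1) {
  evidence <- purrr::map_dfr(models, function(m) {
    fit <- fit_vpvd(trials, model = m, ...)
    log_marginal_likelihood(fit, seed = bridge_seed)
  })
  comparison_table(evidence)
}
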