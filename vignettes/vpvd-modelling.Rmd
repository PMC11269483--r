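---
title: "Modelling reversal learning on the valence-probe visual discrimination task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reversal learning on the valence-probe visual discrimination task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and what the package models

The valence-probe visual discrimination (VPVD) task is a three-stimulus
touchscreen discrimination used to separate learning from positive and
negative feedback in rodents. Stimulus A is reinforced on every choice,
stimulus B never, and a probe stimulus C is reinforced on 50% of choices.
Standard trials present A against B; probe trials pair C with A (positive
probe) or with B (negative probe), each embedded exactly once per 8-trial
bin at a random position that is never the first trial of the bin, in
sessions of up to 200 trials. After acquisition, the A/B contingency is
reversed between sessions and flexibility is measured by how quickly choice
adapts.

`vpvdrl` implements this design end to end: schedule generation
(`generate_schedule()`, independently re-checked by `validate_schedule()`),
a nine-member family of reinforcement-learning (RL) observation models,
hierarchical Bayesian fitting, model comparison by log marginal likelihood,
highest-density-interval (HDI) group contrasts, posterior predictive
simulation, and the conventional phase-coded behavioural metrics. Because
no trial-level dataset is publicly deposited for this paradigm with drug
groups, the package ships a synthetic-cohort generator
(`cohort_config()`, `generate_cohort()`) that reproduces the study
structure — three dose groups (vehicle/low/high), around 12 subjects per
group, a between-session reversal, 200-trial sessions — with known
ground-truth parameters, so that every downstream stage is testable.

## The RL model family

Values are updated by the delta rule. Writing $c_t$ for the chosen stimulus
and $r_t \in \{0,1\}$ for reinforcement,

$$Q_{t+1}(c_t) = Q_t(c_t) + \alpha\,(r_t - Q_t(c_t)),$$

with $\alpha = \alpha_{rew}$ after reinforcement and $\alpha = \alpha_{pun}$
otherwise in split-rate models, or a single shared $\alpha$. Choice between
the two presented options is a softmax on additive logits

$$x(\text{option}) = \beta\,Q(\text{option})
  + \kappa_{stim}\,\mathbb{1}[\text{stimulus repeated}]
  + \kappa_{side}\,\mathbb{1}[\text{side repeated}],$$

where $\beta \ge 0$ is reinforcement sensitivity (inverse temperature) and
the $\kappa$ terms capture value-independent stickiness for the previously
chosen stimulus and screen side. The richest model adds a forgetting factor
$\rho$: after each trial every non-chosen stimulus value decays,
$Q \leftarrow \rho\,Q + (1-\rho)\,Q_0$ by default, so $\rho = 1$ means no
forgetting and the richer model nests the simpler ones exactly. The nine
models are the combinations registered in `list_models()`: shared vs split
learning rates crossed with the presence of $\kappa_{stim}$,
$\kappa_{side}$, and (model 9 only) $\rho$.

Numerical and structural choices:

* **Initial values.** $Q_0 = 0.5$ for all three stimuli — the midpoint of
  the 0/1 reinforcement scale, unbiased between reward and punishment.
  Configurable via `q0`.
* **Forgetting variant.** The published functional form of $\rho$ is not
  restated outside supplementary material we treat as unavailable, so both
  defensible readings are implemented: decay toward the initial value
  (`rho_mode = "initial"`, the default, which makes $\rho = 1$ exactly
  neutral) and pure decay toward zero (`rho_mode = "decay"`). Neither is
  asserted to be the published form.
* **State carrying.** Q-values carry across sessions; the stickiness
  indicators refer to the previous trial only and reset at each session
  boundary (no "previous trial" across days). During fitting the observed
  reinforcement column is taken as ground truth, so the likelihood never
  needs to know whether a reversal has occurred.
* **Softmax stability.** All softmax computations subtract the maximum
  logit; likelihood probabilities are floored at `1e-300` before `log`.
* **Dual likelihood routes.** `session_log_likelihood()` has a naive
  per-trial R implementation and a compiled kernel; the test suite holds
  them equal to machine precision, and the nesting identities (model 9 with
  neutral parameters reproduces each smaller model bit-for-bit) are
  asserted exactly.

## The synthetic cohort as the study conditions

The generator draws each subject's parameters from group-level normal
distributions on transformed scales — logit for learning rates and $\rho$,
log for $\beta$, identity for $\kappa$ — mirroring the structure the fitted
model assumes. The default vehicle-group means (natural scale
$\alpha_{rew}=0.20$, $\alpha_{pun}=0.15$, $\beta=4$,
$\kappa_{side}=\kappa_{stim}=0.2$, $\rho=0.95$; between-subject SDs 0.4,
0.3, 0.2, 0.3 on the transformed scales) are fixed once as values a
behavioural-RL practitioner would call typical for rats on a visual
discrimination: learning rates in the 0.1–0.3 range, sensitivity high
enough to reach 80–90% asymptotic accuracy on a 0–1 value scale, mild
positive stickiness, and weak forgetting. Dose effects are injected as mean
shifts via `effect_preset()`; the presets encode the reported effect
directions qualitatively (e.g. `"2a-low"`: lower punishment learning rate
and sensitivity, higher stickiness) with declared magnitudes of 0.8 on
logit learning rates and 0.4 elsewhere — moderate-to-large
pharmacological effects.

What the generator deliberately does not emulate: response and collection
latencies, omitted trials, satiety or motivation drift, attrition, and the
criterion-based session-extension logistics of real training. Passing
recovery tests therefore demonstrates that the pipeline is correct and
well calibrated *under the model's own assumptions*, not that real rats
satisfy those assumptions.

## Hierarchical fitting

`fit_vpvd()` performs one joint fit per experiment with group-indexed means:
subject parameters $\theta_{p,s} \sim \mathcal{N}(\mu_{p,g(s)}, \sigma_p)$
on the transformed scale, weakly informative priors
$\mu \sim \mathcal{N}(0,1)$ and $\sigma \sim \text{half-}\mathcal{N}(1)$
(`vpvd_priors()`). The SDs are shared across dose groups — with a dozen
subjects per group, group-specific SDs are poorly identified and the
published analysis does not indicate them.

The sampler is adaptive Metropolis-within-Gibbs, designed around the fact
that the likelihood (but nothing else) is expensive:

* subject-level parameters are updated as per-subject joint blocks with
  Haario-style empirical-covariance proposals, one compiled likelihood
  evaluation per sweep for all subjects;
* group means have exact conjugate Gibbs draws; group SDs use a cheap
  log-scale random walk repeated several times per sweep;
* interweaved non-centered moves — translating a group mean with its
  subjects riding along, and rescaling a group SD with the standardised
  subject effects held fixed — break the mean/SD-versus-subject funnel that
  otherwise stalls centered samplers in hierarchical models;
* all proposal scales and covariances adapt during warmup only, so the
  post-warmup chain is a fixed-kernel Markov chain.

Convergence is summarised by split-$\hat R$ and effective sample size on
the group-level parameters; any split-$\hat R > 1.05$ raises a warning and
marks the fit non-converged. Defaults are 4 chains of 1000 warmup + 1000
sampling iterations; the tests and the acceptance script use reduced
presets (2 chains, 500–900 + 500–900) with correspondingly reduced problem
sizes, chosen as the package's standard small-scale verification setting.

Contrasts (`group_difference()`, `contrast_table()`) are formed per
posterior draw as treated-minus-control differences of group means
(back-transformed to the natural scale, as this literature plots them) and
flagged by the HDI evidence rule: `STRONG` when 0 lies outside the 95% HDI,
`MODERATE` when outside the 75% HDI only, `NONE` otherwise. `hdi()` is the
empirical shortest interval, tested against a brute-force scan.

## Model comparison

`log_marginal_likelihood()` estimates each model's evidence — the
likelihood integrated over the hierarchical prior — by iterative bridge
sampling on the unconstrained parameterisation (group means, log SDs,
subject parameters), with a moment-matched multivariate normal proposal
fitted to half of the posterior draws. The iteration uses geometric
damping, which leaves the fixed point unchanged but suppresses the
period-two oscillation the plain iteration exhibits when overlap is weak.
The reported standard error uses the independent-draw approximation and
slightly understates the error of autocorrelated MCMC draws; the toy
conjugate test in the suite checks the estimator against a closed form.
`posterior_model_probabilities()` converts evidences to log posterior model
probabilities under equiprobable priors (a log-sum-exp normalisation), and
`comparison_table()` ranks models, breaking ties by the smaller (more
parsimonious) model id. Models whose fits fail the split-$\hat R$ gate are
excluded from ranking and carry `NA` markers rather than a number — richer
models in this family are known to fail to converge on some datasets, and
a non-converged evidence value would be meaningless.

## Conventional behavioural metrics

`vpvd_metrics()` reproduces the standard analysis stream. Post-reversal
standard-trial outcomes, concatenated across sessions, are classified by
rolling 30-trial windows with one-tailed binomial cutoffs computed from the
binomial CDF at $\alpha = 0.05$ ($\le 10/30$ below chance, $\ge 20/30$
above): trials are labelled perseverative until the first window that is
not below chance, random until the first window above chance, and learning
thereafter — the monotone phase order; once random responding begins, a
later below-chance window does not re-open the perseverative phase.
Sequences shorter than one window are labelled random with a warning
(insufficient evidence either way). Errors to criterion counts errors up to
and including the first disjoint 30-trial block with at least 24 correct;
trailing partial blocks cannot qualify, and a never-reached criterion is
marked rather than silently truncated. Probe trials are excluded from phase
coding and the criterion. Percent-correct and percent-optimal-choice
measures, and win-stay/lose-shift proportions (within-session pairs where
the previously chosen stimulus is available again), complete the table.

The exact binomial thresholds in the antecedent literature are not restated
in the source for this paradigm; computing them from the CDF at the stated
window and criterion is this package's declared convention, and both the
window and $\alpha$ are arguments.

## Design decisions that were genuinely open

* **Partial probe bins.** When a session length is not a multiple of 8 the
  trailing partial bin holds only standard trials, keeping the one-probe-
  of-each-type-per-bin invariant clean.
* **Side assignment** is an independent fair coin per trial; the source
  counterbalances stimulus identity across animals but is silent on
  per-trial side placement.
* **Probe-type semantics after reversal.** Probe labels follow the current
  contingency (a positive probe always pairs the currently rewarded
  stimulus with C), so reversal-phase schedules are generated under the
  reversed stimulus set and percent-optimal measures are scored against
  current reward probabilities.
* **Evidence estimator.** Bridge sampling matches standard practice for
  Stan-era hierarchical RL analyses; the source does not name its
  estimator, so this is recorded as an assumption, not an attribution.
* **Scale of verification runs.** Recovery and model-recovery checks run at
  a reduced scale (6 subjects per group, 6 sessions for parameter and
  effect recovery; 3 per group, 6 sessions, models {1,3,5,7} for model
  recovery), the package's declared small-scale setting for routine
  verification; the full study scale (12 per group, 14 sessions) uses the
  same code paths.

## Known limitations

* The sampler is a random-walk scheme, not gradient-based; very weakly
  identified parameters (notably $\rho$ close to 1 combined with small
  learning rates) mix slowly, and model 9 can legitimately fail the
  convergence gate on small datasets — mirroring the non-convergence the
  published analysis itself reports for its richer model on one dataset.
* Bridge-sampling standard errors assume independent draws and are
  optimistic for short chains; model ranking in the tests relies on
  evidence gaps far larger than this error.
* The forgetting factor's published functional form is unavailable; results
  involving $\rho$ are conditional on the implemented variant.
* Latencies, omissions and motivational dynamics are outside the model
  family by design.

## A worked example

```{r example}
library(vpvdrl)

cfg <- cohort_config(n_per_group = 6, sessions_pre = 0, sessions_post = 6,
                     max_trials = 200, model = 9, effects = "2a-low",
                     seed = 1)
cohort <- generate_cohort(cfg)

fit <- fit_vpvd(cohort$trials, model = 9, chains = 2,
                iter_warmup = 800, iter_sample = 800, seed = 1)
tidy(fit)                 # posterior group means with 75%/95% HDIs
contrast_table(fit)       # dose-group contrasts with evidence flags
autoplot(fit)

metrics <- vpvd_metrics(cohort$trials, cfg$stimulus_set)
autoplot(metrics)

evidence <- compare_models(cohort$trials, models = c(1, 7, 9),
                           chains = 2, iter_warmup = 800,
                           iter_sample = 800, seed = 1)
evidence
```
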