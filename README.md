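# vpvdrl

Reinforcement-learning analysis of the **valence-probe visual
discrimination (VPVD)** reversal task — the rodent touchscreen paradigm
used to dissect how serotonergic drugs modulate learning from positive and
negative feedback and cognitive flexibility.

In the VPVD task, stimulus **A** is always reinforced, **B** never, and a
probe stimulus **C** is reinforced 50% of the time; probe trials pair C
with A (positive probe) or B (negative probe), once each per 8-trial bin,
never on a bin's first trial, in sessions of up to 200 trials. After
acquisition the A/B contingency is reversed between sessions. `vpvdrl`
provides a tested pipeline for this design:

* **Task simulation** — schedule generation with the probe-bin invariants
  (`generate_schedule()`, `validate_schedule()`), reinforcement rules and
  reversal (`reward_outcome()`, `apply_reversal()`), and synthetic cohorts
  with three dose groups and known ground truth (`cohort_config()`,
  `generate_cohort()`, `effect_preset()`).
* **The nine-model RL family** — Q-learning with shared or split
  reward/punishment learning rates, softmax choice with stimulus and side
  stickiness, and trial-wise value forgetting:

  Q(c) ← Q(c) + α·(r − Q(c)),  α = α_rew or α_pun

  P(choose left) = softmax over β·Q + κ_stim·1[stimulus repeat] + κ_side·1[side repeat]

  (`model_spec()`, `list_models()`, `session_log_likelihood()`,
  `simulate_agent()`).
* **Hierarchical Bayesian fitting** — one joint fit across dose groups by
  adaptive MCMC with a compiled likelihood kernel, split-Rhat/ESS
  diagnostics (`fit_vpvd()`, `tidy()`, `glance()`, `autoplot()`).
* **Inference** — shortest-interval HDIs, dose-group contrasts with the
  0-outside-75%/95%-HDI evidence flags, posterior predictive simulation
  (`hdi()`, `group_difference()`, `contrast_table()`,
  `posterior_predictive_simulate()`).
* **Model comparison** — bridge-sampled log marginal likelihoods and log
  posterior model probabilities under equiprobable priors, with a
  convergence gate (`log_marginal_likelihood()`,
  `posterior_model_probabilities()`, `comparison_table()`,
  `compare_models()`).
* **Conventional behavioural metrics** — perseverative/random/learning
  phase coding by rolling 30-trial binomial windows, errors to the 24/30
  criterion, percent correct / percent optimal choice, win-stay/lose-shift
  (`label_phases()`, `errors_to_criterion()`, `percent_measures()`,
  `win_stay_lose_shift()`, `vpvd_metrics()`).

See the vignette (`vignettes/vpvd-modelling.Rmd`) for the model family,
priors, sampler design, and the package's design decisions.

## Worked example

Simulate a reduced cohort with a known dose effect (the "2a-low" preset
lowers the punishment learning rate and reinforcement sensitivity and
raises both stickiness parameters in the low-dose group), fit the richest
model, and test the contrasts:

```r
library(vpvdrl)

cfg <- cohort_config(n_per_group = 6, sessions_pre = 0, sessions_post = 6,
                     max_trials = 200, model = 9, effects = "2a-low",
                     seed = 401)
cohort <- generate_cohort(cfg)
fit <- fit_vpvd(cohort$trials, model = 9, chains = 2,
                iter_warmup = 800, iter_sample = 800, seed = 501)
contrast_table(fit)
```

The contrast table this run prints (selected columns):

```
    parameter group estimate hdi95_lower hdi95_upper     flag direction
1   alpha_rew   low   0.1111     -0.0718      0.3550     NONE         -
2   alpha_rew  high   0.0608     -0.1123      0.2473     NONE         -
3   alpha_pun   low   0.0887     -0.3056      0.5107     NONE         -
4   alpha_pun  high  -0.1815     -0.4154      0.0189 MODERATE      down
5        beta   low  -1.7781     -3.1897     -0.4983   STRONG      down
6        beta  high   0.7078     -1.0662      2.3785     NONE         -
7  kappa_side   low   0.6429      0.4680      0.8363   STRONG        up
8  kappa_side  high   0.2159      0.0242      0.4133   STRONG        up
9  kappa_stim   low   0.2796     -0.0450      0.5987 MODERATE        up
10 kappa_stim  high  -0.2127     -0.5509      0.1312 MODERATE      down
11        rho   low  -0.0168     -0.0734      0.0411     NONE         -
12        rho  high  -0.0354     -0.0822      0.0188 MODERATE      down
```

Each row is a treated-vs-vehicle difference in the posterior group mean:
`flag` is `STRONG` when 0 is outside the 95% HDI, `MODERATE` when outside
the 75% HDI only, and `direction` gives the sign of a flagged effect. In
this reduced run the injected drops in reinforcement sensitivity (`beta`)
and rises in both stickiness parameters are flagged in the injected
directions; the injected punishment-learning-rate drop is not resolved at
this scale because the forgetting factor `rho` can absorb it — at the full
study scale (12 subjects per group, 14 sessions; see the acceptance
checks) it is recovered as well.

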