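# pwmmrm — propensity-weighted MMRM analysis of placebo-controlled trials

Randomized trials in major depressive disorder routinely fail because of
high and heterogeneous placebo response. Even under randomization, the
*individual propensity to respond to placebo* — the non-specific
improvement a subject would show under any intervention — is unobserved
and can be imbalanced across arms, diluting the estimable drug–placebo
difference.

`pwmmrm` implements a five-stage analysis that estimates each subject's
placebo-response propensity from data collected *before* randomization
and uses it to weight the primary efficacy analysis:

1. **Label** end-of-study placebo response in the placebo arm as a
   clinically relevant fractional reduction of the total rating-scale
   score (defaults: 41% on the HAMD-17, the equipercentile-linked
   equivalent of 38% on the MADRS; CGI-I anchor machinery included).
2. **Train** a multilayer perceptron mapping the 17 screening→baseline
   HAMD-17 item changes Δx ∈ ℤ¹⁷ to P(response) on a 75% split of the
   labeled placebo arm, with a topology grid search (1–3 logistic hidden
   layers, 1–17 nodes).
3. **Validate** on the held-out 25% by bootstrap ROC AUC with a
   percentile confidence interval.
4. **Predict** the propensity *pᵢ* for every randomized subject in every
   arm and form the analysis weight *wᵢ = 1 / clip(pᵢ; p_min, p_max)*.
5. **Estimate** the treatment effect with a weighted mixed model for
   repeated measures (MMRM) on the change from baseline *y_iv*:

   fixed effects — visit (classification), treatment×visit, centred
   baseline and baseline×visit; within-subject covariance — unstructured
   Σ (T×T), REML, with per-subject weights dividing the residual
   covariance, `V_i = Σ_obs(i) / w_i`. The treatment effect (TE) is the
   LS-mean difference active − placebo at week 8, and the effect size is
   `|TE| / (SE / √(1/n₁ + 1/n₂))`.

A sensitivity module refits the 2×3 grid {weighted, unweighted} ×
{all, p < 0.2 removed, p > 0.8 removed} and summarizes instability by the
mean relative absolute TE deviation
`B = mean |TE_subset − TE_all| / |TE_all|`.

Because no public data exist for the motivating case study, the package
ships a first-class synthetic-trial generator in which a latent
propensity πᵢ ~ Beta(a, b) drives both pre-randomization item drift and
the post-randomization placebo trajectory, so every stage is testable
end to end.

## Worked example

```r
library(pwmmrm)

cfg <- run_config(sim = sim_config(), seed = 1,
                  train = train_config(max_epochs = 200),
                  mmrm = mmrm_spec(df_method = "residual"))
rep <- run_pipeline(cfg)
print(rep)
```

```
Propensity-weighted trial analysis
  census: active_high=154, active_low=156, placebo=149
  response threshold: 41% reduction (HAMD17)
  selected topology: 1
ROC AUC 0.795 (95% bootstrap CI 0.624-0.936, 1000 replicates)

Treatment effects at the analysis visit:
  [unweighted]
    active_low_vs_placebo at week8: TE -0.926 (SE 0.488, df 2411.0), p 0.0578, effect size 0.222
    active_high_vs_placebo at week8: TE -1.119 (SE 0.490, df 2411.0), p 0.0224, effect size 0.269
  [weighted]
    active_low_vs_placebo at week8: TE -1.368 (SE 0.501, df 2411.0), p 0.00639, effect size 0.319
    active_high_vs_placebo at week8: TE -1.522 (SE 0.498, df 2411.0), p 0.00225, effect size 0.360

Sensitivity bias B: weighted 0.279, unweighted 0.637
```

Reading this: the simulated trial (459 subjects, three arms, 8 weeks)
carries a genuine drug effect that is masked in the conventional
analysis by subjects whose improvement is non-specific. The validation
AUC of 0.80 says the pre-randomization item changes predict placebo
response well above chance. Weighting by the inverse propensity
increases the estimated TE magnitudes and effect sizes and turns a
borderline low-dose contrast (p = 0.058) into a clear one (p = 0.006).
The bias summary shows the weighted analysis is far less sensitive to
removing extreme-propensity subjects (B = 0.28 vs 0.64).

Individual stages are plain functions returning classed objects
(`trial_dataset`, `pwmmrm_mlp`, `pwmmrm_fit` with
`print`/`summary`/`coef`/`vcov`/`logLik` methods, `treatment_effect`,
`sensitivity_report`); see `?mmrm_fit`, `?train_mlp`,
`?run_sensitivity_grid`, `?generate_trial`.

A thin command-line wrapper ships at `inst/cli/pwmmrm`
(`simulate` / `analyze` / `sensitivity` / `report` subcommands).

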