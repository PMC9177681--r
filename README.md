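# tntmodel

Trial-by-trial belief modeling of memory intrusion control in
think/no-think (TNT) suppression experiments.

During a TNT task, participants repeatedly suppress a cued memory and
report after each no-think trial whether it intruded anyway. `tntmodel`
treats those binary rating sequences as the output of a learning agent
that forms a *belief* — the predicted probability
$\hat\mu_1^{(t)}$ that the upcoming cue will trigger an intrusion —
and updates it trial by trial. Beliefs index *predictive* control
(suppression deployed in anticipation); the prediction error left by an
intrusion, $\mathrm{PE}^{(t)} = y^{(t)} - \hat\mu_1^{(t)}$, indexes
*reactive* control. The package is written for computational
psychiatry / model-based neuroimaging researchers who need this pipeline
end to end:

* **Perceptual models** — Rescorla–Wagner
  ($V^{(t)} = V^{(t-1)} + \alpha(y^{(t)} - V^{(t-1)})$), a Kalman filter
  with gain recursion $K^{(t)} = \frac{K^{(t-1)}+\pi\omega}
  {K^{(t-1)}+\pi\omega+1}$, and a two-level hierarchical Gaussian filter
  (HGF) with $\hat\mu_1 = \mathrm{sigmoid}(\mu_2)$ and uncertainty-weighted
  updates governed by the log-volatility step size $\omega$ — each with
  *state*, *item*, and precision-weighted *combined* belief sources.
* **Response model** — beta density with mean $\theta$ (belief) and
  inverse decision noise $\nu$; model accuracy as summed negative
  log-likelihood; multi-start box-bounded MAP estimation.
* **Validation suite** — model falsification, trajectory / model /
  parameter recovery, and group-difference power, on seeded synthetic
  cohorts of closed-loop virtual agents.
* **Model selection** — random-effects Bayesian model selection
  (variational Dirichlet; XP, BOR, PXP), family-level inference,
  between-group frequency tests, and Bayesian model averaging.
* **Modulators** — belief- and PE⁺-modulated event regressors exported as
  BIDS-style events TSV for connectivity modelling backends.
* **Group statistics** — one-tailed coupling contrasts with BH-FDR,
  bootstrap CIs, posterior probabilities and ROPE Bayes factors; the
  circular *imbalance angle* between predictive and reactive control
  (0° = balance, +45° = purely predictive) with circular means, bootstrap
  CIs and Watson two-sample tests; symptom correlation analyses.

## Worked example

```r
library(tntmodel)

design <- tnt_design(seed = 1)           # 18 items x 8 reps over 4 sessions
agent  <- simulate_agent(design, "hgf2", "combined",
                         params = list(omega = -2.5),
                         suppression = 0.05, seed = 21)
tapply(agent$data$outcome, agent$data$session, mean)
#>         1         2         3         4
#> 0.5277778 0.4444444 0.3888889 0.2500000

fit <- fit_model(agent$data$outcome, "hgf2", "combined",
                 items = agent$data$item_id, seed = 1)
fit
#> <tnt_fit> hgf2-combined
#>   params: omega = -2.862 ; nu = 1
#>   accuracy (NLL): -530.346
```

The simulated agent's intrusion proportion declines from near chance
(0.53) toward 0.25 across the four sessions — the behavioral signature of
successful suppression — and refitting the generating model recovers a
belief-updating speed ($\hat\omega = -2.86$) close to the generating
$\omega = -2.5$; the negative NLL means the fitted beliefs predict the
ratings far better than chance. The fitted trajectory feeds the modulator
construction:

```r
mods <- build_modulators(fit$trajectory$muhat, agent$data$outcome,
                         onsets = (design$trial - 1) * 7)
head(mods, 3)
#>   onset duration trial_type    belief    pe_pos
#> 1     0        3  intrusion 0.5000000 0.5000000
#> 2     7        3  intrusion 0.6030226 0.3969774
#> 3    14        3  intrusion 0.6704490 0.3295510
```

Every no-think trial carries its belief height; only intrusion trials
carry the positive prediction error that drives reactive control.

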