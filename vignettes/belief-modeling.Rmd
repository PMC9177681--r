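---
title: "Trial-by-trial belief models of memory intrusion control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-by-trial belief models of memory intrusion control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntmodel)
```

## The problem

In a think/no-think (TNT) suppression experiment, participants repeatedly
try to keep a cued memory out of awareness and report after every no-think
trial whether the memory intruded anyway (a binary rating). Across the four
sessions of the task the proportion of intrusions typically declines from
near chance toward 25-35% as suppression takes hold. `tntmodel` treats
these rating sequences as the output of a learning agent who forms a
*belief* - the predicted probability that the upcoming cue will trigger an
intrusion - and updates it from trial to trial. The belief and the
prediction error (PE) it leaves behind index two modes of inhibitory
control: *predictive* control deployed in anticipation, and *reactive*
control that corrects intrusions which crossed the proactive gate.

The package implements the full analysis pipeline around this idea: the
perceptual learning models and their belief sources, the beta-density
response model and its MAP inversion, a simulation-based validation suite,
random-effects Bayesian model selection (RFX-BMS) and model averaging
(BMA), construction of the belief/PE parametric modulators consumed by
effective-connectivity models, and the circular statistics of the
predictive-reactive imbalance.

## Perceptual models

All models receive the binary outcome sequence $y^{(t)} \in \{0, 1\}$
(1 = intrusion); since agents predict their own ratings, the input at trial
$t$ is the rating at $t-1$. Every filter starts from a belief of 0.5.

* **Rescorla-Wagner (RW)** - fixed learning rate $\alpha \in [0,1]$:
  $V^{(t)} = V^{(t-1)} + \alpha\,(y^{(t)} - V^{(t-1)})$. The prediction for
  trial $t$ is $V^{(t-1)}$.
* **Kalman filter (KF)** - dynamic gain
  $K^{(t)} = \frac{K^{(t-1)} + \pi\omega}{K^{(t-1)} + \pi\omega + 1}$
  with belief reliability $\pi > 0$ and process uncertainty $\omega > 0$;
  beliefs move by the gain-weighted PE of the previous trial. The gain
  converges monotonically to the fixed point of this recursion, so
  uncertainty is effectively constant at steady state (no volatility).
* **Two-level hierarchical Gaussian filter (HGF)** - the first level is
  the Bernoulli intrusion outcome with prediction
  $\hat\mu_1^{(t)} = \mathrm{sigmoid}(\mu_2^{(t-1)})$; the second level is
  a Gaussian random walk with step variance $e^{\omega}$. Updates are
  first-level prediction errors weighted by second-level uncertainty
  ($\psi = 1/\pi_2$), so more uncertain beliefs move faster. The free
  parameter $\omega$ (native scale, typically negative) sets the speed of
  belief adjustment.

The first-level PE is $\mathrm{PE}^{(t)} = y^{(t)} - \hat\mu_1^{(t)}$: a
belief of 0.3 followed by an intrusion leaves a PE of 0.7 for reactive
control. (Only this outcome-minus-prediction quantity is used; the
level-2 update is driven by the same signal.)

### Belief sources

Each perceptual model exists in three source variants. The *state* source
filters the entire trial sequence; the *item* source runs an independent
filter over each word-object pair's own repetition history (at most 18
items, 8 repetitions each under the canonical design) and reassembles the
per-item beliefs chronologically; the *combined* source fuses the two. For
the HGF the fusion is precision-weighted,
$\hat\mu_c = \frac{\hat\mu_{1s}\hat\pi_{1s} + \hat\mu_{1i}\hat\pi_{1i}}
{\hat\pi_{1s} + \hat\pi_{1i}}$, with the Bernoulli prediction precision
$\hat\pi_1 = 1/(\hat\mu_1(1-\hat\mu_1))$ - the only belief-level precision
a two-level binary filter carries. RW and KF have no belief-level
precision, so their sources are averaged arithmetically. An item belief
exists only from the item's second repetition onward; earlier trials carry
the state belief. Items with fewer than two usable repetitions are dropped
with a warning, mirroring the exclusion of sparse items in real data.

## Response model and estimation

Beliefs map onto the binary ratings through a beta density with mean
$\theta$ (the belief) and concentration $\nu$ (inverse decision noise):
$\alpha_b = \theta\nu$, $\beta_b = \nu - \alpha_b$. Binary outcomes are
degenerate under a continuous density, so outcomes and beliefs are
clamped to $[10^{-4}, 1 - 10^{-4}]$. Model accuracy is the summed negative
log-likelihood of the ratings.

Two numerical properties of this response model matter and are worth
stating explicitly:

* For $\nu < 1$ the beta density is U-shaped, and its value at the clamped
  outcome points grows almost independently of the belief - a pure
  artifact optimum in which the likelihood decouples from the trajectory.
  Estimation is therefore box-bounded at $\nu \ge 1$; the bound is also
  the unbiased generative mapping used in the simulations.
* Even for $\nu \ge 1$ the density sinks again when beliefs approach
  certainty (the gamma-function pole at a vanishing shape parameter), so
  the likelihood-optimal belief for a perfectly predictable outcome sits
  near 0.85-0.9 rather than at 1. Consequently a generating RW learning
  rate of exactly 1 is recovered as a high but sub-unit rate, and learning
  rates that would drive beliefs to the bounds are penalised. This is a
  property of the response model, not of the optimiser.

`fit_model()` returns the maximum a posteriori estimate under Gaussian
priors on transformed parameters: $\omega \sim N(-3, 16)$ on its native
scale (high variance, to catch between-subject variability), KF
$\log\pi, \log\omega \sim N(0, 4)$, RW $\mathrm{logit}\,\alpha \sim
N(0,1)$, and $\log\nu \sim N(0, 4)$ above the $\nu \ge 1$ bound.
Optimisation is L-BFGS-B from five starts (the prior mean plus four
jittered by a quarter prior-sd), keeping the best objective; the fit is
deterministic given a seed. A `prior_stuck` flag marks fits whose
perceptual parameters did not leave the prior mean. For sequences with no
learnable structure the posterior prefers slowing belief updating
($\omega$ at or below its prior mean) and the trajectory stays pinned near
0.5; the trajectories remain usable for modulator construction.

## Synthetic agents and their calibration

`simulate_agent()` implements the generative procedure used throughout the
validation suite: beliefs are propagated closed-loop on the agent's own
ratings, shifted down by a *suppression factor* (without it the positive
feedback between rated intrusions and rising beliefs tilts trajectories
toward 1), perturbed by Gaussian noise, clamped, and converted to a rating
by choosing the response that maximally improves the cumulative beta-model
log-accuracy at $\nu = 1$ (for a single trial this reduces to a threshold
at 0.5; ties resolve to "no intrusion").

Two generator constants required calibration choices:

* **Suppression factor** - grid-searched per model/source
  (`tune_suppression()`, default grid 0 to 0.2 in steps of 0.01, 20 agents
  per value, common random numbers) to minimise the mean squared
  difference between the simulated and target session profiles. Ties take
  the smallest factor.
* **Belief noise sd** - the magnitude of the Gaussian perturbation is not
  determined by the model equations, but it controls the stochasticity of
  the response mapping. Very small values (at or below ~0.1) make the
  threshold response quasi-deterministic: agents absorb into all-or-none
  rating runs within the first session, profiles are flat, and the
  perceptual parameter leaves no footprint in the data. The default was
  therefore calibrated once against the packaged target profile by the
  same MSE criterion used for the suppression factor; the loss is flat
  between roughly 0.25 and 0.40, and the default is fixed at **0.3**. At
  this level simulated cohorts start near chance and decline smoothly
  across sessions.

The packaged target profile (`tnt_target_profile()`) declines 0.50, 0.42,
0.35, 0.30 across the four sessions. It is a synthetic stand-in with the
qualitative shape of real TNT intrusion data (which are not
redistributable), so falsification checks against it demonstrate the
*generative adequacy* of the models, not agreement with any particular
cohort.

Generating perceptual parameters are drawn from the estimation priors
(`draw_perceptual_params()`), i.e. $\omega \sim N(-3, 16)$ for the HGF.
This wide draw intentionally includes agents that barely learn and agents
that track their last rating almost deterministically.

## Validation suite

* **Falsification** (`run_falsification()`): can each model generate the
  session-wise decline? Ratings are averaged across repeated simulations
  per virtual subject; reported are the mean difference (MD) and the mean
  per-subject profile correlation (MC) against the target.
* **Trajectory recovery** (`trajectory_recovery()`): fit all source
  variants to data generated by one of them; the candidate whose fitted
  belief trajectory correlates best with the latent (noiseless, suppressed)
  generating trajectory is marked, and choices aggregate into a confusion
  matrix and its Bayes inversion under a uniform generator prior.
* **Model recovery** (`model_recovery()`): same logic on predictive
  accuracy, with accuracy summed over each virtual subject's repeats
  before the argmin; ties split uniformly.
* **Parameter recovery** (`parameter_recovery()`): generating parameters
  drawn per simulated dataset, the same model refitted, and
  fitted-vs-generating correlations computed within virtual subject and
  averaged. The desk scale is 50 subjects x 20 draws (the study scale of
  200 x 100 is reachable by changing two arguments).
* **Power** (`power_analysis()`): frequency of significant two-sample
  t tests on the fitted perceptual parameter across simulated two-group
  experiments. The group effect size is a required input - it is a
  property of a particular cohort, not of the models.

What these simulations do *not* establish: the generator shares the
perceptual models with the fitted agents, its noise enters the belief (one
of several defensible readings), and real raters exhibit slow drifts,
lapses and item idiosyncrasies that the agents lack. Passing recoveries
therefore certify the pipeline's internal consistency at the stated
conditions, not performance on any empirical dataset. Under these
conditions the recovery ordering is stable (HGF-item clearly best, KF
$\omega$ near zero because the gain depends on $\pi$ and $\omega$ only
through their product), but the absolute correlation level is sensitive to
the generator's noise magnitude, which real data do not pin down.

## Model selection and averaging

`rfx_bms()` implements random-effects BMS: model identity is a random
effect across subjects, with a Dirichlet prior ($\alpha_0 = 1$ per model)
over population model frequencies updated by the standard variational
iteration (tolerance $10^{-6}$). Exceedance probabilities come from
Monte-Carlo sampling of the posterior Dirichlet ($10^6$ draws, seeded);
the Bayesian omnibus risk (BOR) compares the free energy of the
random-effects model against the equal-frequency null; protected
exceedance probabilities follow the identity
$\mathrm{PXP} = \mathrm{XP}\,(1 - \mathrm{BOR}) + \mathrm{BOR}/K$, which
the implementation satisfies to machine precision. `family_bms()` pools
log evidence within families by log-sum-exp minus log family size (uniform
within-family prior); `between_group_bms()` compares the pooled
random-effects account of several groups against group-specific ones,
returning the posterior probability of a shared frequency profile at equal
prior odds. `bma()` averages subject-level parameters across a family,
weighted by the subject's within-group model posteriors.

## Modulators for connectivity modelling

`build_modulators()` exports the two modulatory inputs for any
effective-connectivity backend as a BIDS-style events table: a boxcar over
all no-think trials whose height is the combined belief, and a boxcar
restricted to intrusion trials whose height is the positive prediction
error (PE+; non-intrusion trials carry no reactive demand and are
excluded). Heights are neither orthogonalised nor mean-centred by default
(a flag exists). The boxcar duration defaults to the 3-s cue presentation;
setting it to 0 yields stick functions. Numeric columns round-trip through
TSV at 15 significant digits.

## Imbalance geometry and group statistics

Predictive and reactive coupling parameters (negative = inhibitory
top-down modulation) are projected onto orthogonal axes of a circular
space whose 0-degree reference sits at the bottom of the y-axis:
negative predictive coupling points at +45 deg, negative reactive at -45
deg (their positive counterparts at the opposite directions). The
imbalance angle is the direction of the resultant vector, computed with
the two-argument arctangent - the printed single-argument form is
quadrant-ambiguous, and the two-argument convention is the only one that
makes predictive dominance strictly positive. Perfect balance is 0
degrees; +45 is purely predictive control.

Group means use the circular mean (resultant direction of unit vectors)
with a percentile bootstrap CI computed on wrapped deviations from the
observed mean, so intervals behave across the +/-180 discontinuity. Group
comparisons use Watson's two-sample $U^2$ with a seeded permutation
p-value ($10^4$ label permutations), which is rotation-invariant by
construction.

`coupling_contrasts()` runs the four one-tailed effect families
(control-by-group interactions against a designated case group;
within-group predictive-minus-reactive effects; negative reactive
coupling; negative predictive coupling) with Benjamini-Hochberg FDR within
each family, 2000-resample bootstrap CIs, a bootstrap posterior
probability that the group mean differs from zero, and a ROPE Bayes
factor: posterior draws of Cohen's d from the noninformative normal model
(90,000 draws) against a Cauchy$(0, \sqrt2/2)$ prior, with the region of
practical equivalence $|d| < 0.1$; the reported factor is prior-to-
posterior ROPE mass, so large values favour a real effect. Symptom
analyses use Spearman correlations with joint-subject bootstrap CIs,
subscales residualised on total symptom severity within group
(`adjust_for_severity()`), and bootstrap tests of dependent or independent
correlation differences (90% CIs, normal-approximation Z).

## Numerical choices and degenerate inputs

* Beliefs and outcomes clamp at $\varepsilon = 10^{-4}$; $\mu_2$ clamps at
  $\pm 36$ inside the sigmoid so first-level precisions stay finite.
* The variational BMS update stops at $10^{-6}$ on the concentration
  parameters and refuses non-finite evidence.
* A zero resultant vector has no direction: the subject is flagged NA with
  a warning rather than silently assigned an angle.
* Ties: the argmax response rule resolves to "no intrusion"; accuracy ties
  in model recovery split uniformly; suppression-tuning ties take the
  smallest factor.
* Sub-seeds for nested simulation loops derive deterministically from the
  master seed and stay below $2^{31}$.

## Problem sizes

The packaged defaults run the validation suite at a desk scale chosen to
keep a full check of the pipeline in the tens of minutes on a single core:
falsification at 50 virtual subjects x 20 repeats, parameter recovery at
50 subjects x 20 draws, suppression tuning at 20 agents per grid value.
The study-scale equivalents (200 x 100) are plain argument changes.

## Known limitations

* The deposited cohort data (per-subject coupling parameters and clinical
  scores) are not bundled; `read_coupling_table()` loads them once
  downloaded, and the deposited-data checks fail visibly in their absence
  rather than being skipped.
* The generator's belief-noise magnitude is a calibrated constant; the
  absolute size of recovery correlations moves with it (their ordering
  does not).
* DCM inversion itself (neural/hemodynamic state equations, variational
  Laplace over fMRI data) is out of scope; the package constructs the
  modulator inputs and consumes the resulting coupling parameters.
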