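---
title: "Modeling decision-making under uncertainty and its relation to delusional thinking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling decision-making under uncertainty and its relation to delusional thinking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volbandit)
```

## What this package models

Several aspects of decision-making under uncertainty have been linked to
delusional thinking: a self-reported tendency to jump to conclusions
(JTC), poor integration of disconfirmatory evidence (BADE), excessive
switching after rewards in probabilistic reversal learning, and elevated
random exploration in explore/exploit dilemmas. `volbandit` implements
the full computational chain needed to study these links in simulation:
generative models of the two tasks, the two learning models fit to them,
the descriptive and questionnaire metrics, a synthetic-cohort generator
with planted symptom effects, and the regression stage that relates
everything to paranoia and delusional-ideation scales.

Everything runs on synthetic cohorts with known ground truth, so each
stage of the chain can be validated: the simulators against the task
designs, the fitters against parameter recovery, and the regression
stage against planted effects.

## The reversal-learning task and the HGF

In the three-option probabilistic reversal learning task (3PRL), decks
win with probabilities 0.9/0.5/0.1 for the first two 40-trial blocks and
0.8/0.4/0.2 for the last two; the switch is unsignalled. Whenever the
participant picks the best deck on 9 of the last 10 trials, the best
deck covertly moves to one of the other two (`prl_config()`,
`simulate_prl()`). Two design points were genuinely open and are resolved
as follows: the rolling choice window resets after each reversal (so a
reversal cannot immediately chain into another), and the contingency
transition neither resets the window nor re-randomizes the deck
assignment -- it only swaps the probability values, preserving each
deck's rank, because the transition is presented to participants as
nothing at all.

Learning on this task is modeled with a three-level Hierarchical
Gaussian Filter (HGF) in a multi-arm bandit configuration
(`hgf_params()`, `hgf_forward()`): each deck has its own level-2
stimulus--outcome tendency on the logit scale, and a single level-3
state tracks the log-volatility of the environment, shared across decks.
On each trial the chosen deck's level-2 belief receives the standard
binary-HGF variational update; the unchosen decks receive only the
prediction step (autoregressive drift toward an attractor plus variance
inflation); level 3 is updated from the chosen deck's volatility
prediction error. Parameters:

* `omega2` -- tonic log-volatility at level 2 (baseline learning step),
* `kappa` -- coupling of the volatility estimate into level-2 updates,
* `omega3` -- meta-volatility (how fast volatility beliefs move),
* `mu3_0` -- the prior belief about volatility, the quantity of primary
  clinical interest: a high `mu3_0` agent expects contingencies to shift
  erratically, switches more after wins, and abandons losing decks
  faster.

The response model is a softmax over the decks' predicted win
probabilities with inverse temperature $\beta_t = \beta_0
e^{-\hat\mu_{3,t}}$: the more volatile the agent believes the world to
be, the noisier its choices. Coupling $\beta$ to the trial-wise
volatility estimate is the default; a `beta_coupling = "prior"` switch
fixes it at $\beta_0 e^{-\mu_3^0}$ instead, because the verbal
description of the original analysis is ambiguous between the two.

Two configuration constants deserve justification. We set $\beta_0 = 5$
and the autoregressive rates $\phi_2 = \phi_3 = 0.05$. These were chosen
by forward simulation before any acceptance testing: with $\beta_0 = 1$
an agent with a weak volatility prior chooses almost uniformly, which is
neither realistic task behavior (simulated best-deck accuracy collapses
toward chance) nor compatible with identifying the learning parameters;
with $\beta_0 = 5$ simulated accuracy spans roughly 0.4--0.6 against a
1/3 chance floor, in the range real participants produce, and `omega2`
becomes identifiable. A strong drift ($\phi = 0.1$) erases belief
differences quickly and similarly masks `omega2`; 0.05 keeps the
autoregressive character with a gentler pull.

### Fitting and recoverability

`hgf_fit()` computes MAP estimates of (`omega2`, `omega3`, `log kappa`,
`mu3_0`) under weakly-informative Gaussian priors by multi-start
Nelder-Mead; the remaining parameters stay at their configured values.
Fit quality is summarized by BIC. `fit_hgf()` follows the convention of
fitting the two contingency regimes (blocks 1--2 and 3--4) separately.
`hgf_recovery()` is the recoverability suite: simulate agents from a
plausible grid (`omega2` in [-4.5, -1.5], `omega3` in [-7, -4], `kappa`
in [0.5, 1.5], `mu3_0` in [-3.5, -0.5]), refit, and tabulate
true-versus-recovered correlations. At 160 trials, `omega2` recovers at
about $r = 0.75$ and `omega3` essentially not at all ($r \approx 0$) --
the latter replicating the known weak recoverability of third-level
volatility parameters at session length. One caveat cuts the other way:
because our response model couples the inverse temperature directly to
the volatility belief, `mu3_0` leaves a strong signature in choice
stochasticity and recovers well here ($r > 0.9$), more strongly than
reported for toolbox configurations in which the coupling is less
direct. Conclusions about `mu3_0` recovery therefore depend on the
response model, and passing recovery in this configuration does not
certify the parameter in others.

## The Horizon task and the Kalman/logistic model

`horizon_config()` and `horizon_games()` generate 80 games of the
Horizon explore/exploit task: two slot machines with Gaussian rewards
(common SD 8 points), four forced choices per game in an equal `[2 2]`
or unequal `[1 3]` pattern, then 1 (H1) or 6 (H6) free choices. The
horizon-by-information cells are exactly balanced (20 games each), the
generative mean difference is drawn from a symmetric grid over
[-30, +30] points (step 2), and the reference level is 50 points. The
grid, step, SD and baseline are configuration entries because the
administered task prints the range but not the exact set.

The learning model (`kalman_update()`, `learning_rate_sequence()`) is a
Kalman filter on each machine's mean reward with learning rates that
decay from `alpha1` toward the asymptote
$\alpha_\infty = \tfrac12(-\alpha_d + \sqrt{\alpha_d^2 + 4\alpha_d})$,
where $\alpha_d$ encodes the believed drift of the means. The decision
model (`horizon_choice_prob()`) is the logistic rule
$p(\text{right}) = 1/(1 + e^{(\Delta R + A \Delta I + B)/\sigma})$ with
$\Delta R = R_\text{left} - R_\text{right}$, information differential
$\Delta I$, information bonus $A$, spatial bias $B$, and decision noise
$\sigma$. The printed orientation is implemented exactly as written; it
satisfies the dominance property (a much better right machine drives
$p(\text{right}) \to 1$), so no internal re-orientation was needed. Only
the first free (fifth) choice of each game enters the likelihood; later
H6 choices are simulated but not fit.

`fit_horizon()` estimates, per subject, `R0`, `alpha1`, `alpha_inf`, and
per-horizon `A` and `B` plus per-horizon-and-condition `sigma`. The
default route is full hierarchical Bayes by MCMC (JAGS): subject-level
parameters are drawn from group-level Gaussians (Beta distributions for
the learning rates) with weakly-informative hyperpriors, and posterior
means are the point estimates; effective sample sizes are reported and
a warning is raised below 50. A per-subject MAP route with one
empirical-Bayes shrinkage pass (`method = "map"`) exists for small
cohorts and quick tests. Random exploration is `sigma_H6 - sigma_H1`
per information condition and directed exploration is `A_H6 - A_H1`
(`exploration_contrasts()`).

`horizon_recovery()` simulates cohorts from trait grids chosen to match
the spread seen in Horizon-task samples (see the function documentation)
with decision noise treated as a horizon-level trait, and scores
recovered noise at the horizon level by averaging the two condition
estimates on the log scale. At 40 subjects by 80 games the decision
noises recover at roughly $r = 0.83$--$0.88$. The H6 information bonus
is intrinsically harder: only the 20 unequal-information H6 games carry
any information about it, giving a Fisher-information standard error
near 7 points against a population spread of 10, an attenuation ceiling
around $r = 0.8$ before learning-parameter uncertainty is added.
Observed recovery hovers near 0.6--0.7 and should be read with that
ceiling in mind.

## Metrics

`win_switch_rate()` and `lose_stay_rate()` count transitions on
consecutive trials (the last trial contributes none; block boundaries do
not break transitions since the task is continuous on screen) and emit
`NA`, never 0, when no qualifying trials exist. `bade_eii()` scores
evidence-integration impairment as the mean over scenarios of
(mean of the three Absurd ratings) + (mean of the two final Lure
ratings); ratings live on a 0--100 scroll-bar scale, a configuration
constant since the instrument defines anchors but not units.
`dacobs_jtc()` sums six 1--7 Likert items (the item count is an argument
because published descriptions disagree between six and seven items),
and `bcis_composite()` is self-reflectiveness minus self-certainty.
`subject_metrics()` assembles the per-subject table, propagating missing
values explicitly so the analysis stage can do model-wise complete-case
selection, mirroring the smaller Horizon-task subsample in real studies.

## Synthetic cohorts and planted effects

`generate_cohort()` creates control and patient groups whose agents play
both tasks with known parameters, plus BADE grids, questionnaire items,
and symptom scores. Symptom scores are built on a continuous latent --
paranoia driven by the volatility prior and random exploration,
delusional ideation by the JTC propensity -- then discretized and
truncated to each instrument's support (r-GPTS-b 0--40, PDI-21 0--336,
PANSS items 1--7, patients only). The truncation at the floor
deliberately produces the right-skewed, zero-inflated distributions
these instruments show in practice.

The default effect sizes (`effect_plan()`: 0.6 standardized for the
volatility prior, 0.35 for random exploration, 0.6 for JTC, with a
patient shift of 0.7 on the volatility prior and 8 points on PDI-21)
were calibrated by simulation so that a cohort of about 90 subjects
reproduces the magnitudes reported for real cohorts of this size:
regression $R^2$ in the 0.07--0.40 band, a volatility-prior/paranoia
rank correlation near 0.3--0.45, and a patient win-switch elevation of
moderate size ($d \approx 0.45$). A null plan (`null_effect_plan()`)
zeroes every planted dependence.

What the generator does *not* emulate: item-level psychometrics (factor
structure, reverse keying), missing-data mechanisms, practice and
fatigue effects, and any dependence of symptoms on parameters beyond
the planted linear-latent form. Passing tests on these cohorts
therefore validates the pipeline's machinery -- not the claim that real
symptom scales relate to real task behavior.

## The statistical stage

`run_analysis()` reproduces the full analysis plan on a metrics table:
Mann-Whitney group tests per metric; zero-order Spearman correlations
(overall and per group, uncorrected, with an optional
Benjamini-Hochberg column); and eight regression cells -- four outcomes
(clinician-rated suspiciousness P6 and delusions P1 in patients;
self-reported paranoia r-GPTS-b and delusional ideation PDI-21 in the
whole sample) crossed with behavioral and computational predictor sets.
In each cell the outcome is residualized on its companion scale
(`residualize()`), outcome and continuous predictors pass through the
skew-minimizing log transform (`log_transform_minimizing_skew()`, a
fixed candidate family `identity` versus `log(x - min + c)` over an
offset grid, always monotone; age, gender and group are exempt), LASSO
selects predictors (`lasso_select()`), and OLS on the retained set
(`ols_fit()`) reports coefficients, p-values and $R^2$.

The LASSO penalty is chosen by seeded 10-fold cross-validation with the
one-standard-error rule by default. The min-CV rule is available via
`rule = "min"`, but the 1-SE rule is the default because the stage's
purpose is parsimonious selection and overfitting control: in planted
simulations the min-CV rule retains spurious predictors in roughly
40--50% of null cells, which would defeat the specificity question the
analysis is designed to answer, while the 1-SE rule keeps false
retention below ~10% at the cost of some power in the small patient-only
cells -- a cost that mirrors the sparse retained sets reported for
cohorts of this size. Covariates enter the LASSO like any other
predictor and can be shrunk away. Every transform descriptor, seed and
lambda is recorded in the report manifest so a run can be reproduced
exactly (`run_pipeline()` writes the whole report directory plus file
hashes).

## Problem sizes and numerical choices

The shipped validation uses the scales at which the methods are
informative while staying desk-sized: recovery at 50 subjects by 160
trials (HGF) and 40 subjects by 80 games (Horizon, 2 MCMC chains, 3000
iterations thinned by 3 after 800 warm-up), and 20 replicate cohorts of
87 subjects for the planted-effect specificity checks. Optimizer
settings: 5 Nelder-Mead restarts (first at the prior mean, others
jittered), relative tolerance 1e-6; optimizer and sampler seeds all
derive from one master seed (`derive_seed()`). Degenerate inputs are
contracts, not surprises: ill-posed HGF updates abort with the trial
index, constant controls in `residualize()` fall back to centering with
a warning, an empty LASSO retained set is a legal outcome recorded as an
intercept-only model, and rank-deficient OLS designs are rejected with
the offending columns named.

## Known limitations

* `omega3` is effectively unrecoverable at session length, and `mu3_0`
  recovery is specific to the volatility-coupled softmax used here;
  both are reported, not asserted, by the recovery suite.
* The H6 information bonus recovery sits near its design-imposed
  information ceiling (20 informative games per subject).
* The synthetic symptom model is linear in the planted latents;
  non-monotone or threshold relations would not be detected by the
  planted-effect checks.
* PANSS items are generated for patients only, so patient-cell models
  run at half the cohort size and are correspondingly unstable -- as in
  the real studies this machinery emulates.
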