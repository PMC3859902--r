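---
title: "Q-learning analysis of discrimination learning: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-learning analysis of discrimination learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdisc)
```

# The task and its structure

The package models a two-alternative instrumental discrimination task. Six
discriminative stimuli each demand either a LEFT or a RIGHT response (three
per side); a correct response delivers a distinct rewarding outcome
(`US = 1`), an incorrect one delivers nothing (`US = 0`). Contingencies are
fixed for the whole session. A session is 96 trials in 8 blocks of 12; every
stimulus appears exactly twice per block, in an independently randomized
order per block.

Two structural choices were genuinely open and are resolved as follows:

* **Counterbalancing.** Which labels serve as stimuli vs outcomes, and which
  stimuli reward LEFT, is randomized per subject via the seed of
  `make_contingency()`. A Latin-square scheme would also be defensible; the
  per-subject random bijection is simpler and has the same marginal property
  (over seeds, each stimulus is assigned LEFT about half the time, which the
  test suite checks).
* **Block randomization.** Each block's 12 slots are an independent uniform
  permutation. `validate_schedule()` checks the invariants (96 trials, block
  arithmetic, twice-per-block counts) on any schedule, generated or imported.

# The learning model

One weight `W` is kept per (stimulus, response) pair — 12 in total — because
the subject's decision is LEFT vs RIGHT *given* a stimulus. After each
choice only the chosen pair's weight moves, by the delta rule
`W <- W + alpha * (US - W)` with learning rate `alpha` in `[0, 1]`. Since
`US` and the initial weights lie in `[0, 1]`, the update is a convex
combination and weights can never leave `[0, 1]`.

Choice is a softmax over the two weights of the presented stimulus with
inverse-gain parameter `beta`:
`P(LEFT) = exp(W_L/beta) / (exp(W_L/beta) + exp(W_R/beta))`. `beta` has the
units of the weights (dimensionless here); because weight differences are
bounded by 1, `beta = 0.1` already produces near-deterministic choice while
`beta = 1` caps the per-trial choice probability at about
`plogis(1) = 0.73`.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `alpha` | — | fitted / sampled | fraction of the prediction error applied per trial |
| `beta` | — | fitted / sampled | softmax inverse gain; exploration–exploitation balance |
| `w_init` | — | 0.5 | midpoint of the feedback range: first choices are 50/50 and negative feedback is informative from trial 1 |
| grid step | — | 0.01 | exhaustive ML search over `alpha` 0–1, `beta` 0.01–1 |

`w_init` must be shared between the generator and the fitter. With a
symmetric initialization the `alpha = 0` grid point reproduces the random
responder exactly (every choice probability is 0.5), which guarantees the
fitted log likelihood is at least `96 * log(0.5)` and hence that the
pseudo-R² is never negative.

## Numerical choices

* The softmax is evaluated as a logistic of the weight difference
  (`plogis((W_L - W_R)/beta)`), which is the log-sum-exp-stabilized form for
  two options; likelihoods are accumulated in log space
  (`plogis(..., log.p = TRUE)`).
* The `beta` grid starts at 0.01, not 0: a zero-temperature softmax assigns
  probability 0 to any observed choice of the lower-weighted option, making
  the log likelihood `-Inf`. The learning-rate grid does include 0.
* Exact likelihood ties on the grid (which occur, e.g., on the `alpha = 0`
  line, where `beta` is unidentified) are broken deterministically in favor
  of the smallest `beta`, then the smallest `alpha`.
* The grid search is exact, not approximate: for a fixed session the weight
  trajectory depends only on `alpha`, so the implementation replays the
  session once per `alpha` value (vectorized across the whole `alpha` grid)
  and evaluates all `beta` columns from the stored per-trial weight
  differences. `session_loglik()` is the simple scalar reference
  implementation; the test suite holds the two routes together and checks
  both against an independent brute-force oracle on enumerated short
  sessions.

## The pseudo-R² sign convention

The conventional comparison statistic against the chance model with
`r = n * log(0.5)` is reported as `1 - LLE/r` (the McFadden form): 0 at
chance, 1 for perfect prediction, positive whenever the model beats chance.
The raw ratio `(LLE - r)/r` is *negative* for better-than-chance fits, which
contradicts how positive published values of this statistic are read;
`pseudo_r2()` therefore uses the McFadden form, which has the same magnitude
and the interpretable sign.

# The synthetic cohort generator

`cohort_spec()` defaults describe the study conditions the package emulates:
11 controls and 17 patients, generating parameters drawn per group from
normal distributions with means (SD) of 0.217 (0.036) / 0.70 (0.26) for
controls and 0.163 (0.041) / 0.85 (0.30) for patients, truncated to the
fitting grid's support (`alpha` to `[0, 1]`, `beta` to `(0, 1]`). Normality
is an assumption of the generator — group summaries alone do not determine a
distribution — and truncation at these means/SDs shifts the means by well
under 0.01 (a large-sample test verifies this).

Clinical covariates (disease duration, Hoehn & Yahr stage, UPDRS III, daily
dopamine-dose equivalent, BDI) are sampled for patients as independent
truncated normals at reference patient summary statistics, deliberately
**uncoupled** from `alpha`: they exist so the covariate screen has a true
null to find.

Regional gray-matter values use a single-latent-driver structure on the
standardized scale: `vmPFC = roi_effect * z(alpha) + noise`, and each
bystander region (`rIFG`, `NAcc`) equals
`roi_cross_corr * vmPFC + noise`, rescaled to density-like units
(mean 0.5, SD 0.05). Defaults `roi_effect = 0.6` and `roi_cross_corr = 0.5`
give the driver a strong but not certain detection probability at n = 17 and
give bystanders an indirect association of about 0.3 that should die under
partialling. This is a deliberate abstraction: it gives the
partial-correlation analysis a recoverable ground truth, and it makes no
claim about how ROI values would be extracted from real images (voxelwise
morphometry pipelines are out of scope entirely).

What the generator does *not* emulate about real data: reaction times,
lapses and perseveration, medication state, explicit-knowledge strategies,
and any non-Q-learning structure in real choice sequences. Passing tests
therefore certify the pipeline's internal correctness and its behavior on
model-consistent data, not the adequacy of the Q-learning model for any real
cohort.

# Statistical analyses

Group contrasts default to a two-sided permutation test on the difference of
group means (10,000 seeded label shuffles, implemented vectorized), the
distribution-free choice for n = 11 vs 17; Welch's t and Mann–Whitney are
available for parity with standard toolboxes. Repeated-measures ANOVA
machinery (sphericity tests and corrections) is intentionally not provided;
`group_report()` instead contrasts each block's accuracy with a Bonferroni
factor of 8 alongside the three main measures.

The brain–behavior stage computes, per region, the Pearson correlation with
a per-subject measure (permutation p by shuffling the measure) and the
partial correlation controlling for the other regions by the residual
method: both the target region and the measure are regressed on the controls
(least squares with intercept) and the residuals correlated, with
permutation inference on the measure residuals. At these dimensions the
residual method is algebraically identical to the inverse-correlation-matrix
formula. Controls with a condition number above `kappa_max` (default 1e8),
or a target that is an exact linear function of the controls, are flagged
`collinear` rather than computed.

# Identifiability and known limitations

The central caveat for users is the shape of the (alpha, beta) likelihood
surface on 96 trials. The two parameters trade off along a ridge — slower
learning with a sharper softmax mimics faster learning with a flatter one —
and the ridge supports two modes: one near the generating values and one in
the small-`alpha`/small-`beta` "exploitative" corner that explains the same
data as slow weight drift with near-deterministic choice. Single-subject
grid-ML estimates are therefore noisy and their *distribution across
subjects is bimodal*: in the package's own recovery experiments the median
recovered `alpha` sits essentially on the generating value while the mean is
pulled upward by the corner mode and the `alpha = 1` tail, and mean
recovered `beta` is pulled downward. An independently written reference
implementation reproduces this behavior exactly, so it is a property of
maximum likelihood on this task length, not of the code. Consequences:

* Mean recovered parameters over simulated cohorts can sit outside a
  ±0.05/±0.10 band around the generating values even with hundreds of
  subjects; medians and rank statistics are far better behaved.
* Group contrasts on *recovered* learning rates at realistic group sizes
  (11 vs 17) are underpowered when the generating group difference (0.054)
  is small relative to per-subject estimator noise; contrasts on generating
  parameters separate cleanly. Users comparing groups on fitted parameters
  should expect this attenuation, which hierarchical (empirical-Bayes)
  estimators are designed to address — such estimators are deliberately out
  of scope here.

Problem sizes used by the test suite and acceptance script — 200 sessions
per recovery arm, 200 seeded cohorts for contrast/association patterns, 500
random-responder fits, 10,000 schedule seeds for uniformity checks — were
chosen as the smallest runs whose Monte Carlo error is negligible relative
to the assertions made about them.

# Degenerate inputs and edge behavior

* `beta <= 0` is rejected everywhere (generator and fitter).
* Sessions with unknown stimuli, non-LEFT/RIGHT responses, or non-binary
  feedback raise structured errors naming the offending trial.
* A one-trial session has a completely flat likelihood surface; the
  tie-break returns `(alpha = 0, beta = 0.01)`.
* `alpha_sd = 0` / `beta_sd = 0` cohort specs produce identical parameters
  within group; constant covariates are flagged in the screen rather than
  correlated.
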