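---
title: "Modeling probabilistic inferences with PCS networks and MM-ML strategy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling probabilistic inferences with PCS networks and MM-ML strategy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsdm)
```

## The task environment

A probabilistic inference task asks which of two options is better on an
unobservable criterion, given four binary cue predictions (+1 favors, −1
disfavors) whose validities — the proportion of past predictions that came
true — are displayed explicitly. Chance level is .50 for a binary choice,
so only validities strictly inside (.5, 1) carry information, and
`make_task()` enforces this along with descending validity order. Tasks in
which one option weakly dominates the other (at least as good on every cue)
are trivial and are excluded by the generator, as are duplicates and tasks
on which the naïve Bayesian posteriors tie, so that scoring against the
rational benchmark is defined on every task.

`generate_task_set()` samples validities uniformly and cue values as fair
coins. The sampling distribution of validities is not dictated by the task
format; the default range (.60, .94) spans the printed example tasks and is
a parameter, not an estimate.

## The PCS network

The network couples a clamped driver node, four cue nodes and two option
nodes with symmetric links. Driver→cue weights are chance-corrected
validities raised to the sensitivity parameter $P$:
$w_{v_i} = (v_i - .5)^P$. The exponent reparameterizes the weighting
policy continuously: $P = 1$ weights linearly, $P < 1$ compresses validity
differences toward equal (compensatory) weighting, $P > 1$ amplifies them
toward lexicographic (non-compensatory) behavior, since the weight ratio
$((v_1-.5)/(v_2-.5))^P$ is strictly increasing in $P$.

Updating is synchronous interactive activation: every non-driver node
receives the weighted sum of its neighbours' activations and moves toward
the ceiling ($a_{max}$) for positive input or the floor ($a_{min}$) for
negative input, with multiplicative decay. The defaults are the published
values of this model family — decay .05, floor −1, ceiling 1, cue–option
magnitude .01, option–option inhibition −.2 — and every constant is a
`pcs_constants()` field, so alternative parameterizations reproduce their
own iteration counts bit for bit.

Three numerical choices deserve note:

- **Stopping rule.** "Until convergence" is operationalized as every
  node changing less than 1e−6 for 10 consecutive iterations, with a hard
  cap of 3000. Both threshold and window are configuration keys because
  the reported time prediction *is* the iteration count.
- **Iteration convention.** The count can be read at the first stable
  iteration (default) or at the end of the stability window
  (`iteration_convention = "window_end"`); the two differ by a constant
  (window − 1), which the contrast transform removes anyway.
- **Ties.** Exact activation ties at convergence yield a "random" choice
  prediction, which enters likelihoods at probability .5 and is excluded
  from adherence denominators, mirroring the treatment of heuristic ties.

The dynamics are checked in the test suite against an independent
straight-line implementation of the same recursion (node-by-node loops, no
shared code) to 1e−10, and for exact mirror symmetry: swapping the option
columns must swap the option activations bit for bit.

With these defaults the option activations settle around ±.75, so the
activation difference spans roughly [0, 1.6] and the determinism parameter
$\lambda \in [0, 5]$ covers choice probabilities from .5 up to
$\approx 1/(1+e^{-8})$; $\lambda$ applies to the raw difference with no
extra scaling.

## Heuristics, time predictions, and the rational benchmark

TTB inspects cues in validity order and decides by the first
discriminating one (confidence = its validity); EQW compares unweighted
cue sums; WADD_c compares sums weighted by $(v_i - .5)$. Serial strategies
predict decision time by elementary-information-process (EIP) counts: 3
per cue examined for TTB (two reads, one comparison), constants 15 and 23
for EQW and WADD_c. The literature names the construct but not one
canonical count; any strictly monotone recount yields the same contrast
vector up to a positive affine transform for TTB and identically zero
contrasts for the constant-time strategies, and the classification
machinery is invariant to exactly those transforms — so the choice of
scheme cannot affect classifications.

The naïve Bayesian solution multiplies validity likelihood ratios
$v/(1-v)$ over discriminating cues (independence, equal priors); it
defines the performance benchmark and the participant-level exclusion
criterion.

## MM-ML classification

For a strategy $s$ with per-task predictions, the participant's data
vector — 60 choices, 60 preprocessed ln decision times, 60 confidences —
has log-likelihood

$$\log L_s = \log L_{choice} + \log L_{time} + \log L_{conf}.$$

Choices are Bernoulli: deterministic strategies use a constant error rate
$\varepsilon$ (MLE: observed error proportion on non-random trials, capped
at .5 so a strategy cannot gain from systematic anti-adherence);
`PCS_fitted` uses the logistic rule in the signed activation difference.
Times and confidences are Gaussian around an intercept plus a slope on the
strategy's contrast predictions (raw predictions mapped to zero-sum,
range-one contrasts). Slopes are constrained non-negative — a strategy
must not profit from *anti*-correlated process predictions — and
collapse to intercept-only models when the contrast is constant (the
EQW/WADD_c time case). Variances are ML estimates floored at 1e−6 so
noise-free data remain finite.

Model selection is by BIC $= -2\log L + k\ln n$ with $n$ the number of
scalar observations entering the likelihood (180 minus censored trials).
Parameter counts are a fixed, documented convention: 1 (ε) + 3 + 3 = 7 for
the deterministic strategies and `PCS_fix`, and 9 for `PCS_fitted`, whose
choice component carries λ plus the two grid-search dimensions. The counts
are per-measure, so subset-measure classification (e.g. choice-only)
penalizes coherently. BIC ties break toward fewer parameters, then
alphabetically.

The grid search evaluates all 51 × 51 combinations of $P, \lambda \in
[0, 5]$ in steps of .1. Network predictions depend on $P$ only, so
`pcs_grid_predictions()` caches one prediction table per $P$ for a task
set, and the per-participant search reduces to closed-form Gaussian fits
per $P$ plus a vectorized logistic profile over $\lambda$. Likelihood ties
break toward the smallest $P$, then the smallest $\lambda$. The
preregistered-style restricted range $P \in [1, 2]$ is available by
passing a narrower `P_grid`; with generating values outside the range, fits
pile onto the corner, which the tests reproduce.

**Saturated-model check.** The winner's choice component is compared by a
likelihood-ratio $G^2$ against a saturated model with one free choice
probability per distinct cue pattern, on a $\chi^2$ with (patterns −
choice parameters) degrees of freedom. Trials on which the winner predicts
random choice are excluded here, as in adherence: a perfectly conforming
agent still flips a fair coin on those trials, and including them would
attribute coin-flip entropy to model misfit.

**Cross-validation.** `crossval_classify()` partitions the 60 tasks into
six seeded folds, refits all parameters (including the grid) on five folds
and accumulates the held-out log-likelihood; the winner is the largest
summed out-of-sample score, with no BIC penalty since nothing is fit to
the held-out data. One estimator detail: a boundary estimate
$\hat\varepsilon = 0$ would score $-\infty$ on a single unseen mismatch,
which falsifies the generating strategy for an appreciable share of
low-noise agents. Held-out scoring therefore floors the error rate at
$0.5/n_{train}^2$ — half a pseudo-mismatch spread over the training
trials — a vanishing smoothing that keeps scores finite while leaving the
noise-free limit intact (a fixed $0.5/n$ floor is *not* used: with no
parsimony penalty its cost exceeds the logistic rule's near-deterministic
tail and flips noise-free fixed-network agents to the fitted variant).

## The synthetic-data generator

`agent_spec()` + `simulate_participant()` invert the MM-ML measurement
model: choices are the strategy's predictions flipped with probability ε
(or logistic draws for `PCS_fitted`; fair coins on random-prediction
trials), ln decision times are Gaussian around an intercept plus slope on
the time contrast, confidences likewise on the 50–100 slider scale with
censoring at the bounds (clipping, mirroring a slider's response floor and
ceiling). Defaults encode the two-condition study structure the pipeline
targets: intuition ln-times center at ln 5583 ms with a deliberation shift
of ln(9241/5583); slopes default to 0.48 ln-units and 10.69 slider points
per unit contrast (the magnitudes of the reported mixed-model
coefficients); deliberation halves the choice error rate (default ε = .08
→ .04) and PCS agents default to sensitivity 1.70 (intuition) vs 1.97
(deliberation). Residual SDs (.35 ln-units, 10 slider points) are
conventions chosen as realistic for self-paced decision data, not
estimates. `study_spec()` defaults to 67 + 61 participants, 60 tasks, and
a mixture dominated by the PCS variants (.59 combined) with .28
weighted-additive and .13 simple heuristics.

Strategy labels are allocated by largest-remainder rounding by default, so
a mixture reproduces its own label counts exactly — convenient for
benchmarks. For calibration studies of between-condition tests this is the
wrong regime (deterministic labels leave no sampling variability under the
null), so `allocation = "multinomial"` draws labels independently; the
type-I-error check of the distribution chi-square runs under that setting
and rejects at ≈5% across 200 replicate studies of 10 + 10 participants.

What the generator does *not* emulate: within-participant strategy
switching, fatigue or learning beyond a linear ln-time drift, slider
rounding habits, response-time distributions beyond the lognormal, or
correlated residuals between time and confidence. Passing recovery tests
therefore shows the estimator works when its assumptions hold — it does
not certify those assumptions for real data.

## The analysis pipeline

`run_study_report()` chains: participant exclusion below 55%
Bayes-consistent choices; censoring of decision times above 60 s and
beyond 3 SD from the grand mean (on the ln scale by default, matching the
downstream ln analyses; the raw scale is an option since the convention is
not fixed by the format); per-participant ln-transform with linear
trial-order partialing; BIC and (optionally) cross-validated
classification with the grid cache shared across participants; adherence
and correlation tables (individual Pearson correlations averaged by
Fisher z; zero-variance contrasts reported as exactly 0); performance
against the naïve Bayes benchmark; and the per-condition comparison of the
fitted sensitivity parameter (Wilcoxon rank-sum) plus a chi-square test of
the winner distribution across conditions, dropping strategies nobody was
assigned to. Mixed-effects interaction models are deliberately out of
scope; the pipeline reports per-participant correlation summaries and the
trial table can be exported for external mixed-model fitting.

Trial-level censoring applies to the time measure only (choices and
confidences are retained), and the BIC observation count shrinks
accordingly. Exclusion accounting (kept + excluded = input, at both
levels) is asserted in the tests.

## Problem sizes and reproducibility

Everything is seeded: task generation, agent simulation, fold assignment,
and study allocation; per-participant seeds derive from the study's master
seed, so reports regenerate bit for bit. The test suite's benchmarks use
one shared 60-task set and grid cache: 100 agents (20 per strategy, ε =
.05, σ = .1) for strategy recovery with ≥90% required accuracy; 20 seeds
per generating value for parameter recovery with a ±0.3 median error
bound on $P$; 15 agents for CV/BIC agreement (≥80%); 200 reduced-size
replicate studies for chi-square calibration. `scripts/acceptance.R`
additionally simulates a full 128-participant study through the complete
pipeline with cross-validation.

## Known limitations

- The network constants are the model family's published defaults, not
  fitted; groups using other parameterizations must set `pcs_constants()`
  accordingly, and iteration counts are only comparable within one
  configuration.
- The BIC parameter-count convention (7/7/9) is one defensible choice
  among several in the multiple-measure literature; it is configurable in
  effect via the measure subset but not per-strategy.
- Choice-only classification cannot reliably separate WADD_c from the PCS
  variants (their choice predictions largely coincide); the tests assert
  this degradation rather than hide it. Conclusions about those
  strategies should rest on the three-measure classification.
- The grid's resolution (.1) lower-bounds the achievable parameter
  precision, and λ estimates are weakly identified when activation
  differences are uniformly large (most choice probabilities saturate).
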