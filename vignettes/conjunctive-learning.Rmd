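---
title: "Learning values over conjunctions: models, pattern analyses and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning values over conjunctions: models, pattern analyses and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjrl)
```

## The scientific problem

When outcomes depend on *combinations* of stimulus features rather than on
the features themselves, feature-based reinforcement learning fails. The
task this package models makes that failure precise: four compound stimuli
built from three features — AB, AC, B and C — predict a "go" target with
probability 0.7 (AB, C) or 0.3 (AC, B). Every single feature predicts the
target exactly half the time, so only conjunctive representations carry
predictive information. Subjects reveal what they have learned through
reaction times: a speeded response window (calibrated so naive responding
succeeds half the time) rewards anticipation of the target, and
anticipation requires value.

`conjrl` implements the full analysis chain for this design: trial
generation, four learning models fit jointly to log reaction times,
cross-validated and Bayesian random-effects model comparison, construction
of feature and conjunctive prediction-error regressors, trial-pair
pattern-similarity regression with permutation inference, and a
localizer-template pattern-content analysis — plus generators that produce
behavior, multivoxel-like patterns, activation estimates and localizer
blocks with the statistical structure each analysis assumes.

## Learning models

All models share the delta rule

$$V(s)^{t+1} = V(s)^t + \alpha\,[R_t - V(s)^t],$$

where $R_t \in \{0,1\}$ indicates whether the target appeared and $\alpha$
is the learning rate. Values represent the association between a stimulus
and the *target*, not the monetary outcome: reward additionally depends on
whether the response beat the threshold, which is not part of the learned
contingency. The models differ only in their state space:

* **No learning** — no value regressor; log reaction times are fit by
  their mean.
* **Base rate** — a single state shared by all stimuli.
* **Feature** — one value per feature (A, B, C); a compound's value is the
  sum of its features' values ($V(AB) = V(A) + V(B)$) and each present
  feature receives the full $\alpha\,\delta$ update (no division by the
  number of features).
* **Conjunctive** — one value per stimulus; only the presented stimulus
  updates.
* **Value spread** — conjunctive learning in which a fraction $\omega$ of
  every update leaks to each *other* stimulus sharing a feature:
  $V(s')^{t+1} = V(s')^t + \alpha\,[R_t - V(s)^t]\,\omega\,O(s,s')$ for
  all $s' \neq s$, with $O$ the feature-overlap indicator. Overlap pairs
  are (AB, AC), (AB, B) and (AC, C); spreading crosses target classes (an
  AB trial updates both AC and B). With $\omega = 0$ the model reproduces
  the conjunctive trace exactly — a nesting the tests exploit.

Values are *not* clipped to $[0,1]$ for the feature and value-spread
models; the dynamics are left exactly as the update equations state.
Because the category-to-feature mappings change between runs, the state is
re-initialized to $v_0$ (default 0) at every run boundary; a no-reset
option exists for sensitivity analyses, and $v_0$ can be freed as a fitted
parameter bounded to $[0,1]$.

## Fitting and model comparison

Log reaction times on responded trials are modeled as Gaussian around
$\beta_0 + \beta_1 v_t$:

$$\mathrm{LL} = n \log\!\frac{1}{\sqrt{2\pi}\,\sigma}
  - \frac{1}{2\sigma^2} \sum_t \big(rt^t - \textstyle\sum_k \beta_k
  V^t_k\big)^2 .$$

Only trials with a response enter the likelihood (misses have no reaction
time); this inclusion rule is configurable. For any candidate
$(\alpha, \omega, v_0)$ the weights $\beta$ and the residual SD $\sigma$
have closed-form maximum-likelihood values (ordinary least squares and the
root-mean-square residual), so they are profiled out and the learning
parameters are optimized by bounded L-BFGS-B from 20 seeded restarts
(defaults; ties broken by first occurrence). $\sigma$ is floored at
$10^{-4}$ log-units so noiseless synthetic data cannot degenerate the
density. When the value trace is numerically constant (e.g. $\alpha = 0$
with $v_0 = 0$), the fit falls back to intercept-only rather than leaving
the slope unidentified.

Out-of-sample performance uses leave-one-run-out cross-validation:
parameters (including the profiled $\sigma$) are fit on two runs and the
held-out run is scored; the summed held-out log-likelihood is divided by
the number of included held-out trials so subjects with different response
counts are comparable. One run is the natural fold because category
mappings change between runs.

Group-level selection is random-effects Bayesian model comparison: model
frequencies get a Dirichlet prior ($\alpha_0 = 1$), a variational update
estimates the posterior, exceedance probabilities come from $10^6$
Monte-Carlo draws of the posterior Dirichlet, and the Bayesian omnibus
risk (the posterior probability that all models are equally frequent)
converts them to protected exceedance probabilities
$\mathrm{pEP}_k = \mathrm{xp}_k (1 - \mathrm{BOR}) + \mathrm{BOR}/K$,
which sum to 1 by construction. Cross-validated predictive log-likelihoods
serve as the evidence proxy. One caveat the test suite documents
explicitly: the variational frequency posterior coincides with the exact
hierarchical posterior when each subject's best model is decisive, but it
is overconfident when subject-level evidence is ambiguous and the sample
is small — a property of the standard algorithm, not of this
implementation. Pairwise comparisons use the exact Wilcoxon signed-rank
test (normal approximation beyond 25 non-zero pairs); its exact null
p-distribution is discrete and therefore conservative, which is what the
calibration test asserts.

The per-run **conjunctive-learning index** is
$\mathrm{LL}_{\text{conjunctive}} - \mathrm{LL}_{\text{value spread}}$
evaluated per run at each model's own per-subject maximum-likelihood
parameters: 0 when the fitted spread is zero and increasingly negative the
more value spreading contaminates purely conjunctive behavior. An
engagement nuisance
($\mathrm{LL}_{\text{value spread}} - \mathrm{LL}_{\text{no learning}}$)
separates index effects from overall task engagement.

## Prediction-error regressors and the striatal decomposition

The feature-model prediction-error trace and the *difference* between the
feature and conjunctive traces form two z-scored trial regressors. The
difference construction isolates variance that conjunctive learning
explains over and above feature learning and reduces the shared variance
relative to using the raw conjunctive trace; under the
conjunctive-minus-feature sign convention the residual correlation with
the feature regressor is negative. Both conventions are supported and the
choice is stamped on the output, because published descriptions of the
subtraction's direction are themselves inconsistent. Regressor parameters
default to group-median fitted learning rates, mirroring the use of
regressors identical across subjects.

Group inference on per-trial activation estimates is two-stage:
per-subject ordinary least squares on (intercept, target, feature PE,
conjunctive difference PE), then one-sample t-tests across subjects —
equivalent to a random-intercept mixed model for balanced designs. The
run-level brain-behavior coupling regresses the per-run conjunctive-PE
coefficient on the per-run pattern-overlap coefficient after
within-subject centering. With only three runs per subject the unweighted
per-subject slopes are heavy-tailed (a subject whose runs happen to have
nearly equal overlap coefficients produces a wild slope), so the reported
point estimate is the precision-weighted pooled slope while the t-test
operates on the per-subject slopes; both are returned.

## Pattern-similarity analysis

Trial-pair similarity is the Pearson correlation of the two trials'
activation patterns across units, clipped to $|r| \le 1 - 10^{-7}$ and
Fisher-transformed. The pair-level design contains: within-stimulus
similarity (1 same stimulus, else 0); overlap (+1 share a feature, −1 no
shared feature, 0 same stimulus); prediction-error and value similarity
(negated absolute differences of the trial-wise model quantities, so
positive coefficients mean similarity coding — the sign convention is
recorded); response and target nuisances (±1 codings); one same-run
indicator per run; linear and quadratic elapsed-time terms and a
time × within-stimulus interaction. Value and PE columns are residualized
against the response and target codings (shared variance goes to the
outcome nuisances), and every column is z-scored so coefficients are
comparable. All pairs, within and across runs, enter the regression; the
run and time nuisances absorb session structure.

The optional value × epoch interaction asks whether outcome-similarity
coding changes over learning. Epoch is +1 when both trials fall in the
late half of their run, −1 when both are early, 0 otherwise. Three
numerical choices matter here and are deliberate: the epoch main effect
and a within-stimulus × epoch term enter alongside the interaction
(otherwise late-versus-early mean shifts and the dominant within-stimulus
structure alias into it); the interaction is defined over between-stimulus
pairs only (same-stimulus similarity is the within-stimulus effect); and
the value code is centered within the both-early and both-late pair groups
so the column carries only the change in value-similarity *slope*.

Inference is permutation-based: the vector of pair similarities is
shuffled uniformly (10,000 times by default), the full model refit, and
one-sided p-values computed with the +1 correction,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, with
the tested direction configurable per column. A stricter trial-label
permutation mode is available. Region contrasts recompute the coefficient
difference under independent shuffles of each region's similarities.
Because coefficients are estimated by a fixed linear projection of the
similarity vector, each permutation is a matrix product; the null for
10,000 shuffles on a 7,140-pair matrix takes seconds.

## Pattern-content analysis

Category templates are the mean localizer pattern per stimulus class.
Each task trial is correlated with the template of the category playing
its *diagnostic* feature in that run — B and AB trials against B's
category, C and AC against C's — so a single-feature stimulus and its
two-feature counterpart are always scored against the same template
within a run, and condition differences reflect task representations
only. Similarity is the same clipped, Fisher-transformed correlation as
in the PSA. Condition contrasts use within-run shuffles of trial labels;
between-region differences and the region × condition interaction use
trial-wise region swaps (the trials are shared, so region assignment is
exchangeable under the null). Templates are built from all localizer
runs; a mean-pattern-removal toggle exists and defaults to off.

## The synthetic-data generators

The generators define the study conditions everything above is validated
against; their defaults are fixed, not tuning knobs.

**Behavior.** Value-spread learning with $\alpha = 0.3$ and
$\omega = 0.44$ (the mean fitted spread the design targets), log
reaction-time intercept $\log(0.4\,\mathrm{s})$, value slope $-0.4$
(higher value, faster response) and residual SD 0.15 log-units. The
response threshold is calibrated before the task in 30 ms steps on
value-free trials and tracks performance in 10 ms steps during it, so a
non-learning subject succeeds on about half of target trials. Responses
always occur on target trials; on non-target trials the probability of an
anticipatory response (a false alarm) is logistic in value,
$\mathrm{plogis}(-2 + 3v)$ — roughly 12% at $v = 0$ and 50% at
$v \approx 0.7$, matching the qualitative false-alarm gradient the design
produces. Rewards follow the payoff rule: +25¢ for a hit, −25¢ for a
false alarm, nothing otherwise. The generative rule for anticipation is a
package choice (no published generative model exists for it); its
parameters are configurable.

**Patterns.** Each trial's pattern is built from a fixed orthonormal
basis: `within_strength` (default 1) times the stimulus prototype,
`overlap_strength` (default 0.8) times the feature components — which are
the localizer-category prototypes under the run's counterbalanced
feature-to-category mapping — `value_slope` (default 0.5) times the
updated value along a value axis, plus unit Gaussian noise (`noise_sd`
0.2, `n_units` 60). Two representational modes encode the competing
hypotheses: `"additive"` builds two-feature patterns as the sum of their
feature components (the sensory-cortex prediction), `"conjunctive"` gives
them their own prototypes orthogonal to every feature component (the
pattern-separated prediction); single-feature stimuli always carry both
their prototype and their component. The defaults were chosen once to
produce effect magnitudes comparable to published pattern-similarity
analyses (within-stimulus Fisher-z around 0.1, overlap around 0.02) and
were not revisited. `epoch_mod` plants learning-related repulsion: value
coding starts on the shared axis and progressively anti-aligns the
equal-valued stimulus pairs (AB vs C, AC vs B) over the run,
norm-preserving, so the planted value × epoch interaction is negative;
values around 1.5–2 complete the anti-alignment within the run. The
localizer generator emits category prototypes plus noise, so templates
and task patterns interlock by construction.

**What the generators do not emulate:** hemodynamics, temporal
autocorrelation, scanner drift and motion, spatial noise correlations,
inter-subject variability in representational geometry, and attention
fluctuations. Passing the synthetic round trips therefore demonstrates
that the analysis chain recovers what it is designed to recover from data
with the assumed structure — not that real tissue behaves like the
generator.

## Problem sizes and numerical choices

Validation simulations use 30 subjects, 3 runs of 40 trials, 60-unit
patterns and 20-subject group similarity matrices — enough for every
planted effect to be decisively detected while the whole suite runs in a
few minutes. Degenerate inputs are handled explicitly: zero-variance
trial patterns are flagged and excluded from the similarity regression;
zero-variance regressors are rejected rather than silently z-scored;
rank-deficient designs name their collinear columns; all-zero paired
differences make the signed-rank comparison an error, not a p-value;
single-run data cannot be cross-validated. Permutation p-values are never
zero by construction. Every stochastic routine takes an explicit seed and
records it in its output.

## Limitations

Per-subject fitting only (no hierarchical shrinkage); two-stage summaries
instead of full-likelihood mixed models (exact only for balanced
designs); the evidence proxy for Bayesian model selection is the
cross-validated predictive likelihood, one of several defensible choices;
and the conjunctive index's sign convention (more negative = less purely
conjunctive) is a package decision where published descriptions are
ambiguous, stamped on all outputs.
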