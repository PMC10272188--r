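---
title: "Modelling probabilistic Go/NoGo reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probabilistic Go/NoGo reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(revlearn)
```

## The task

`revlearn` studies behavioural flexibility in a probabilistic Go/NoGo
reversal-learning task. Two tactile patterns are presented in randomized
order; for one of them the rewarded response is "Go", for the other
"NoGo", but only probabilistically: on each trial the assigned rewarded
response follows the prevailing rule with probability `p_high = 0.7` and
is inverted otherwise. At a random trial inside a window (trials 20–25 of
a 45-trial block) the rule reverses, and the learner has to notice this
from feedback alone. The default configuration — 3 runs of 4 blocks of 45
trials, 540 trials in all, with a fresh pair from 8 patterns in every
block — is what `task_config()` produces.

```{r}
cfg <- task_config()
cfg
design <- generate_design(cfg, seed = 1)
design$blocks[[1]]$reversal_trial
```

Each block is carved into four 10-trial phases used by downstream
analyses: learning-naïve (LN, the first ten trials), learning-expert (LE,
the ten trials immediately before the reversal), reversal-naïve (RN, the
first ten reversed trials) and reversal-expert (RE, the last ten of the
block). When the reversal falls at trial 20 the LN and LE windows overlap
in trial 10; the later label wins, which keeps LE (the window the
reversal analyses condition on) at exactly ten trials and leaves LN with
nine in that one case. Labelling is deterministic given the reversal
trial, so the choice is a pure convention — but it must be fixed once,
and this is the convention the whole package uses.

Two representational details matter everywhere:

* **Latent mapping, not motor response.** Agents choose between the two
  stimulus–response *mappings* (`y = 1`: stimulus 1 → Go / stimulus 2 →
  NoGo; `y = 0`: the inverse). The motor response follows from the chosen
  mapping and the stimulus on show. "Staying" in `p_staying()` means
  repeating the mapping choice, which is the quantity that is stable
  across stimulus alternation.
* **Response-independent model input.** The binary sequence `u1` the
  learning models filter encodes whether each trial's feedback is
  evidence for mapping 1. It is a function of the stimulus and the
  assigned rewarded response only (`encode_model_input()` demonstrates
  the equivalence from the observed triplet), so the perceptual input
  sequence is a property of the task, independent of behaviour — which is
  what makes Bayes-optimal perceptual parameters well defined.

## The four models

*Random responding* chooses mapping 1 with a constant bias `b`.
*Noisy win-stay-lose-switch* repeats a rewarded choice and abandons an
unrewarded one, lapsing with probability `epsilon`, so the favoured
option is taken with probability `1 - epsilon/2`. *Rescorla–Wagner*
learns a value per mapping with a fixed learning rate `alpha`, updating
only the chosen option with the binary reward, and chooses through a
softmax with inverse temperature `beta`; values reset to `V0 = 0.5` each
block. These bookkeeping choices (two options, chosen-option update) are
the conventional ones for two-alternative bandit-style analyses.

The *two-level Hierarchical Gaussian Filter* replaces the fixed learning
rate with a precision weight that evolves trial by trial. The belief
about the mapping lives on the latent scale as a Gaussian with mean `u2`;
its logistic transform `u1hat = s(u2)` predicts the next input. One
filter step computes the Bernoulli variance of the prediction
(`phi1hat`), diffuses the belief variance by `exp(omega)` (`phi2hat`),
forms the precision weight `phi2 = 1/(1/phi2hat + phi1hat)`, and moves
the belief by `phi2 * delta1`, where `delta1 = u1 - u1hat` is the outcome
prediction error. The variance of the prediction is evaluated at the
current-trial prediction `u1hat(t)`; since `u1hat(t)` is itself a
function of the previous posterior this is the internally consistent
reading of the update, and the filter is verified in the tests against an
independent straight-line transcription of the equations. The volatility
level of the full three-level filter is removed by fixing its constants
to zero — appropriate for a task whose participants are told there is
exactly one reversal per block. Responses come from the unit-square
sigmoid `p(y=1) = u1hat^zeta / (u1hat^zeta + (1-u1hat)^zeta)`; we use the
normalizing form with `(1-u1hat)` in both denominator terms throughout.
`zeta = 0` is indifference, `zeta = 1` probability matching, large `zeta`
near-deterministic.

```{r}
tr <- hgf_filter(c(1, 1, 0, 1), omega = 0)
tr[, c("u1hat", "phi2", "delta1", "u2")]
```

Beliefs and values reset at each block start: every block introduces a
new pattern pair, so carrying beliefs across blocks would let the model
transfer knowledge the participant cannot have. Whether the original
analyses filtered continuously or reset per block is not something the
task description pins down; per-block reset is the reading consistent
with novel stimuli per block, and it also makes run-wise
cross-validation clean (held-out blocks are self-contained).

## Fitting and model comparison

`fit_map()` maximizes log-likelihood plus log-prior on transformed
scales (`omega` untransformed, `zeta` and `beta` log, `alpha` and the
probability parameters logit) with BFGS from multiple prior-drawn
starts. The default priors — `omega ~ N(-3, 16)`, `log zeta ~ N(0, 1)`,
`logit alpha ~ N(0, 1)`, `log beta ~ N(log 5, 1)` — are weakly
informative and centred near the simulation settings; they are the
package's own choice and every one is configurable. The default of 8
restarts is conservative; the larger simulation studies in the tests and
the acceptance script use 4, which is ample for these smooth
two-parameter posteriors (restart agreement is itself under test).

Model evidence uses the Laplace approximation on the transformed scale:
`LME = logjoint(theta_MAP) + (d/2) log(2*pi) - 0.5 * log det H`, with `H`
the central finite-difference Hessian (step `1e-4`). A
non-positive-definite Hessian is repaired by clamping eigenvalues with a
warning rather than failing, since flat directions do occur for
degenerate agents (for example `zeta -> 0` makes `omega` unidentified).
`bic()` provides the complexity-penalized likelihood alternative, and
`cross_validate()` a leave-one-run-out predictive check.

Group selection uses random-effects Bayesian model selection
(`rfx_bms()`): a variational Dirichlet posterior over model frequencies
(uniform prior `alpha0 = 1`, convergence at `max |delta alpha| < 1e-6`),
with exceedance probabilities estimated from 10^6 Dirichlet draws. The
Monte-Carlo route is kept (rather than the closed form available for two
models) because it generalizes to any number of models and its error,
about `3/sqrt(n)`, is negligible at the default draw count.

## Behavioural summaries

`p_staying()` conditions stay behaviour on the previous trial's outcome,
excluding each block's first trial; a conditional with no qualifying
trials is `NA`, never silently 0. `proportion_correct_by_phase()` scores
a trial correct when the chosen mapping matches the prevailing rule —
not when it happens to be rewarded. Under the 70/30 contingency a
perfect rule-follower is rewarded on only 70% of trials, so the
rule-based reading is the one under which learning curves can approach
1; `reversal_aligned_curve()` uses the same convention.

## Cross-phase RSA

The RSA stage asks whether condition-wise activity patterns
(HIT/CR/FA/MISS) recorded before a reversal resemble those after it
because they share the *stimulus* or because they share the *outcome*.
Correlating four pre-reversal condition patterns with four post-reversal
ones gives a non-symmetric 4×4 matrix (`empirical_rdm()`). The
outcome-selective model RDM marks the diagonal as similar; the
stimulus-selective model marks HIT~CR and FA~MISS pairs, because the
contingency flip relabels the same tactile pattern's rewarded outcome
across the reversal. The statistic is the mean correlation over
model-similar cells minus the mean over model-dissimilar cells, computed
on raw Pearson r (1 - r is the equivalent distance framing).

Group inference combines a one-sided Wilcoxon signed-rank test with a
permutation test. The permutation scheme relabels conditions within
subject: each iteration applies an independent random permutation to the
pre-epoch rows and the post-epoch columns of every subject's RDM and
recomputes the group mean. Because the RDM is condition-wise, there are
only 24 × 24 distinct relabelings, so the statistic is precomputed for
all of them and iterations reduce to indexed draws — distributionally
identical to naive resampling and much faster. P-values use the
`(b+1)/(n+1)` smoothing, and the reported "effect size" is the observed
group-mean statistic, stated as such because the similar-minus-dissimilar
mean is the quantity the tests are about.

`synth_patterns()` generates the calibration and recovery material: per
subject, condition vectors are a stimulus code (one Gaussian template
per tactile pattern, shared across the reversal by the conditions that
physically present that pattern) plus an outcome code (one template per
outcome category, shared across epochs) plus i.i.d. voxel noise. One
geometric consequence is worth knowing: a pure stimulus coder also
correlates some cells the *outcome* model counts as dissimilar
(e.g. pre-HIT with post-FA, both pattern A), so the off-target
statistic under a pure coder is slightly *negative* rather than zero.
That direction is conservative — a pure coder can never fake the other
model's selectivity — and the selectivity-recovery tests assert exactly
this behaviour.

What the generator does not emulate: spatial voxel correlation,
inter-subject alignment of templates, haemodynamic confounds, and
condition-count imbalance between phases. Passing recovery tests
therefore show that the statistics detect the coding structure they
target at realistic SNR, not that real fMRI patterns are this clean.

## Simulation sizes and numerical choices

The package's simulation studies use sizes chosen to give stable
Monte-Carlo estimates at interactive runtimes: 20-subject cohorts for
recovery studies (matching the order of the 32-subject empirical
cohort), 1000 repetitions for p(staying) profiles, 1000 seeded blocks
for contingency checks, 200 repetitions at 199 permutations for
permutation-p calibration, and 10^4–10^6 draws where a Monte-Carlo
tail probability is the target. Recovery cohorts draw `omega` uniformly
from [-6, -1] and `zeta` log-uniformly from [0.5, 8] — the range within
which the task is actually learnable at 540 trials and which brackets
the response settings used for the p(staying) simulations (`b = 0.5`,
`epsilon = 0.05`, `beta = 5`, `zeta = 0.5`, with Bayes-optimal `omega`
and `alpha` for each input sequence).

Other numerical choices: `optimize()` with tolerance `1e-6` for the
one-dimensional Bayes-optimal searches over `omega` in [-10, 2] and
`alpha` in [0.001, 0.999] (a constant input sequence pushes both to
their upper bound — the least-surprise solution is instant learning, so
the bound is reported, with a warning only if the objective is entirely
flat); likelihood clamping at `1e-12` inside the optimizer so BFGS never
sees an infinite objective while the exported
`negative_log_likelihood()` still reports `+Inf` with diagnostics;
per-block child RNG streams keyed on (run, block) so that enlarging a
design leaves existing blocks bit-identical.

## Known limitations

The HGF here is the two-level binary variant; volatility learning,
continuous inputs, and response-time models are out of scope. Invalid
trials are supported in imported data (they stay in the filtered history
but are masked from likelihood sums) but are not simulated. The
permutation scheme operates on condition labels, not on trials before
averaging; with condition-wise RDMs the two readings coincide in
expectation, but trial-level shuffling would additionally randomize
within-condition averaging noise.

## An end-to-end run

`run_pipeline()` chains the stages and writes one artifact per stage
plus a manifest with the seed and a configuration hash:

```{r, eval = FALSE}
res <- run_pipeline(default_run_config(), out_dir = "revlearn-run",
                    seed = 1)
res$bms
```
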