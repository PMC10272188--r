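# revlearn

Simulation and computational modelling of probabilistic Go/NoGo
reversal learning.

## What this is for

In probabilistic reversal-learning tasks, a participant learns by trial
and error which of two responses ("Go" or "NoGo") to each of two tactile
patterns is the more often rewarded (70% vs 30%), and then — at an
unannounced trial mid-block — the stimulus–response rule flips and they
must relearn. Behaviour in such tasks is the standard assay of cognitive
flexibility, and the interesting scientific questions are *computational*:
do people track outcome history with a fixed learning rate, a simple
heuristic, or do they dynamically adjust how much each prediction error
moves their beliefs?

`revlearn` provides the full analysis stack for this question on
simulated (or imported) choice data:

* **Task generator** — blocked designs (default 3 runs × 4 blocks × 45
  trials = 540), reversal drawn uniformly from trials 20–25, 70/30
  contingency, 10-trial learning phases (LN/LE/RN/RE).
* **Four agents** — random responding (bias *b*), noisy
  win-stay-lose-switch (lapse *ε*), Rescorla–Wagner
  (*V<sub>t</sub> = V<sub>t−1</sub> + α(r<sub>t−1</sub> − V<sub>t−1</sub>)*
  with softmax choice, inverse temperature *β*), and a two-level
  Hierarchical Gaussian Filter whose belief update
  *u₂⁽ᵗ⁾ = u₂⁽ᵗ⁻¹⁾ + φ₂⁽ᵗ⁾ δ₁⁽ᵗ⁾* weights the outcome prediction error
  *δ₁ = u₁ − û₁* by an evolving precision φ₂ — a dynamic learning rate —
  with step-size parameter ω and unit-square-sigmoid response
  determinism ζ.
* **Inference** — MAP fitting (BFGS, multiple restarts, configurable
  priors on transformed scales), Laplace log-model evidence, BIC,
  Bayes-optimal perceptual parameters (least cumulative Shannon surprise
  for a given input sequence), leave-one-run-out cross-validation.
* **Model comparison** — per-subject evidence differences (log Bayes
  factors) and random-effects Bayesian model selection with expected
  model frequencies and exceedance probabilities.
* **Behavioural summaries** — p(staying) by previous outcome, phase-wise
  accuracy, reversal-aligned learning curves, paired phase contrasts.
* **Cross-phase RSA** — stimulus- vs outcome-selective binary model
  RDMs, non-symmetric 4×4 pre×post condition correlation matrices,
  similar-minus-dissimilar statistics, Wilcoxon signed-rank and
  label-permutation group inference, and a synthetic pattern generator
  with controllable stimulus/outcome coding strength.

See `vignettes/modelling-reversal-learning.Rmd` for the models,
conventions, and numerical choices in detail.

## Worked example

Simulate a near-optimal hierarchical learner on the default 540-trial
task, summarize its behaviour, and ask which model explains it:

```r
library(revlearn)

design <- generate_design(task_config(), seed = 1)
omega_opt <- bayes_optimal_params("hgf", design)  # -2.462 for this design

agent <- simulate_hgf(design, omega = as.numeric(omega_opt), zeta = 4,
                      seed = 2)
proportion_correct_by_phase(agent)
#> # A tibble: 4 × 4
#>   subject phase accuracy n_trials
#>     <int> <chr>    <dbl>    <int>
#> 1       1 LN       0.831      118
#> 2       1 LE       0.858      120
#> 3       1 RN       0.392      120
#> 4       1 RE       0.875      120

fit <- fit_map("hgf", agent, n_restarts = 4, seed = 1)
fit
#> <fit_result: hgf model, 540 trials>
#>   MAP: omega = -2.479, zeta = 3.473
#>   NLL = 161.343, log-joint = -165.350 (5/5 restarts converged)
laplace_lme(fit)                                  # -167.63
laplace_lme(fit_map("rw", agent, n_restarts = 4, seed = 1))  # -174.24
```

The phase table shows the signature of flexible learning: accuracy
climbs to 0.86 before the reversal, collapses to 0.39 in the ten trials
right after it (the agent is still acting on the old rule), and recovers
to 0.88 by block end. The generating parameters (ω = −2.46, ζ = 4) are
recovered at (−2.48, 3.47), and the fitted HGF's log-model evidence
beats the Rescorla–Wagner fit by ~6.6 nats — a per-subject log Bayes
factor favouring precision-weighted over fixed-rate learning, which
`rfx_bms()` aggregates across a cohort into expected model frequencies
and exceedance probabilities.

`run_pipeline(default_run_config(), out_dir = "run1", seed = 1)` chains
all stages (simulate → fit → BMS → behaviour → RSA) and writes CSV/JSON
artifacts plus a manifest.

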