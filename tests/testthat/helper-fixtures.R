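# Shared fixtures: small designs keep unit tests fast; the full-size
# design is only used where the property under test needs it.

small_config <- function(...) {
  task_config(n_runs = 1, blocks_per_run = 2, ...)
}

small_design <- function(seed = 1, ...) {
  generate_design(small_config(...), seed = seed)
}

default_design <- function(seed = 1) {
  generate_design(task_config(), seed = seed)
}

# Hand-built trial tibble for metric edge cases: one block, explicit
# choices and outcomes.
toy_trials <- function(y, outcome, rule = rep(1L, length(y)),
                       phase = rep("LN", length(y))) {
  n <- length(y)
  tibble::tibble(subject = 1L, run = 1L, block = 1L, trial = seq_len(n),
                 reversal = n + 1L, stimulus = rep(1L, n), rule = rule,
                 phase = phase, u1 = rep(1L, n), y = as.integer(y),
                 p_choice = rep(0.5, n),
                 response = ifelse(y == 1L, "Go", "NoGo"),
                 outcome = as.integer(outcome),
                 outcome_category = outcome_category(
                   ifelse(y == 1L, "Go", "NoGo"), as.integer(outcome)),
                 correct = as.integer(y == rule), valid = TRUE)
}
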