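# Task design: blocked probabilistic Go/NoGo reversal task.
#
# Each block pairs two tactile patterns; one is the "Go" pattern (its
# higher-rewarded response is Go) and the other the "NoGo" pattern. The
# stimulus-response contingency holds with probability p_high and is
# inverted at a reversal trial drawn uniformly from a window.

#' Configure a probabilistic reversal-learning task
#'
#' Builds a validated configuration for the blocked Go/NoGo reversal task.
#' Defaults reproduce the design used throughout the package: 3 runs of 4
#' blocks of 45 trials (540 trials), a 70/30 reward contingency, a reversal
#' drawn uniformly from trials 20--25, two patterns drawn per block from a
#' set of 8, and 10-trial learning phases.
#'
#' @param n_runs Number of runs.
#' @param blocks_per_run Blocks per run.
#' @param trials_per_block Trials in each block.
#' @param p_high Probability that a trial's rewarded response follows the
#'   currently prevailing stimulus-response rule. Must lie in (0.5, 1].
#' @param reversal_window Length-2 integer vector; the reversal trial (the
#'   first trial governed by the reversed rule, 1-based) is drawn uniformly
#'   from this inclusive window.
#' @param n_patterns Size of the tactile pattern set blocks draw from.
#' @param phase_len Trials per learning phase (LN/LE/RN/RE).
#' @param seed Optional default RNG seed stored with the configuration.
#'
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$trials_per_block
#' @export
task_config <- function(n_runs = 3, blocks_per_run = 4, trials_per_block = 45,
                        p_high = 0.7, reversal_window = c(20L, 25L),
                        n_patterns = 8, phase_len = 10, seed = NULL) {
  stopifnot(n_runs >= 1, blocks_per_run >= 1, trials_per_block >= 2)
  if (!(p_high > 0.5 && p_high <= 1)) {
    stop("p_high must lie in (0.5, 1]", call. = FALSE)
  }
  reversal_window <- as.integer(reversal_window)
  if (length(reversal_window) != 2L || reversal_window[1] > reversal_window[2]) {
    stop("reversal_window must be an ordered pair", call. = FALSE)
  }
  if (reversal_window[1] < 2L || reversal_window[2] > trials_per_block - 1L) {
    stop("reversal_window must lie inside [2, trials_per_block - 1]",
         call. = FALSE)
  }
  if (phase_len > floor(trials_per_block / 2)) {
    stop("phase_len must not exceed floor(trials_per_block / 2)", call. = FALSE)
  }
  if (n_patterns < 2) stop("n_patterns must be >= 2", call. = FALSE)
  structure(
    list(n_runs = as.integer(n_runs),
         blocks_per_run = as.integer(blocks_per_run),
         trials_per_block = as.integer(trials_per_block),
         p_high = p_high,
         reversal_window = reversal_window,
         n_patterns = as.integer(n_patterns),
         phase_len = as.integer(phase_len),
         seed = seed),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Probabilistic Go/NoGo reversal task configuration\n")
  cat(sprintf("  %d run(s) x %d block(s) x %d trials = %d trials\n",
              x$n_runs, x$blocks_per_run, x$trials_per_block,
              x$n_runs * x$blocks_per_run * x$trials_per_block))
  cat(sprintf("  contingency p = %.2f, reversal window [%d, %d], phases of %d\n",
              x$p_high, x$reversal_window[1], x$reversal_window[2],
              x$phase_len))
  invisible(x)
}

# Deterministic per-block child seed so that blocks are reproducible
# independently of how many other blocks exist. Keyed on (run, block).
.block_seed <- function(seed, run, block) {
  as.integer((seed * 2654435761 + run * 97003 + block * 193) %% 2147483647)
}

# Response prescribed by latent mapping for a stimulus. Mapping 1 is
# stimulus1 -> Go / stimulus2 -> NoGo; mapping 0 the inverse.
.mapping_response <- function(stimulus, mapping) {
  ifelse((stimulus == 1L) == (mapping == 1L), "Go", "NoGo")
}

#' Generate the blocked reversal task design
#'
#' Draws the full trial structure for every block: the pattern pair, the
#' reversal trial, a near-balanced randomized stimulus sequence, and the
#' per-trial assigned rewarded response (the contingent response with
#' probability `p_high`, pre-drawn per trial). Each block uses its own
#' child RNG stream derived from the master seed, so regenerating with more
#' blocks leaves existing blocks untouched.
#'
#' @param config A [task_config()].
#' @param seed Master RNG seed; defaults to the seed stored in `config`,
#'   falling back to 1.
#'
#' @return An object of class `task_design`: a list with the `config` and a
#'   list of `block_design` objects. Each block carries `run`, `block`
#'   (global index), `go_pattern`, `nogo_pattern`, `reversal_trial`,
#'   per-trial `stimulus` (1 or 2, where 1 is the initial Go pattern),
#'   `assigned_response`, `rule` (prevailing mapping, 1 before the reversal
#'   and 0 from it on), `u1` (binary evidence for mapping 1), and `phase`.
#' @examples
#' d <- generate_design(task_config(), seed = 1)
#' length(d$blocks)
#' @export
generate_design <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  n <- config$trials_per_block
  blocks <- vector("list", config$n_runs * config$blocks_per_run)
  idx <- 0L
  for (run in seq_len(config$n_runs)) {
    for (blk in seq_len(config$blocks_per_run)) {
      idx <- idx + 1L
      set.seed(.block_seed(seed, run, blk))
      pair <- sample.int(config$n_patterns, 2L)
      win <- config$reversal_window
      reversal <- win[1] + sample.int(win[2] - win[1] + 1L, 1L) - 1L
      # near-balanced stimulus multiset, randomly permuted
      stim <- sample(rep(c(1L, 2L), length.out = n))
      rule <- ifelse(seq_len(n) < reversal, 1L, 0L)
      contingent <- .mapping_response(stim, rule)
      flip <- runif(n) >= config$p_high
      assigned <- ifelse(flip, ifelse(contingent == "Go", "NoGo", "Go"),
                         contingent)
      u1 <- as.integer(assigned == .mapping_response(stim, 1L))
      block <- structure(
        list(run = run, block = idx,
             go_pattern = pair[1], nogo_pattern = pair[2],
             reversal_trial = reversal,
             stimulus = stim, assigned_response = assigned,
             rule = rule, u1 = u1, phase = NULL),
        class = "block_design")
      block$phase <- assign_phases(block, config)
      blocks[[idx]] <- block
    }
  }
  structure(list(config = config, seed = seed, blocks = blocks),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Reversal task design: %d blocks x %d trials (seed %s)\n",
              length(x$blocks), x$config$trials_per_block,
              format(x$seed)))
  invisible(x)
}

#' Label trials of a block into learning phases
#'
#' LN covers the first `phase_len` trials, LE the `phase_len` trials
#' immediately before the reversal, RN the first `phase_len` trials from the
#' reversal on, and RE the last `phase_len` trials of the block. Remaining
#' trials are labelled `"none"`. If LN and LE overlap (the reversal falls at
#' trial `2 * phase_len`), the later label (LE) wins.
#'
#' @param block A `block_design`.
#' @param config The [task_config()] the block was generated under.
#' @return Character vector of phase labels, one per trial.
#' @export
assign_phases <- function(block, config) {
  n <- length(block$stimulus)
  k <- config$phase_len
  rev <- block$reversal_trial
  if (rev - k < 1L || rev + k - 1L > n) {
    stop("phase windows exceed block bounds", call. = FALSE)
  }
  phase <- rep("none", n)
  phase[seq_len(k)] <- "LN"
  phase[(rev - k):(rev - 1L)] <- "LE"
  phase[rev:(rev + k - 1L)] <- "RN"
  phase[(n - k + 1L):n] <- "RE"
  phase
}

#' Resolve a single trial's outcome
#'
#' Given a block, a trial index, and a response, returns the reward outcome
#' (1 iff the response matches the trial's assigned rewarded response) and
#' the outcome category: HIT (Go, rewarded), CR (NoGo, rewarded), FA (Go,
#' unrewarded), MISS (NoGo, unrewarded).
#'
#' @param block A `block_design`.
#' @param trial_index Trial index within the block (1-based).
#' @param response `"Go"` or `"NoGo"`.
#' @return List with `response`, `outcome` (0/1), `outcome_category`,
#'   `stimulus` and `u1` for the trial.
#' @export
play_trial <- function(block, trial_index, response) {
  response <- match.arg(response, .responses)
  outcome <- as.integer(response == block$assigned_response[trial_index])
  list(response = response,
       outcome = outcome,
       outcome_category = outcome_category(response, outcome),
       stimulus = block$stimulus[trial_index],
       u1 = block$u1[trial_index])
}

#' Categorize responses and outcomes
#'
#' @param response Character vector of `"Go"`/`"NoGo"`.
#' @param outcome Integer vector of rewards (0/1).
#' @return Character vector in HIT/CR/FA/MISS.
#' @export
outcome_category <- function(response, outcome) {
  ifelse(outcome == 1L,
         ifelse(response == "Go", "HIT", "CR"),
         ifelse(response == "Go", "FA", "MISS"))
}

#' Encode a trial's feedback as binary evidence for mapping 1
#'
#' The learning models filter a binary sequence `u1` where 1 means the
#' trial's feedback supports the mapping stimulus1 -> Go / stimulus2 -> NoGo:
#' either the executed response was consistent with that mapping and was
#' rewarded, or it was consistent with the opposite mapping and went
#' unrewarded. The encoding depends only on the stimulus and the assigned
#' rewarded response, so the resulting input sequence is independent of the
#' agent's behaviour.
#'
#' @param stimulus Integer vector in \{1, 2\}.
#' @param response Character vector of `"Go"`/`"NoGo"`.
#' @param outcome Integer reward vector (0/1).
#' @return Integer vector of 0/1.
#' @examples
#' encode_model_input(1, "Go", 1)  # rewarded mapping-1 response -> 1
#' @export
encode_model_input <- function(stimulus, response, outcome) {
  mapping1 <- .mapping_response(stimulus, 1L)
  as.integer((response == mapping1) == (outcome == 1L))
}
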