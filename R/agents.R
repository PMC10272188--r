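# Behavioural agents: closed-loop simulators for the four learning models.
#
# All agents choose between the two latent stimulus-response mappings
# (y = 1: stimulus1 -> Go / stimulus2 -> NoGo; y = 0: the inverse) and the
# motor response follows from the chosen mapping and the presented
# stimulus. Model states reset at each block start (a fresh pattern pair is
# introduced), while parameters are shared across blocks.

#' Run the two-level Hierarchical Gaussian Filter over a binary sequence
#'
#' Sequentially applies the precision-weighted update equations of the
#' two-level HGF for binary inputs (volatility level removed by fixing the
#' third-level constants to zero). On each trial the prediction is
#' `u1hat = s(u2)` with `s` the logistic sigmoid; its Bernoulli variance
#' `phi1hat = u1hat * (1 - u1hat)` and the diffused second-level variance
#' `phi2hat = phi2 + exp(omega)` combine into the precision weight
#' `phi2 = 1 / (1 / phi2hat + phi1hat)`, which scales the prediction error
#' `delta1 = u1 - u1hat` in the belief update `u2 <- u2 + phi2 * delta1`.
#' `phi2` acts as a dynamic learning rate; `abs(delta1)` is the Bayesian
#' surprise used downstream.
#'
#' @param u1 Binary input vector (0/1).
#' @param omega Log step-size of the second-level random walk.
#' @param u2_0 Initial second-level mean.
#' @param phi2_0 Initial second-level variance (> 0).
#' @return A tibble with one row per trial: `u1`, `u1hat`, `phi1hat`,
#'   `phi2hat`, `phi2`, `delta1`, `abs_delta1`, `u2`.
#' @examples
#' hgf_filter(c(1, 1, 0), omega = 0)
#' @export
hgf_filter <- function(u1, omega, u2_0 = 0, phi2_0 = 1) {
  if (!all(u1 %in% c(0, 1))) stop("u1 must be binary (0/1)", call. = FALSE)
  if (phi2_0 <= 0) stop("phi2_0 must be positive", call. = FALSE)
  s <- .hgf_core(u1, omega, u2_0, phi2_0)
  tibble::tibble(u1 = as.integer(u1), u1hat = s$u1hat, phi1hat = s$phi1hat,
                 phi2hat = s$phi2hat, phi2 = s$phi2, delta1 = s$delta1,
                 abs_delta1 = abs(s$delta1), u2 = s$u2)
}

# Bare-vector filter core shared with the likelihood code (no validation,
# no tibble construction: it sits inside optimizer inner loops).
.hgf_core <- function(u1, omega, u2_0 = 0, phi2_0 = 1) {
  n <- length(u1)
  u1hat <- phi1hat <- phi2hat <- phi2 <- delta1 <- u2 <- numeric(n)
  u2_prev <- u2_0
  phi2_prev <- phi2_0
  e_omega <- exp(omega)
  for (t in seq_len(n)) {
    u1hat[t] <- 1 / (1 + exp(-u2_prev))
    phi1hat[t] <- u1hat[t] * (1 - u1hat[t])
    phi2hat[t] <- phi2_prev + e_omega
    phi2[t] <- 1 / (1 / phi2hat[t] + phi1hat[t])
    delta1[t] <- u1[t] - u1hat[t]
    u2[t] <- u2_prev + phi2[t] * delta1[t]
    u2_prev <- u2[t]
    phi2_prev <- phi2[t]
  }
  list(u1hat = u1hat, phi1hat = phi1hat, phi2hat = phi2hat, phi2 = phi2,
       delta1 = delta1, u2 = u2)
}

#' Unit-square sigmoid response model
#'
#' Maps the predicted probability of mapping 1 onto the probability of
#' choosing it: `p(y = 1) = u1hat^zeta / (u1hat^zeta + (1 - u1hat)^zeta)`.
#' `zeta = 0` yields indifference (p = 0.5), `zeta = 1` probability
#' matching, and large `zeta` near-deterministic choice of the currently
#' favoured mapping.
#'
#' @param u1hat Predicted probability in (0, 1); vectorized.
#' @param zeta Response determinism (>= 0).
#' @return Probability of choosing mapping 1.
#' @export
hgf_response_prob <- function(u1hat, zeta) {
  if (zeta < 0) stop("zeta must be non-negative", call. = FALSE)
  a <- u1hat^zeta
  b <- (1 - u1hat)^zeta
  a / (a + b)
}

#' Rescorla-Wagner value update
#'
#' `V <- V + alpha * (r - V)`: the chosen option's value moves toward the
#' observed reward by a fixed fraction `alpha` of the prediction error.
#'
#' @param V Current value (in \[0, 1\]).
#' @param r Observed reward (0/1).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
rw_step <- function(V, r, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  V + alpha * (r - V)
}

#' Softmax choice probabilities
#'
#' @param V Numeric vector of option values.
#' @param beta Inverse temperature (>= 0); 0 gives uniform choice.
#' @return Vector of choice probabilities summing to 1.
#' @export
softmax_prob <- function(V, beta) {
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  z <- exp(beta * V - max(beta * V))
  z / sum(z)
}

# Assemble the per-trial tibble shared by all simulators.
.assemble_trials <- function(design, subject, model, y, p1, extra = NULL) {
  blocks <- design$blocks
  n <- design$config$trials_per_block
  out <- tibble::tibble(
    subject = as.integer(subject),
    run = rep(vapply(blocks, `[[`, integer(1), "run"), each = n),
    block = rep(vapply(blocks, `[[`, integer(1), "block"), each = n),
    trial = rep(seq_len(n), length(blocks)),
    reversal = rep(vapply(blocks, `[[`, integer(1), "reversal_trial"),
                   each = n),
    stimulus = unlist(lapply(blocks, `[[`, "stimulus")),
    rule = unlist(lapply(blocks, `[[`, "rule")),
    phase = unlist(lapply(blocks, `[[`, "phase")),
    u1 = unlist(lapply(blocks, `[[`, "u1")),
    y = as.integer(y),
    p_choice = p1)
  out$response <- .mapping_response(out$stimulus, out$y)
  assigned <- unlist(lapply(blocks, `[[`, "assigned_response"))
  out$outcome <- as.integer(out$response == assigned)
  out$outcome_category <- outcome_category(out$response, out$outcome)
  out$correct <- as.integer(out$y == out$rule)
  out$valid <- TRUE
  if (!is.null(extra)) out <- tibble::as_tibble(cbind(out, extra))
  attr(out, "model") <- model
  class(out) <- c("agent_trajectory", class(out))
  out
}

#' @export
print.agent_trajectory <- function(x, ...) {
  cat(sprintf("<agent_trajectory: %s model, %d trials, %d block(s)>\n",
              attr(x, "model"), nrow(x), length(unique(x$block))))
  NextMethod()
}

#' Simulate a randomly responding agent
#'
#' Chooses mapping 1 with constant probability `b` on every trial,
#' independent of history.
#'
#' @param design A [generate_design()] result.
#' @param b Choice bias toward mapping 1, in \[0, 1\].
#' @param seed RNG seed.
#' @param subject Subject id recorded in the output.
#' @return An `agent_trajectory` tibble (one row per trial).
#' @export
simulate_random <- function(design, b = 0.5, seed = 1, subject = 1L) {
  stopifnot(inherits(design, "task_design"), b >= 0, b <= 1)
  set.seed(seed)
  n_total <- length(design$blocks) * design$config$trials_per_block
  p1 <- rep(b, n_total)
  y <- rbinom(n_total, 1L, p1)
  .assemble_trials(design, subject, "random", y, p1)
}

#' Simulate a noisy win-stay-lose-switch agent
#'
#' Repeats the previous mapping choice after a reward and switches after a
#' non-reward, lapsing with probability `epsilon`: the favoured option is
#' chosen with probability `1 - epsilon/2`, the other with `epsilon/2`.
#' The first trial of each block is chosen uniformly.
#'
#' @inheritParams simulate_random
#' @param epsilon Lapse probability in \[0, 1\].
#' @return An `agent_trajectory` tibble.
#' @export
simulate_wsls <- function(design, epsilon = 0.05, seed = 1, subject = 1L) {
  stopifnot(inherits(design, "task_design"), epsilon >= 0, epsilon <= 1)
  set.seed(seed)
  n <- design$config$trials_per_block
  y <- p1 <- numeric(0)
  for (block in design$blocks) {
    yb <- integer(n); pb <- numeric(n)
    for (t in seq_len(n)) {
      pb[t] <- if (t == 1L) 0.5 else {
        r_prev <- as.integer(.mapping_response(block$stimulus[t - 1L],
                                               yb[t - 1L]) ==
                               block$assigned_response[t - 1L])
        stay1 <- (yb[t - 1L] == 1L) == (r_prev == 1L)
        if (stay1) 1 - epsilon / 2 else epsilon / 2
      }
      yb[t] <- rbinom(1L, 1L, pb[t])
    }
    y <- c(y, yb); p1 <- c(p1, pb)
  }
  .assemble_trials(design, subject, "wsls", y, p1)
}

#' Simulate a Rescorla-Wagner agent
#'
#' Tracks a value for each of the two mappings; only the chosen mapping's
#' value is updated with the observed reward ([rw_step()]), and choices are
#' drawn from the softmax over the two values ([softmax_prob()]). Values
#' reset to `V0` at each block start.
#'
#' @inheritParams simulate_random
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Softmax inverse temperature (>= 0).
#' @param V0 Initial value for both mappings.
#' @return An `agent_trajectory` tibble with per-trial values `v1`, `v0`.
#' @export
simulate_rw <- function(design, alpha, beta = 5, V0 = 0.5, seed = 1,
                        subject = 1L) {
  stopifnot(inherits(design, "task_design"), V0 >= 0, V0 <= 1)
  set.seed(seed)
  n <- design$config$trials_per_block
  y <- p1 <- v1 <- v0 <- numeric(0)
  for (block in design$blocks) {
    V <- c(V0, V0)  # values of mapping 1, mapping 0
    yb <- integer(n); pb <- v1b <- v0b <- numeric(n)
    for (t in seq_len(n)) {
      v1b[t] <- V[1]; v0b[t] <- V[2]
      pb[t] <- softmax_prob(V, beta)[1]
      yb[t] <- rbinom(1L, 1L, pb[t])
      r <- as.integer(.mapping_response(block$stimulus[t], yb[t]) ==
                        block$assigned_response[t])
      k <- if (yb[t] == 1L) 1L else 2L
      V[k] <- rw_step(V[k], r, alpha)
    }
    y <- c(y, yb); p1 <- c(p1, pb); v1 <- c(v1, v1b); v0 <- c(v0, v0b)
  }
  .assemble_trials(design, subject, "rw", y, p1,
                   extra = data.frame(v1 = v1, v0 = v0))
}

#' Simulate a two-level HGF agent
#'
#' Closed loop against the task: on each trial the agent predicts
#' `u1hat = s(u2)`, chooses a mapping through the unit-square sigmoid
#' ([hgf_response_prob()]), emits the response implied by the chosen mapping
#' and the presented stimulus, observes the outcome, encodes it as binary
#' evidence `u1` for mapping 1, and performs one precision-weighted filter
#' step. Beliefs reset at each block start (a new pattern pair is
#' introduced); `omega` and `zeta` are shared across blocks.
#'
#' @inheritParams simulate_random
#' @param omega Log step-size of the second-level random walk.
#' @param zeta Response determinism of the unit-square sigmoid.
#' @param u2_0,phi2_0 Initial second-level mean and variance.
#' @return An `agent_trajectory` tibble including the filter trajectory
#'   columns `u1hat`, `u2`, `phi2`, `delta1`, `abs_delta1`.
#' @export
simulate_hgf <- function(design, omega, zeta = 0.5, u2_0 = 0, phi2_0 = 1,
                         seed = 1, subject = 1L) {
  stopifnot(inherits(design, "task_design"))
  set.seed(seed)
  n <- design$config$trials_per_block
  y <- p1 <- numeric(0)
  traj <- NULL
  for (block in design$blocks) {
    # the filter input is response-independent, so the trajectory can be
    # computed per block up front and choices drawn from its predictions
    tb <- hgf_filter(block$u1, omega, u2_0 = u2_0, phi2_0 = phi2_0)
    pb <- hgf_response_prob(tb$u1hat, zeta)
    yb <- rbinom(n, 1L, pb)
    y <- c(y, yb); p1 <- c(p1, pb)
    traj <- rbind(traj, tb[, c("u1hat", "u2", "phi2", "delta1", "abs_delta1")])
  }
  .assemble_trials(design, subject, "hgf", y, p1, extra = as.data.frame(traj))
}

#' Write an agent trajectory to CSV
#'
#' One row per trial; HGF filter columns are included when present and left
#' out otherwise.
#'
#' @param trials An `agent_trajectory` tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trials, path) {
  cols <- c("subject", "run", "block", "trial", "stimulus", "u1",
            "u1hat", "u2", "phi2", "delta1", "abs_delta1",
            "p_choice", "y", "response", "outcome", "outcome_category",
            "phase")
  cols <- intersect(cols, names(trials))
  write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE)
  invisible(path)
}
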