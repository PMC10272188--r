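# Model fitting: MAP estimation on transformed scales, Laplace model
# evidence, BIC, Bayes-optimal perceptual parameters, cross-validation.

.transforms <- list(
  identity = list(to = identity, from = identity),
  log      = list(to = log,      from = exp),
  logit    = list(to = stats::qlogis, from = stats::plogis)
)

#' Default MAP priors for each model
#'
#' Gaussian priors on transformed parameter scales: `omega` on the identity
#' scale with mean -3 and variance 16; `log(zeta)`, `log(beta)` (centred on
#' `log(5)`), `logit(alpha)`, `logit(b)` and `logit(epsilon)` standard
#' normal-ish. These are weakly informative and centred near the simulation
#' settings used for the task; every element can be overridden.
#'
#' @param model One of `"random"`, `"wsls"`, `"rw"`, `"hgf"`.
#' @return Named list: per parameter a list with `transform`, `mean`, `sd`
#'   (on the transformed scale).
#' @export
default_priors <- function(model = c("random", "wsls", "rw", "hgf")) {
  model <- match.arg(model)
  switch(model,
    random = list(b = list(transform = "logit", mean = 0, sd = 1)),
    wsls = list(epsilon = list(transform = "logit", mean = 0, sd = 1)),
    rw = list(alpha = list(transform = "logit", mean = 0, sd = 1),
              beta = list(transform = "log", mean = log(5), sd = 1)),
    hgf = list(omega = list(transform = "identity", mean = -3, sd = 4),
               zeta = list(transform = "log", mean = 0, sd = 1)))
}

.to_natural <- function(theta, priors) {
  stats::setNames(
    lapply(seq_along(priors), function(i) {
      unname(.transforms[[priors[[i]]$transform]]$from(theta[i]))
    }),
    names(priors))
}

.to_transformed <- function(params, priors) {
  vapply(names(priors), function(nm) {
    .transforms[[priors[[nm]]$transform]]$to(params[[nm]])
  }, numeric(1))
}

.log_prior <- function(theta, priors) {
  sum(vapply(seq_along(priors), function(i) {
    dnorm(theta[i], priors[[i]]$mean, priors[[i]]$sd, log = TRUE)
  }, numeric(1)))
}

# Per-trial probability of choosing mapping 1 given the history, with
# per-block state reset. Works from observed choices/outcomes, so it
# applies equally to simulated and imported data.
.choice_probs <- function(model, params, trials) {
  p_all <- numeric(nrow(trials))
  for (ix in split(seq_len(nrow(trials)), trials$block)) {
    y <- trials$y[ix]; r <- trials$outcome[ix]; u1 <- trials$u1[ix]
    n <- length(ix)
    p <- switch(model,
      random = rep(params$b, n),
      wsls = {
        pb <- rep(0.5, n)
        if (n > 1) {
          stay1 <- (y[-n] == 1L) == (r[-n] == 1L)
          pb[-1] <- ifelse(stay1, 1 - params$epsilon / 2, params$epsilon / 2)
        }
        pb
      },
      rw = {
        v1 <- 0.5; v0 <- 0.5
        a <- params$alpha; be <- params$beta
        pb <- numeric(n)
        for (t in seq_len(n)) {
          pb[t] <- 1 / (1 + exp(-be * (v1 - v0)))
          if (y[t] == 1L) v1 <- v1 + a * (r[t] - v1)
          else v0 <- v0 + a * (r[t] - v0)
        }
        pb
      },
      hgf = {
        u1hat <- .hgf_core(u1, params$omega,
                           u2_0 = params$u2_0 %||% 0,
                           phi2_0 = params$phi2_0 %||% 1)$u1hat
        hgf_response_prob(u1hat, params$zeta)
      },
      stop("unknown model: ", model, call. = FALSE))
    p_all[ix] <- p
  }
  p_all
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative log-likelihood of observed choices under a model
#'
#' Sums `-log p(y_t | history, params)` over valid trials, with model state
#' reset at each block boundary. A trial the model assigns probability zero
#' returns `+Inf` with a `zero_prob_trials` attribute listing the offending
#' rows rather than throwing.
#'
#' @param model One of `"random"`, `"wsls"`, `"rw"`, `"hgf"`.
#' @param params Named list of natural-scale parameters for the model.
#' @param trials An `agent_trajectory`-shaped tibble (needs `block`, `y`,
#'   `outcome`, `u1`, and optionally `valid`).
#' @return Scalar NLL.
#' @export
negative_log_likelihood <- function(model, params, trials) {
  valid <- if (is.null(trials$valid)) rep(TRUE, nrow(trials)) else trials$valid
  p1 <- .choice_probs(model, params, trials)
  p_obs <- ifelse(trials$y == 1L, p1, 1 - p1)
  if (any(p_obs[valid] <= 0)) {
    out <- Inf
    attr(out, "zero_prob_trials") <- which(p_obs <= 0 & valid)
    return(out)
  }
  -sum(log(p_obs[valid]))
}

# Clamped per-trial log-likelihood used inside optimization (keeps BFGS
# away from non-finite objective values at extreme parameters). Invalid
# trials stay in the history the model filters but are masked from the sum.
.nll_floored <- function(model, params, trials, floor = 1e-12) {
  valid <- if (is.null(trials$valid)) rep(TRUE, nrow(trials)) else trials$valid
  p1 <- .choice_probs(model, params, trials)
  p_obs <- pmin(pmax(ifelse(trials$y == 1L, p1, 1 - p1), floor), 1)
  -sum(log(p_obs[valid]))
}

#' Bayes-optimal perceptual parameter for a fixed input sequence
#'
#' Finds the perceptual parameter (HGF `omega`, or RW learning rate
#' `alpha` with the value read as the probability of `u1 = 1`) minimizing
#' the cumulative Shannon surprise `sum_t -log p(u1_t | prediction_t)` over
#' the given binary input sequence, by bounded scalar optimization. The
#' input sequence is a property of the task, independent of any responses;
#' filter state resets per block.
#'
#' @param model `"hgf"` or `"rw"`.
#' @param input Either a `task_design` (uses each block's `u1` sequence) or
#'   a binary vector treated as one block.
#' @param interval Search interval; defaults to `c(-10, 2)` for `omega` and
#'   `c(0.001, 0.999)` for `alpha`.
#' @return The optimal parameter value (named scalar), with the achieved
#'   surprise as attribute `"surprise"`.
#' @export
bayes_optimal_params <- function(model = c("hgf", "rw"), input,
                                 interval = NULL) {
  model <- match.arg(model)
  seqs <- if (inherits(input, "task_design")) {
    lapply(input$blocks, `[[`, "u1")
  } else list(as.integer(input))
  if (!all(unlist(seqs) %in% c(0, 1))) {
    stop("input must be binary", call. = FALSE)
  }
  if (is.null(interval)) {
    interval <- if (model == "hgf") c(-10, 2) else c(0.001, 0.999)
  }
  surprise <- function(par) {
    sum(vapply(seqs, function(u1) {
      p <- if (model == "hgf") {
        .hgf_core(u1, omega = par)$u1hat
      } else {
        V <- numeric(length(u1))
        V[1] <- 0.5
        for (t in seq_along(u1)[-1]) {
          V[t] <- V[t - 1] + par * (u1[t - 1] - V[t - 1])
        }
        V
      }
      p_obs <- pmin(pmax(ifelse(u1 == 1L, p, 1 - p), 1e-12), 1)
      -sum(log(p_obs))
    }, numeric(1)))
  }
  probes <- surprise(interval[1]) ; probes <- c(probes, vapply(
    seq(interval[1], interval[2], length.out = 5)[-1], surprise, numeric(1)))
  if (diff(range(probes)) < 1e-12) {
    warning("surprise objective is flat over the interval; returning midpoint")
    out <- mean(interval)
    attr(out, "surprise") <- surprise(out)
    names(out) <- if (model == "hgf") "omega" else "alpha"
    return(out)
  }
  opt <- optimize(surprise, interval, tol = 1e-6)
  out <- opt$minimum
  attr(out, "surprise") <- opt$objective
  names(out) <- if (model == "hgf") "omega" else "alpha"
  out
}

#' Fit a model to choice data by MAP estimation
#'
#' Maximizes log-likelihood plus log-prior on the transformed parameter
#' scale with BFGS, taking the best of `n_restarts` initializations drawn
#' from the prior (plus one start at the prior mean). Estimates are
#' returned on the natural scale.
#'
#' @param model One of `"random"`, `"wsls"`, `"rw"`, `"hgf"`.
#' @param trials Trial tibble as in [negative_log_likelihood()].
#' @param priors Prior specification as produced by [default_priors()].
#' @param n_restarts Number of random restarts.
#' @param seed RNG seed for the restart draws.
#' @return A `fit_result`: MAP `estimates` (natural scale), `theta_hat`
#'   (transformed), `nll`, `logjoint_value`, the `logjoint` function used
#'   (for evidence computation), dimension `d`, `n_trials`, and optimizer
#'   diagnostics.
#' @export
fit_map <- function(model, trials, priors = default_priors(model),
                    n_restarts = 8, seed = 1) {
  n_valid <- if (is.null(trials$valid)) nrow(trials) else sum(trials$valid)
  neg_logjoint <- function(theta) {
    .nll_floored(model, .to_natural(theta, priors), trials) -
      .log_prior(theta, priors)
  }
  set.seed(seed)
  d <- length(priors)
  mu <- vapply(priors, `[[`, numeric(1), "mean")
  sd <- vapply(priors, `[[`, numeric(1), "sd")
  starts <- rbind(mu, matrix(rnorm(n_restarts * d, rep(mu, each = n_restarts),
                                   rep(sd, each = n_restarts)),
                             ncol = d))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(optim(starts[i, ], neg_logjoint, method = "BFGS",
                   control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("all optimizer restarts failed for model ", model, call. = FALSE)
  }
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  theta_hat <- stats::setNames(best$par, names(priors))
  est <- .to_natural(theta_hat, priors)
  structure(
    list(model = model,
         estimates = est,
         theta_hat = theta_hat,
         priors = priors,
         nll = .nll_floored(model, est, trials),
         logjoint = function(theta) -neg_logjoint(theta),
         logjoint_value = -best$value,
         d = d,
         n_trials = n_valid,
         convergence = best$convergence,
         n_restarts_tried = nrow(starts),
         n_restarts_converged = sum(vapply(fits, `[[`, numeric(1),
                                           "convergence") == 0),
         restart_values = -values),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s model, %d trials>\n", x$model, x$n_trials))
  est <- unlist(x$estimates)
  cat("  MAP:", paste(sprintf("%s = %.4g", names(est), est), collapse = ", "),
      "\n")
  cat(sprintf("  NLL = %.3f, log-joint = %.3f (%d/%d restarts converged)\n",
              x$nll, x$logjoint_value, x$n_restarts_converged,
              x$n_restarts_tried))
  invisible(x)
}

# Central finite-difference Hessian (symmetrized).
.fd_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' Laplace approximation to the log-model evidence
#'
#' `LME = logjoint(theta_MAP) + (d/2) log(2 pi) - (1/2) log det H`, with `H`
#' the finite-difference Hessian of the negative log-joint on the
#' transformed scale. A non-positive-definite Hessian is repaired by
#' clamping its eigenvalues to a small positive floor, with a warning;
#' exact for a Gaussian (quadratic log-joint).
#'
#' @param fit A `fit_result` (or any list with elements `logjoint`,
#'   `theta_hat`, and `logjoint_value`).
#' @param step Finite-difference step on the transformed scale.
#' @return Scalar LME (nats).
#' @export
laplace_lme <- function(fit, step = 1e-4) {
  H <- .fd_hessian(function(th) -fit$logjoint(th), fit$theta_hat, h = step)
  if (any(!is.finite(H))) stop("Hessian is not finite at the MAP", call. = FALSE)
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(eig <= 0)) {
    warning("Hessian not positive definite at the MAP; clamping eigenvalues")
    eig <- pmax(eig, 1e-8)
  }
  logdet <- sum(log(eig))
  if (!is.finite(logdet)) {
    stop("Hessian is singular after repair; LME unavailable", call. = FALSE)
  }
  d <- length(fit$theta_hat)
  fit$logjoint_value + (d / 2) * log(2 * pi) - logdet / 2
}

#' Bayesian information criterion
#'
#' `BIC = 2 * NLL + d * log(n_trials)`.
#'
#' @param fit A `fit_result`.
#' @param n_trials Number of trials; defaults to the fitted count.
#' @return Scalar BIC.
#' @export
bic <- function(fit, n_trials = fit$n_trials) {
  2 * fit$nll + fit$d * log(n_trials)
}

#' Leave-one-run-out cross-validation of a choice model
#'
#' For each run, fits the model on the remaining runs and scores the mean
#' held-out log predictive probability per trial (model state resets per
#' block, so held-out blocks are self-contained).
#'
#' @inheritParams fit_map
#' @return List with `fold_scores` (named by held-out run), `mean_score`,
#'   and the per-fold `fits`.
#' @export
cross_validate <- function(model, trials, priors = default_priors(model),
                           n_restarts = 4, seed = 1) {
  runs <- sort(unique(trials$run))
  if (length(runs) < 2) stop("cross-validation needs at least 2 runs",
                             call. = FALSE)
  fits <- list(); scores <- numeric(0)
  for (r in runs) {
    train <- trials[trials$run != r, ]
    test <- trials[trials$run == r, ]
    if (length(unique(test$block)) < 1 || nrow(test) == 0) {
      stop("held-out fold for run ", r, " contains no blocks", call. = FALSE)
    }
    fit <- fit_map(model, train, priors, n_restarts = n_restarts, seed = seed)
    scores[as.character(r)] <- -.nll_floored(model, fit$estimates, test) /
      nrow(test)
    fits[[as.character(r)]] <- fit
  }
  list(fold_scores = scores, mean_score = mean(scores), fits = fits)
}
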