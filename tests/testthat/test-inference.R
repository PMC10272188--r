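test_that("NLL has the closed-form value for indifferent and perfect models", {
  d <- default_design(seed = 1)
  tr <- simulate_random(d, b = 0.5, seed = 1)
  # an indifferent model scores n * ln 2
  expect_equal(negative_log_likelihood("random", list(b = 0.5), tr),
               540 * log(2))
  # a model predicting every observed response with p = 1
  tr_all1 <- tr; tr_all1$y <- 1L
  expect_equal(negative_log_likelihood("random", list(b = 1), tr_all1), 0)
  # and zero-probability observations give +Inf with a diagnostic
  tr_mixed <- tr
  nll <- negative_log_likelihood("random", list(b = 1), tr_mixed)
  expect_true(is.infinite(nll) && nll > 0)
  expect_identical(attr(nll, "zero_prob_trials"), which(tr_mixed$y == 0L))
})

test_that("NLL is consistent with the simulator's own trajectory", {
  d <- small_design(seed = 2)
  params <- list(omega = -2, zeta = 3)
  tr <- simulate_hgf(d, omega = params$omega, zeta = params$zeta, seed = 5)
  manual <- -sum(log(ifelse(tr$y == 1L, tr$p_choice, 1 - tr$p_choice)))
  expect_equal(negative_log_likelihood("hgf", params, tr), manual)
  tr_rw <- simulate_rw(d, alpha = 0.25, beta = 4, seed = 5)
  manual_rw <- -sum(log(ifelse(tr_rw$y == 1L, tr_rw$p_choice,
                               1 - tr_rw$p_choice)))
  expect_equal(negative_log_likelihood("rw", list(alpha = 0.25, beta = 4),
                                       tr_rw),
               manual_rw)
  # invalid trials are dropped from the sum
  tr2 <- tr; tr2$valid[1:10] <- FALSE
  expect_lt(negative_log_likelihood("hgf", params, tr2),
            negative_log_likelihood("hgf", params, tr))
})

test_that("Bayes-optimal parameters match a fine grid search", {
  d <- default_design(seed = 3)
  opt <- bayes_optimal_params("hgf", d)
  grid <- seq(-10, 2, length.out = 1000)
  surprise <- function(om) {
    sum(vapply(d$blocks, function(b) {
      p <- hgf_filter(b$u1, om)$u1hat
      -sum(log(ifelse(b$u1 == 1L, p, 1 - p)))
    }, numeric(1)))
  }
  vals <- vapply(grid, surprise, numeric(1))
  expect_lt(abs(as.numeric(opt) - grid[which.min(vals)]), 1e-2)
  expect_lte(attr(opt, "surprise"), min(vals) + 1e-6)
  # argmin property against random probes
  set.seed(4)
  probes <- runif(50, -10, 2)
  expect_true(all(attr(opt, "surprise") <= vapply(probes, surprise,
                                                  numeric(1)) + 1e-9))
})

test_that("constant input pushes the optimal step size to the upper bound", {
  opt <- bayes_optimal_params("hgf", rep(1L, 100), interval = c(-10, 2))
  expect_gt(as.numeric(opt), 1.9)  # optimize() stops just inside the bound
  opt_a <- bayes_optimal_params("rw", rep(1L, 100))
  expect_gt(as.numeric(opt_a), 0.99)
})

test_that("RW Bayes-optimal learning rate matches a grid search", {
  d <- default_design(seed = 5)
  opt <- bayes_optimal_params("rw", d)
  grid <- seq(0.001, 0.999, length.out = 1000)
  surprise <- function(a) {
    sum(vapply(d$blocks, function(b) {
      u1 <- b$u1
      V <- numeric(length(u1)); V[1] <- 0.5
      for (t in seq_along(u1)[-1]) V[t] <- V[t - 1] + a * (u1[t - 1] - V[t - 1])
      -sum(log(ifelse(u1 == 1L, V, 1 - V)))
    }, numeric(1)))
  }
  vals <- vapply(grid, surprise, numeric(1))
  expect_lt(abs(as.numeric(opt) - grid[which.min(vals)]), 1e-3)
})

test_that("MAP fitting recovers a well-determined optimum", {
  d <- default_design(seed = 6)
  gen <- list(omega = -2.5, zeta = 3)
  tr <- simulate_hgf(d, omega = gen$omega, zeta = gen$zeta, seed = 7)
  fit <- fit_map("hgf", tr, n_restarts = 10, seed = 1)
  expect_identical(fit$convergence, 0L)
  # log-joint at the MAP beats the generating parameters
  priors <- default_priors("hgf")
  theta_gen <- c(gen$omega, log(gen$zeta))
  expect_gte(fit$logjoint_value, fit$logjoint(theta_gen))
  # restarts agree on the optimum on well-conditioned data
  spread <- diff(range(fit$restart_values))
  expect_lt(spread, 0.01)
  # near-deterministic data drive zeta above its prior mean
  tr_det <- simulate_hgf(d, omega = -2.5, zeta = 12, seed = 8)
  fit_det <- fit_map("hgf", tr_det, n_restarts = 6, seed = 1)
  expect_gt(fit_det$estimates$zeta, 1)
})

test_that("Laplace evidence is exact for a Gaussian log-joint", {
  # quadratic log-joint c - (theta - a)^2 / (2 v): the Laplace
  # approximation equals the true log integral c + 0.5 log(2 pi v)
  a <- 0.7; v <- 0.3; cc <- -4
  toy <- list(logjoint = function(th) cc - (th - a)^2 / (2 * v),
              theta_hat = a, logjoint_value = cc)
  expect_equal(laplace_lme(toy), cc + 0.5 * log(2 * pi * v), tolerance = 1e-6)
  # translation property: adding a constant shifts the LME by it
  toy2 <- toy
  toy2$logjoint <- function(th) toy$logjoint(th) + 3.2
  toy2$logjoint_value <- toy$logjoint_value + 3.2
  expect_equal(laplace_lme(toy2), laplace_lme(toy) + 3.2, tolerance = 1e-6)
})

test_that("Laplace evidence agrees with quadrature on a 1-parameter model", {
  # Bernoulli likelihood with a logistic link and a standard normal prior
  set.seed(9)
  yobs <- rbinom(40, 1, 0.75)
  logjoint <- function(th) {
    p <- stats::plogis(th)
    sum(yobs * log(p) + (1 - yobs) * log(1 - p)) + dnorm(th, log = TRUE)
  }
  opt <- optimize(function(th) -logjoint(th), c(-5, 5))
  fitlike <- list(logjoint = logjoint, theta_hat = opt$minimum,
                  logjoint_value = -opt$objective)
  exact <- log(stats::integrate(function(th) {
    vapply(th, function(t) exp(logjoint(t)), numeric(1))
  }, -10, 10, rel.tol = 1e-10)$value)
  expect_lt(abs(laplace_lme(fitlike) - exact), 0.05)
})

test_that("a flat direction triggers the positive-definite repair", {
  toy <- list(logjoint = function(th) -(th[1]^2) / 2,  # th[2] unconstrained
              theta_hat = c(0, 0), logjoint_value = 0)
  expect_warning(lme <- laplace_lme(toy), "positive definite")
  expect_true(is.finite(lme))
})

test_that("BIC follows its closed form", {
  fake <- structure(list(nll = 100, d = 2, n_trials = 540),
                    class = "fit_result")
  expect_equal(bic(fake), 200 + 2 * log(540))
  fake0 <- structure(list(nll = 50, d = 0, n_trials = 540),
                     class = "fit_result")
  expect_equal(bic(fake0), 100)
  expect_equal(bic(fake, n_trials = 100), 200 + 2 * log(100))
})

test_that("cross-validation scores and orders models sensibly", {
  cfg <- task_config(n_runs = 3, blocks_per_run = 2)
  d <- generate_design(cfg, seed = 10)
  tr_rand <- simulate_random(d, b = 0.5, seed = 11)
  cv_rand <- cross_validate("random", tr_rand, n_restarts = 2, seed = 1)
  expect_length(cv_rand$fold_scores, 3)
  expect_lt(abs(cv_rand$mean_score + log(2)), 0.02)
  # determinism
  cv_rand2 <- cross_validate("random", tr_rand, n_restarts = 2, seed = 1)
  expect_identical(cv_rand$fold_scores, cv_rand2$fold_scores)
  # HGF-generated data: HGF predicts held-out choices better than chance
  omega <- as.numeric(bayes_optimal_params("hgf", d))
  tr_hgf <- simulate_hgf(d, omega = omega, zeta = 4, seed = 12)
  cv_hgf <- cross_validate("hgf", tr_hgf, n_restarts = 2, seed = 1)
  cv_base <- cross_validate("random", tr_hgf, n_restarts = 2, seed = 1)
  expect_gt(cv_hgf$mean_score, cv_base$mean_score)
  # a single run cannot be cross-validated
  expect_error(cross_validate("random", tr_rand[tr_rand$run == 1, ]),
               "2 runs")
})

test_that("parameter recovery error shrinks with more trials", {
  # fewer trials -> noisier omega estimates (monotone in n)
  cfg_small <- task_config(n_runs = 1, blocks_per_run = 3)  # 135 trials
  errs <- function(cfg, n_sub, seed0) {
    vapply(seq_len(n_sub), function(s) {
      d <- generate_design(cfg, seed = seed0 + s)
      omega <- -3 + 2 * (s %% 3)  # -3, -1, 1 cycle kept well inside range
      tr <- simulate_hgf(d, omega = omega, zeta = 4, seed = seed0 + s)
      fit <- fit_map("hgf", tr, n_restarts = 3, seed = s)
      abs(fit$estimates$omega - omega)
    }, numeric(1))
  }
  e_small <- errs(cfg_small, 12, 300)
  e_large <- errs(task_config(), 12, 300)
  expect_gte(median(e_small), median(e_large))
})
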