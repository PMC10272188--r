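test_that("HGF one-step update matches the hand calculation", {
  # omega = 0, u2_0 = 0, phi2_0 = 1, input 1; verified against a
  # straight-line reimplementation of the update equations
  tr <- hgf_filter(1L, omega = 0)
  expect_equal(tr$u1hat, 0.5)
  expect_equal(tr$phi1hat, 0.25)
  expect_equal(tr$phi2hat, 2)
  expect_equal(tr$phi2, 4 / 3)
  expect_equal(tr$delta1, 0.5)
  expect_equal(tr$u2, 2 / 3)
})

test_that("HGF filter matches an independent straight-line reimplementation", {
  set.seed(42)
  u1 <- rbinom(60, 1, 0.7)
  omega <- -1.5
  # independent oracle: literal sequential transcription
  u2 <- 0; phi2 <- 1
  oracle <- matrix(NA_real_, 60, 2)
  for (t in 1:60) {
    u1hat <- 1 / (1 + exp(-u2))
    phi2hat <- phi2 + exp(omega)
    phi2 <- 1 / (1 / phi2hat + u1hat * (1 - u1hat))
    u2 <- u2 + phi2 * (u1[t] - u1hat)
    oracle[t, ] <- c(u1hat, u2)
  }
  tr <- hgf_filter(u1, omega)
  expect_equal(tr$u1hat, oracle[, 1])
  expect_equal(tr$u2, oracle[, 2])
  expect_equal(tr$abs_delta1, abs(tr$u1 - tr$u1hat))
})

test_that("HGF invariants: bounded prediction, positive shrinking precision", {
  set.seed(1)
  tr <- hgf_filter(rbinom(200, 1, 0.5), omega = -2)
  expect_true(all(tr$u1hat > 0 & tr$u1hat < 1))
  expect_true(all(tr$phi2 > 0 & tr$phi2 < tr$phi2hat))
  expect_true(all(abs(tr$delta1) <= 1))
  # zero-PE fixed point: if u1hat equals the input the belief is unchanged
  still <- hgf_filter(c(1, 1), omega = 0, u2_0 = 30)  # u1hat ~ 1
  expect_lt(abs(still$u2[2] - still$u2[1]), 1e-8)
})

test_that("constant input drives the prediction monotonically toward 1", {
  tr <- hgf_filter(rep(1L, 200), omega = 0)
  expect_true(all(diff(tr$u1hat) > 0))
  expect_gt(tr$u1hat[200], 0.99)
})

test_that("larger omega gives larger average precision weight", {
  set.seed(2)
  u1 <- rbinom(300, 1, 0.7)
  means <- vapply(c(-4, -2, 0), function(om) mean(hgf_filter(u1, om)$phi2),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the belief update is a precision-weighted prediction error step", {
  # structural similarity to a delta-rule: u2 increments are exactly
  # phi2 * delta1, with phi2 playing the role of a per-trial learning rate
  set.seed(3)
  tr <- hgf_filter(rbinom(100, 1, 0.6), omega = -1)
  expect_equal(diff(c(0, tr$u2)), tr$phi2 * tr$delta1)
})

test_that("unit-square sigmoid has the right limits and values", {
  expect_equal(hgf_response_prob(0.5, 7), 0.5)
  expect_equal(hgf_response_prob(c(0.1, 0.9), 0), c(0.5, 0.5))
  expect_equal(hgf_response_prob(0.3, 1), 0.3)
  expect_equal(hgf_response_prob(0.7, 4), 0.7^4 / (0.7^4 + 0.3^4))
  expect_error(hgf_response_prob(0.5, -1), "zeta")
})

test_that("Rescorla-Wagner update and softmax match hand calculations", {
  expect_equal(rw_step(0.5, 1, 0.1), 0.55)
  expect_equal(rw_step(0.3, 0.3, 0.7), 0.3)  # r equal to V: fixed point
  expect_equal(rw_step(0.8, 1, 0), 0.8)      # alpha 0: no learning
  expect_error(rw_step(0.5, 1, 1.5), "alpha")
  expect_equal(softmax_prob(c(0.55, 0.45), 5)[1], 1 / (1 + exp(-0.5)))
  expect_equal(sum(softmax_prob(c(0.2, 0.9), 3)), 1)
  expect_equal(softmax_prob(c(0.1, 0.9), 0), c(0.5, 0.5))
  expect_error(softmax_prob(c(0.5, 0.5), -2), "beta")
})

test_that("all simulators emit valid per-trial choice probabilities", {
  d <- small_design(seed = 5)
  sims <- list(simulate_random(d, b = 0.3, seed = 1),
               simulate_wsls(d, epsilon = 0.1, seed = 1),
               simulate_rw(d, alpha = 0.2, beta = 5, seed = 1),
               simulate_hgf(d, omega = -2, zeta = 2, seed = 1))
  for (tr in sims) {
    expect_true(all(tr$p_choice >= 0 & tr$p_choice <= 1))
    expect_true(all(tr$y %in% 0:1))
    expect_identical(nrow(tr), 90L)
    # implied probability of the complementary mapping
    expect_equal(tr$p_choice + (1 - tr$p_choice), rep(1, nrow(tr)))
    # response derivation respects the chosen mapping
    go_expected <- (tr$stimulus == 1L) == (tr$y == 1L)
    expect_identical(tr$response, ifelse(go_expected, "Go", "NoGo"))
  }
})

test_that("random agent hits its bias and degenerate limits", {
  d <- default_design(seed = 6)
  tr <- simulate_random(d, b = 0.8, seed = 2)
  expect_lt(abs(mean(tr$y) - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(tr)))
  tr1 <- simulate_random(d, b = 1, seed = 2)
  expect_true(all(tr1$y == 1L))
  expect_equal(unname(p_staying(tr1)$p_stay_correct), 1)
})

test_that("deterministic WSLS reproduces the hand-enumerated sequence", {
  d <- generate_design(
    task_config(n_runs = 1, blocks_per_run = 1, trials_per_block = 5,
                reversal_window = c(3, 3), phase_len = 2), seed = 9)
  tr <- simulate_wsls(d, epsilon = 0, seed = 9)
  # trial 1 is uniform; afterwards the rule is deterministic:
  # stay after reward, switch after non-reward
  for (t in 2:5) {
    expected <- if (tr$outcome[t - 1] == 1L) tr$y[t - 1] else 1L - tr$y[t - 1]
    expect_identical(tr$y[t], expected)
    expect_equal(tr$p_choice[t], as.numeric(expected == 1L))
  }
})

test_that("WSLS stay probabilities equal 1 - eps/2 and eps/2", {
  d <- default_design(seed = 10)
  trs <- lapply(1:15, function(s) simulate_wsls(d, epsilon = 0.05, seed = s))
  ps <- p_staying(do.call(rbind, lapply(seq_along(trs), function(i) {
    trs[[i]]$subject <- i; trs[[i]]
  })))
  expect_lt(abs(ps$p_stay_correct - 0.975), 0.01)
  expect_lt(abs(ps$p_stay_wrong - 0.025), 0.01)
  # full lapse: stay probability 0.5 regardless of outcome
  full <- do.call(rbind, lapply(1:5, function(s) {
    simulate_wsls(d, epsilon = 1, seed = 20 + s, subject = s)
  }))
  ps1 <- p_staying(full)
  expect_lt(abs(ps1$p_stay_correct - 0.5), 0.05)
  expect_lt(abs(ps1$p_stay_wrong - 0.5), 0.05)
})

test_that("HGF agent with zeta = 0 behaves like an unbiased random agent", {
  d <- default_design(seed = 12)
  tr <- simulate_hgf(d, omega = -2, zeta = 0, seed = 3)
  expect_true(all(tr$p_choice == 0.5))
  ps <- p_staying(tr)
  expect_lt(abs(ps$p_stay_correct - 0.5), 0.07)
  expect_lt(abs(ps$p_stay_wrong - 0.5), 0.07)
})

test_that("a determined HGF agent is better in expert than naive phases", {
  accs <- list()
  for (s in 1:40) {
    d <- default_design(seed = 100 + s)
    omega <- as.numeric(bayes_optimal_params("hgf", d))
    tr <- simulate_hgf(d, omega = omega, zeta = 8, seed = s, subject = s)
    accs[[s]] <- proportion_correct_by_phase(tr)
  }
  acc <- do.call(rbind, accs)
  grp <- tapply(acc$accuracy, acc$phase, mean)
  expect_gt(grp[["LE"]], grp[["LN"]])
  expect_gt(grp[["RE"]], grp[["RN"]])
})

test_that("simulations are bit-identical under a fixed seed", {
  d <- small_design(seed = 13)
  expect_identical(simulate_hgf(d, omega = -2, zeta = 1, seed = 8),
                   simulate_hgf(d, omega = -2, zeta = 1, seed = 8))
  expect_identical(simulate_rw(d, alpha = 0.3, seed = 8),
                   simulate_rw(d, alpha = 0.3, seed = 8))
})

test_that("trajectory CSV round-trips the serialized columns", {
  d <- small_design(seed = 14)
  tr <- simulate_hgf(d, omega = -2, zeta = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(tr))
  expect_true(all(c("subject", "block", "trial", "u1", "u1hat", "u2",
                    "phi2", "delta1", "abs_delta1", "p_choice", "y",
                    "response", "outcome", "phase") %in% names(back)))
  expect_equal(back$u2, tr$u2)
})
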