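# Group-level model comparison over per-subject log-model evidences.

#' Per-subject log-evidence differences
#'
#' For a two-model evidence matrix, returns the per-subject difference
#' (first column minus second), the count of subjects favouring the first
#' model, and the group sum. Exponentiating a difference gives that
#' subject's Bayes factor.
#'
#' @param lme_matrix Numeric matrix, subjects x 2 models (column names are
#'   carried through if present).
#' @return List with `delta` (per subject), `n_favouring_first`, and
#'   `group_sum`.
#' @export
lme_diff <- function(lme_matrix) {
  lme_matrix <- as.matrix(lme_matrix)
  if (ncol(lme_matrix) != 2) stop("lme_matrix must have exactly 2 columns",
                                  call. = FALSE)
  if (any(!is.finite(lme_matrix))) stop("lme_matrix contains non-finite values",
                                        call. = FALSE)
  delta <- lme_matrix[, 1] - lme_matrix[, 2]
  list(delta = delta,
       n_favouring_first = sum(delta > 0),
       group_sum = sum(delta))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model a subject uses as a random effect with a Dirichlet
#' population distribution over models and estimates its posterior by the
#' standard variational scheme: subject responsibilities
#' `u_nk` proportional to `exp(lme_nk + digamma(alpha_k) - digamma(sum(alpha)))`
#' alternate with the concentration update `alpha_k = alpha0 + sum_n u_nk`
#' until the concentrations stop moving. Exceedance probabilities (the
#' posterior probability that each model is the most frequent in the
#' population) are estimated by Monte-Carlo over Dirichlet draws.
#'
#' @param lme_matrix Numeric matrix, subjects x models, of log-model
#'   evidences.
#' @param alpha0 Prior Dirichlet concentration (scalar, default 1:
#'   uniform).
#' @param n_samples Dirichlet draws for the exceedance estimate.
#' @param seed RNG seed for the draws.
#' @param tol Convergence threshold on `max |delta alpha|`.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A `bms_result`: `alpha` (posterior concentrations), `r`
#'   (expected model frequencies), `xp` (exceedance probabilities), `u`
#'   (subjects x models posterior assignment probabilities), and the
#'   iteration trace.
#' @export
rfx_bms <- function(lme_matrix, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 10000) {
  lme_matrix <- as.matrix(lme_matrix)
  K <- ncol(lme_matrix)
  if (K < 2) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(lme_matrix))) stop("lme_matrix contains non-finite values",
                                        call. = FALSE)
  if (alpha0 <= 0) stop("alpha0 must be positive", call. = FALSE)
  models <- colnames(lme_matrix) %||% paste0("model", seq_len(K))
  alpha <- rep(alpha0, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- sweep(lme_matrix, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    u <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(u)
    step <- max(abs(alpha_new - alpha))
    trace <- c(trace, step)
    alpha <- alpha_new
    if (step < tol) break
    if (it == max_iter) {
      stop("random-effects BMS did not converge after ", max_iter,
           " iterations (last step ", format(step), ")", call. = FALSE)
    }
  }
  r <- alpha / sum(alpha)
  set.seed(seed)
  draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  ncol = K)
  winner <- max.col(draws, ties.method = "first")
  xp <- tabulate(winner, nbins = K) / n_samples
  structure(
    list(alpha = stats::setNames(alpha, models),
         r = stats::setNames(r, models),
         xp = stats::setNames(xp, models),
         u = structure(u, dimnames = list(rownames(lme_matrix), models)),
         alpha0 = alpha0, n_samples = n_samples, iterations = length(trace),
         trace = trace),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  cat(sprintf("  %d subjects, %d models, converged in %d iterations\n",
              nrow(x$u), length(x$r), x$iterations))
  for (k in seq_along(x$r)) {
    cat(sprintf("  %-10s expected frequency %.3f, exceedance %.4f\n",
                names(x$r)[k], x$r[k], x$xp[k]))
  }
  invisible(x)
}
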