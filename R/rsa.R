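# Cross-phase representational similarity analysis.
#
# Condition-wise voxel patterns from a pre-reversal epoch (LE) are
# correlated with patterns from a post-reversal epoch (RN or RE), giving a
# non-symmetric 4x4 matrix over the outcome categories HIT/CR/FA/MISS.
# Binary model RDMs encode two hypotheses about which pre/post condition
# pairs should look alike: the stimulus-selective model (the same tactile
# pattern, whose outcome label flips across the reversal) and the
# outcome-selective model (the same outcome label).

#' Binary model RDM for stimulus- or outcome-selectivity
#'
#' Rows index pre-reversal conditions and columns post-reversal conditions
#' (HIT, CR, FA, MISS); 1 marks model-similar cells. The outcome-selective
#' model is the identity (HIT pre ~ HIT post, ...). The stimulus-selective
#' model pairs conditions that share the tactile pattern across the
#' reversal, where the contingency flip swaps the outcome labels:
#' HIT ~ CR, CR ~ HIT, FA ~ MISS, MISS ~ FA.
#'
#' @param selectivity `"stimulus"` or `"outcome"`.
#' @return A 4x4 binary matrix of class `model_rdm` with a `selectivity`
#'   attribute.
#' @export
model_rdm <- function(selectivity = c("stimulus", "outcome")) {
  selectivity <- match.arg(selectivity)
  m <- matrix(0L, 4, 4, dimnames = list(pre = .conditions,
                                        post = .conditions))
  if (selectivity == "outcome") {
    diag(m) <- 1L
  } else {
    m["HIT", "CR"] <- m["CR", "HIT"] <- 1L
    m["FA", "MISS"] <- m["MISS", "FA"] <- 1L
  }
  structure(m, selectivity = selectivity, class = c("model_rdm", "matrix",
                                                    "array"))
}

.as_condition_matrix <- function(x, who) {
  if (is.list(x)) x <- do.call(rbind, x[.conditions])
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- .conditions
  x <- x[.conditions, , drop = FALSE]
  if (ncol(x) < 3) stop(who, " patterns need at least 3 voxels", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant ", who, " pattern for condition ",
         paste(rownames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  x
}

#' Empirical cross-phase RDM from condition patterns
#'
#' Entry (i, j) is the Pearson correlation between the pre-epoch pattern of
#' condition i and the post-epoch pattern of condition j. Because pre and
#' post are different epochs the matrix is not symmetric and no symmetry is
#' enforced.
#'
#' @param pre,post Condition patterns for one subject: a 4 x n_voxels
#'   matrix with rownames HIT/CR/FA/MISS, or a named list of equal-length
#'   voxel vectors.
#' @return A 4x4 correlation matrix of class `cross_phase_rdm`.
#' @export
empirical_rdm <- function(pre, post) {
  pre <- .as_condition_matrix(pre, "pre")
  post <- .as_condition_matrix(post, "post")
  if (ncol(pre) != ncol(post)) {
    stop("pre and post must have the same voxel count", call. = FALSE)
  }
  r <- cor(t(pre), t(post))
  dimnames(r) <- list(pre = .conditions, post = .conditions)
  structure(r, class = c("cross_phase_rdm", "matrix", "array"))
}

#' Similar-minus-dissimilar RSA statistic
#'
#' Mean correlation over the model-similar cells minus the mean over the
#' model-dissimilar cells of a cross-phase RDM. Positive values indicate
#' that the data follow the model's similarity structure.
#'
#' @param rdm A 4x4 cross-phase correlation matrix.
#' @param model A [model_rdm()].
#' @return Scalar statistic.
#' @export
rsa_statistic <- function(rdm, model) {
  stopifnot(all(dim(rdm) == dim(model)))
  mean(rdm[model == 1L]) - mean(rdm[model == 0L])
}

# All 24 permutations of 1:4, rows of a matrix.
.perms4 <- local({
  perm <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm(v[-i]))
    }))
  }
  perm(1:4)
})

#' Group inference on per-subject RSA statistics
#'
#' Computes each subject's similar-minus-dissimilar statistic, then tests
#' the group two ways: a one-sided Wilcoxon signed-rank test for a positive
#' median, and a one-sided permutation test in which every subject's RDM
#' has its pre-epoch condition labels and (independently) its post-epoch
#' condition labels permuted on each iteration before the group mean
#' statistic is recomputed; the p-value is the smoothed fraction
#' `(b + 1) / (n_perm + 1)` of null group means at or above the observed
#' one. The reported effect size is the observed group-mean statistic.
#'
#' @param subject_rdms List of per-subject `cross_phase_rdm` matrices.
#' @param model A [model_rdm()].
#' @param n_perm Number of permutation iterations.
#' @param seed RNG seed for the permutation draws.
#' @return An `rsa_group_result`: `statistics` (per subject),
#'   `effect_size` (group mean), `p_signed_rank`, `p_permutation`,
#'   `n_perm`, and the permutation null means.
#' @export
group_inference <- function(subject_rdms, model, n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  stats_obs <- vapply(subject_rdms, rsa_statistic, numeric(1), model = model)
  obs_mean <- mean(stats_obs)
  sr <- wilcox.test(stats_obs, mu = 0, alternative = "greater",
                    exact = FALSE, correct = TRUE)
  # Independent row/column label permutations form a 24 x 24 set; the
  # statistic under each is precomputed so iterations reduce to indexing.
  n_pairs <- nrow(.perms4)^2
  stat_table <- vapply(subject_rdms, function(rdm) {
    as.vector(vapply(seq_len(nrow(.perms4)), function(i) {
      vapply(seq_len(nrow(.perms4)), function(j) {
        rsa_statistic(rdm[.perms4[i, ], .perms4[j, ]], model)
      }, numeric(1))
    }, numeric(nrow(.perms4))))
  }, numeric(n_pairs))
  set.seed(seed)
  S <- length(subject_rdms)
  idx <- matrix(sample.int(n_pairs, n_perm * S, replace = TRUE), ncol = S)
  null_means <- rowMeans(matrix(stat_table[cbind(as.vector(idx),
                                                 rep(seq_len(S),
                                                     each = n_perm))],
                                ncol = S))
  p_perm <- (sum(null_means >= obs_mean) + 1) / (n_perm + 1)
  structure(
    list(statistics = stats_obs,
         effect_size = obs_mean,
         p_signed_rank = sr$p.value,
         signed_rank_V = unname(sr$statistic),
         p_permutation = p_perm,
         n_perm = n_perm,
         null_means = null_means,
         selectivity = attr(model, "selectivity")),
    class = "rsa_group_result")
}

#' @export
print.rsa_group_result <- function(x, ...) {
  cat(sprintf("RSA group inference (%s model, %d subjects)\n",
              x$selectivity %||% "?", length(x$statistics)))
  cat(sprintf("  effect size (mean similar - dissimilar) = %.3f\n",
              x$effect_size))
  cat(sprintf("  signed-rank p = %.4g, permutation p = %.4g (%d iterations)\n",
              x$p_signed_rank, x$p_permutation, x$n_perm))
  invisible(x)
}

# Condition -> tactile pattern, per epoch. Pre-reversal the Go pattern (A)
# yields HITs and MISSes; post-reversal the roles swap.
.cond_pattern <- list(
  pre = c(HIT = "A", CR = "B", FA = "B", MISS = "A"),
  post = c(HIT = "B", CR = "A", FA = "A", MISS = "B"))

#' Generate synthetic condition-wise voxel patterns
#'
#' Per subject, condition vectors are built from two additive codes plus
#' voxel noise: a stimulus code (one template per tactile pattern, shared
#' by the conditions that present the same pattern across the reversal)
#' and an outcome code (one template per outcome category, shared across
#' epochs). `stim_signal` and `outcome_signal` scale the two codes;
#' templates are drawn fresh per subject.
#'
#' @param n_subjects Number of subjects.
#' @param n_voxels Voxels per pattern.
#' @param stim_signal,outcome_signal Non-negative code amplitudes.
#' @param noise_sd Gaussian voxel noise SD (> 0).
#' @param epoch_pair Label recorded with the patterns (`"LE-RN"` or
#'   `"LE-RE"`); the generative structure is the same for both.
#' @param seed RNG seed.
#' @return List of subjects, each a list with `pre` and `post` 4 x
#'   `n_voxels` condition matrices.
#' @export
synth_patterns <- function(n_subjects, n_voxels = 100, stim_signal = 1,
                           outcome_signal = 1, noise_sd = 1,
                           epoch_pair = c("LE-RN", "LE-RE"), seed = 1) {
  epoch_pair <- match.arg(epoch_pair)
  stopifnot(stim_signal >= 0, outcome_signal >= 0, noise_sd > 0,
            n_voxels >= 3)
  set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    stim_templates <- list(A = rnorm(n_voxels), B = rnorm(n_voxels))
    out_templates <- lapply(stats::setNames(.conditions, .conditions),
                            function(cc) rnorm(n_voxels))
    make_epoch <- function(epoch) {
      m <- t(vapply(.conditions, function(cc) {
        stim_signal * stim_templates[[.cond_pattern[[epoch]][cc]]] +
          outcome_signal * out_templates[[cc]] +
          rnorm(n_voxels, sd = noise_sd)
      }, numeric(n_voxels)))
      rownames(m) <- .conditions
      m
    }
    list(pre = make_epoch("pre"), post = make_epoch("post"))
  })
  attr(subjects, "epoch_pair") <- epoch_pair
  subjects
}
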