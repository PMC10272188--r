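# Model-independent behavioural summaries.

#' Probability of repeating the previous choice, by previous outcome
#'
#' "Staying" means repeating the latent mapping choice `y` from the
#' previous trial (not the motor Go/NoGo, which flips with the stimulus).
#' The first trial of each block is excluded, and the stay probability is
#' conditioned on whether the previous trial was rewarded. A conditional
#' with no qualifying trials is returned as `NA` (undefined), never 0.
#'
#' @param trials Trial tibble with `block`, `y`, `outcome` (and `subject`;
#'   trials are pooled).
#' @return List with `p_stay_correct`, `p_stay_wrong` and the trial counts
#'   behind each (`n_correct`, `n_wrong`).
#' @export
p_staying <- function(trials) {
  stay <- prev_outcome <- logical(0)
  groups <- interaction(trials$subject %||% 1L, trials$block, drop = TRUE)
  for (ix in split(seq_len(nrow(trials)), groups)) {
    if (length(ix) < 2) next
    y <- trials$y[ix]; r <- trials$outcome[ix]
    stay <- c(stay, y[-1] == y[-length(y)])
    prev_outcome <- c(prev_outcome, r[-length(r)] == 1L)
  }
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  list(p_stay_correct = mean_or_na(stay[prev_outcome]),
       p_stay_wrong = mean_or_na(stay[!prev_outcome]),
       n_correct = sum(prev_outcome),
       n_wrong = sum(!prev_outcome))
}

#' Proportion of correct responses per learning phase
#'
#' "Correct" means the chosen mapping matches the prevailing contingency's
#' better option (`y == rule`), not that the probabilistic reward was
#' actually received -- a perfect agent therefore scores 1 even though only
#' 70\% of its trials are rewarded.
#'
#' @param trials Trial tibble with `subject`, `phase`, `y`, `rule`.
#' @param phases Phases to summarize.
#' @return Tibble with one row per subject x phase: `subject`, `phase`,
#'   `accuracy`, `n_trials`.
#' @export
proportion_correct_by_phase <- function(trials,
                                        phases = c("LN", "LE", "RN", "RE")) {
  trials <- trials[trials$phase %in% phases, ]
  correct <- as.integer(trials$y == trials$rule)
  out <- expand.grid(subject = sort(unique(trials$subject)), phase = phases,
                     stringsAsFactors = FALSE)
  out$accuracy <- NA_real_
  out$n_trials <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- trials$subject == out$subject[i] & trials$phase == out$phase[i]
    if (!any(sel)) {
      stop("phase ", out$phase[i], " is empty for subject ", out$subject[i],
           call. = FALSE)
    }
    out$accuracy[i] <- mean(correct[sel])
    out$n_trials[i] <- sum(sel)
  }
  tibble::as_tibble(out)
}

#' Paired phase comparisons of accuracy
#'
#' Two-sided paired t-tests of per-subject phase accuracies, by default
#' expert vs naive within each learning period (LE vs LN, RE vs RN).
#'
#' @param phase_accuracy Output of [proportion_correct_by_phase()] over
#'   multiple subjects.
#' @param pairs List of length-2 character vectors `(a, b)`; each test is
#'   of `accuracy(a) - accuracy(b)`.
#' @return Tibble with `contrast`, `mean_diff`, `t`, `df`, `p_value`.
#' @export
compare_phases <- function(phase_accuracy,
                           pairs = list(c("LE", "LN"), c("RE", "RN"))) {
  rows <- lapply(pairs, function(pr) {
    a <- phase_accuracy[phase_accuracy$phase == pr[1], ]
    b <- phase_accuracy[phase_accuracy$phase == pr[2], ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    tt <- stats::t.test(a$accuracy, b$accuracy, paired = TRUE)
    tibble::tibble(contrast = paste(pr[1], "-", pr[2]),
                   mean_diff = unname(tt$estimate),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Reversal-aligned accuracy curve
#'
#' Aligns every block at its reversal trial (offset 0 = first trial under
#' the reversed rule) and averages the correct-response indicator across
#' blocks and subjects at each offset, from `-pre_window` to
#' `post_window - 1`. Offsets not covered by some blocks are averaged over
#' the blocks that reach them; a window no block covers triggers a warning
#' and is dropped.
#'
#' @param trials Trial tibble with `block`, `trial`, `reversal`, `y`,
#'   `rule` (and optionally `subject`).
#' @param pre_window Trials before the reversal to include.
#' @param post_window Trials from the reversal on to include.
#' @return Tibble with `offset`, `accuracy`, `n` (observations per
#'   offset).
#' @export
reversal_aligned_curve <- function(trials, pre_window = 19, post_window = 20) {
  offset <- trials$trial - trials$reversal
  keep <- offset >= -pre_window & offset < post_window
  offsets <- seq(-pre_window, post_window - 1)
  if (!all(offsets %in% offset[keep])) {
    warning("requested window extends beyond the block bounds; ",
            "truncating to observed offsets")
    offsets <- intersect(offsets, sort(unique(offset[keep])))
  }
  correct <- as.integer(trials$y == trials$rule)[keep]
  off_k <- offset[keep]
  acc <- vapply(offsets, function(o) mean(correct[off_k == o]), numeric(1))
  n <- vapply(offsets, function(o) sum(off_k == o), integer(1))
  tibble::tibble(offset = offsets, accuracy = acc, n = n)
}
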