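#' Classify stop trials
#'
#' A stop trial is one in which the stimulus spends at least the minimum
#' hold time in the reward zone; boundary equality counts as a stop.
#'
#' @param trials a [trial_table()].
#' @param hold_threshold minimum hold time, seconds (> 0).
#' @return the trial table with its `stop` column set.
#' @export
classify_stops <- function(trials, hold_threshold) {
  check_positive_scalar(hold_threshold, "hold_threshold")
  trials <- validate_trial_table(trials)
  trials$stop <- trials$hold_time >= hold_threshold
  trials
}

#' Behavioral choice accuracy
#'
#' Accuracy is the average of the percentage of stop trials upon target
#' presentation and the percentage of non-stop trials upon distractor
#' presentation; chance level is 50%. Stimulus-independent stopping gives
#' 50% in expectation whatever the stop rate, because the two per-class
#' rates are complementary.
#'
#' @param trials a [trial_table()] with stop flags set (see
#'   [classify_stops()]).
#' @return accuracy in percent, in `[0, 100]`.
#' @export
choice_accuracy <- function(trials) {
  trials <- validate_trial_table(trials)
  if (any(is.na(trials$stop)))
    stop("stop flags not set; run classify_stops() first", call. = FALSE)
  tgt <- trials$stimulus == "target"
  if (!any(tgt)) stop("no target trials", call. = FALSE)
  if (all(tgt)) stop("no distractor trials", call. = FALSE)
  100 * (mean(trials$stop[tgt]) + mean(!trials$stop[!tgt])) / 2
}

#' Ideal-observer ROC on reward-zone hold times
#'
#' The discrimination accuracy of an ideal observer who sees only the time
#' each stimulus spent in the reward zone: `P(T > D) + 0.5 P(T = D)` over
#' all target/distractor cross pairs. This is sensitive to differences in
#' the animal's behavior that the binary stop/non-stop classification does
#' not capture.
#'
#' @param holds_target,holds_distractor non-empty numeric vectors of hold
#'   times, seconds.
#' @return AUC in `[0, 1]`.
#' @export
ideal_observer_auc <- function(holds_target, holds_distractor) {
  if (length(holds_target) == 0 || length(holds_distractor) == 0)
    stop("ideal_observer_auc: empty sample", call. = FALSE)
  auc_cross(holds_target, holds_distractor)
}

#' Rank-sum test on choice data
#'
#' Two-sided Wilcoxon rank-sum test on the reward-zone hold times of target
#' versus distractor trials (exact for small samples, tie-corrected normal
#' approximation otherwise; see [ranksum_test()]).
#'
#' @param trials a [trial_table()].
#' @return the two-sided p-value.
#' @export
choice_ranksum <- function(trials) {
  trials <- validate_trial_table(trials)
  tgt <- trials$hold_time[trials$stimulus == "target"]
  dst <- trials$hold_time[trials$stimulus == "distractor"]
  if (length(tgt) == 0 || length(dst) == 0)
    stop("choice_ranksum: both stimulus classes must be present",
         call. = FALSE)
  ranksum_test(tgt, dst)$p.value
}

#' Exact binomial 95% confidence interval
#'
#' Clopper-Pearson interval for a stop probability estimated from `k`
#' stops out of `n` trials. The lower bound is 0 when `k = 0` and the
#' upper bound is 1 when `k = n`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @return numeric vector `c(lower, upper)`.
#' @export
binomial_ci95 <- function(k, n) {
  if (n < 1) stop("binomial_ci95: n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("binomial_ci95: k must lie in [0, n]",
                           call. = FALSE)
  lower <- if (k == 0) 0 else stats::qbeta(0.025, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(0.975, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Summarize a behavioral session
#'
#' Computes the stop probabilities with exact binomial confidence
#' intervals, the choice accuracy, the ideal-observer ROC value on hold
#' times and the rank-sum p-value for one session.
#'
#' @param trials a [trial_table()].
#' @param hold_threshold minimum hold time for a stop, seconds.
#' @return a list of class `behavior_summary`.
#' @export
behavior_summary <- function(trials, hold_threshold) {
  trials <- classify_stops(trials, hold_threshold)
  tgt <- trials$stimulus == "target"
  k_t <- sum(trials$stop[tgt]); n_t <- sum(tgt)
  k_d <- sum(trials$stop[!tgt]); n_d <- sum(!tgt)
  out <- list(
    n_trials = nrow(trials),
    stop_prob_target = k_t / n_t,
    stop_prob_target_ci = binomial_ci95(k_t, n_t),
    stop_prob_distractor = k_d / n_d,
    stop_prob_distractor_ci = binomial_ci95(k_d, n_d),
    accuracy = choice_accuracy(trials),
    ideal_observer_auc = ideal_observer_auc(trials$hold_time[tgt],
                                            trials$hold_time[!tgt]),
    ranksum_p = choice_ranksum(trials)
  )
  class(out) <- "behavior_summary"
  out
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(paste0("<behavior_summary> %d trials | accuracy %.1f%% | ",
                     "P(stop|target) %.2f [%.2f, %.2f] | ",
                     "P(stop|distractor) %.2f [%.2f, %.2f]\n",
                     "  ideal-observer AUC %.3f | rank-sum p %.3g\n"),
              x$n_trials, x$accuracy,
              x$stop_prob_target, x$stop_prob_target_ci[1],
              x$stop_prob_target_ci[2],
              x$stop_prob_distractor, x$stop_prob_distractor_ci[1],
              x$stop_prob_distractor_ci[2],
              x$ideal_observer_auc, x$ranksum_p))
  invisible(x)
}
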