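#' Per-trial first-spike latencies
#'
#' Times of the first spike in the window `(onset, onset + horizon]` per
#' trial, in ms relative to cortical onset. Trials with no spike in the
#' window are omitted, not zero-filled; the omitted fraction is reported
#' as an attribute.
#'
#' @param unit a [unit_recording()].
#' @param onset_ms cortical onset, ms from stimulus onset.
#' @param horizon_ms latency horizon, ms (default 300).
#' @param trial_ids trials to use (default: all the unit's trials).
#' @return numeric vector of latencies in `(0, horizon_ms]`, with
#'   attribute `fraction_silent`.
#' @export
first_spike_latencies <- function(unit, onset_ms, horizon_ms = 300,
                                  trial_ids = names(unit$spikes)) {
  check_positive_scalar(horizon_ms, "horizon_ms")
  lo <- onset_ms / 1000
  hi <- (onset_ms + horizon_ms) / 1000
  ids <- as.character(trial_ids)
  lat <- vapply(unit$spikes[ids], function(s) {
    s <- s[s > lo & s <= hi]
    if (length(s) > 0) 1000 * (s[1] - lo) else NA_real_
  }, 0)
  out <- lat[!is.na(lat)]
  attr(out, "fraction_silent") <- mean(is.na(lat))
  out
}

#' Paired first-spike latency difference across units
#'
#' For each unit, the difference between the mean first-spike time for the
#' preferred and the non-preferred stimulus is computed; a one-sample
#' two-sided Student's t-test asks whether the mean of these per-unit
#' differences departs from zero. The convention here is
#' non-preferred minus preferred, so a positive difference means the
#' preferred stimulus evokes the earlier first spike.
#'
#' @param latency_pairs a list, one element per unit, each a list with
#'   numeric vectors `preferred` and `nonpreferred` of per-trial first-spike
#'   latencies (ms). Units missing either class are dropped.
#' @return a list with `mean_difference_ms`, `p`, `conf_int` (95%),
#'   `differences` (per retained unit) and `n_units`.
#' @export
latency_difference_test <- function(latency_pairs) {
  diffs <- vapply(latency_pairs, function(u) {
    if (length(u$preferred) == 0 || length(u$nonpreferred) == 0)
      return(NA_real_)
    mean(u$nonpreferred) - mean(u$preferred)
  }, 0)
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2)
    stop("latency_difference_test: need >= 2 units with latencies for both ",
         "stimuli", call. = FALSE)
  tt <- stats::t.test(diffs)
  list(mean_difference_ms = mean(diffs), p = tt$p.value,
       conf_int = as.numeric(tt$conf.int), differences = diffs,
       n_units = length(diffs))
}

#' Collect per-unit preferred/non-preferred latencies
#'
#' Convenience wrapper: splits each unit's trials by its preferred
#' stimulus (from a discrimination result or an explicit preference
#' vector) and extracts first-spike latencies for both classes.
#'
#' @param units list of [unit_recording()] objects.
#' @param trials a [trial_table()].
#' @param preferences named character vector (`"target"`/`"distractor"`)
#'   per unit id; units with other values are skipped.
#' @param onset_ms cortical onset, ms.
#' @param horizon_ms latency horizon, ms.
#' @return a list suitable for [latency_difference_test()].
#' @export
collect_latency_pairs <- function(units, trials, preferences, onset_ms,
                                  horizon_ms = 300) {
  trials <- validate_trial_table(trials)
  tgt <- as.character(trials$trial_id[trials$stimulus == "target"])
  dst <- as.character(trials$trial_id[trials$stimulus == "distractor"])
  out <- list()
  for (u in units) {
    pref <- preferences[[u$unit_id]]
    if (is.null(pref) || !pref %in% c("target", "distractor")) next
    pref_ids <- if (pref == "target") tgt else dst
    non_ids <- if (pref == "target") dst else tgt
    out[[u$unit_id]] <- list(
      preferred = as.numeric(first_spike_latencies(u, onset_ms, horizon_ms,
                                                   pref_ids)),
      nonpreferred = as.numeric(first_spike_latencies(u, onset_ms,
                                                      horizon_ms, non_ids)))
  }
  out
}

#' Poisson fit to a spike-count distribution
#'
#' Fits a Poisson with `lambda` equal to the sample mean and quantifies
#' how well the predicted pmf explains the empirical count histogram:
#' `r2 = 1 - SS_res / SS_tot` over the observed support `0..max(counts)`,
#' with proportions as the response. A degenerate all-equal histogram
#' (e.g. all counts zero) that the prediction matches is reported as
#' `r2 = 1`.
#'
#' @param counts non-negative integer spike counts, `n >= 1`.
#' @return a list of class `poisson_fit`: `lambda`, `support`, `empirical`,
#'   `predicted`, `r2`, `n`.
#' @export
poisson_fit <- function(counts) {
  if (length(counts) == 0) stop("poisson_fit: empty counts", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("poisson_fit: counts must be non-negative integers", call. = FALSE)
  lambda <- mean(counts)
  support <- 0:max(counts)
  emp <- as.numeric(table(factor(counts, levels = support))) / length(counts)
  pred <- stats::dpois(support, lambda)
  ss_tot <- sum((emp - mean(emp))^2)
  ss_res <- sum((emp - pred)^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else -Inf
  } else 1 - ss_res / ss_tot
  structure(list(lambda = lambda, support = support, empirical = emp,
                 predicted = pred, r2 = r2, n = length(counts)),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> lambda = %.3f, R^2 = %.3f (n = %d)\n",
              x$lambda, x$r2, x$n))
  invisible(x)
}

#' Convert a mean spike count to a firing rate
#'
#' @param mean_count mean spikes per window.
#' @param window_ms window length in ms (> 0).
#' @return rate in Hz. For example, 0.6 spikes per 80 ms is 7.5 Hz.
#' @export
count_to_rate <- function(mean_count, window_ms) {
  check_positive_scalar(window_ms, "window_ms")
  mean_count / (window_ms / 1000)
}

#' Peristimulus time histogram
#'
#' Mean spike count per bin across trials, in half-open bins aligned to
#' stimulus onset. The total mass times the trial count equals the number
#' of spikes inside the analysis span.
#'
#' @param unit a [unit_recording()].
#' @param trial_ids trials to average over (default all).
#' @param bin_ms bin width, ms (default 25).
#' @param span_ms two-element vector, histogram extent in ms around
#'   stimulus onset; rounded outward to whole bins.
#' @return a `data.frame` with `bin_start_ms`, `bin_end_ms`, `mean_count`.
#' @export
psth <- function(unit, trial_ids = names(unit$spikes), bin_ms = 25,
                 span_ms = c(-100, 400)) {
  check_positive_scalar(bin_ms, "bin_ms")
  ids <- as.character(trial_ids)
  lo <- floor(span_ms[1] / bin_ms) * bin_ms
  hi <- ceiling(span_ms[2] / bin_ms) * bin_ms
  edges <- seq(lo, hi, by = bin_ms)
  n_bins <- length(edges) - 1
  total <- numeric(n_bins)
  for (id in ids) {
    s_ms <- 1000 * unit$spikes[[id]]
    s_ms <- s_ms[s_ms >= lo & s_ms < hi]
    if (length(s_ms) > 0) {
      b <- findInterval(s_ms, edges, rightmost.closed = FALSE)
      tb <- tabulate(b, nbins = n_bins)
      total <- total + tb
    }
  }
  data.frame(bin_start_ms = edges[-length(edges)], bin_end_ms = edges[-1],
             mean_count = total / length(ids))
}

#' Fractions of trials by spike count
#'
#' Reports, for per-trial counts in a window, the fraction of trials with
#' zero or one spike, with exactly two, and with more than two -- the
#' summary used to characterize how sparsely units fire within the
#' threshold window.
#'
#' @param counts per-trial spike counts.
#' @return named numeric vector
#'   (`le1`, `eq2`, `gt2`), as proportions.
#' @export
count_fractions <- function(counts) {
  c(le1 = mean(counts <= 1), eq2 = mean(counts == 2),
    gt2 = mean(counts > 2))
}
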