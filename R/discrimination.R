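#' Spike counts in a post-onset window
#'
#' Counts spikes per trial in the half-open window
#' `[onset, onset + interval)` ms after stimulus onset.
#'
#' @param unit a [unit_recording()].
#' @param trial_ids trial ids (coerced to character) to count over;
#'   defaults to all the unit's trials.
#' @param onset_ms cortical response onset, ms from stimulus onset.
#' @param interval_ms window length, ms (> 0).
#' @return named integer vector of per-trial counts.
#' @export
count_in_window <- function(unit, trial_ids = names(unit$spikes), onset_ms,
                            interval_ms) {
  check_positive_scalar(interval_ms, "interval_ms")
  lo <- onset_ms / 1000
  hi <- (onset_ms + interval_ms) / 1000
  ids <- as.character(trial_ids)
  missing <- setdiff(ids, names(unit$spikes))
  if (length(missing) > 0)
    stop(sprintf("unit %s has no trial(s) %s", unit$unit_id,
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  vapply(unit$spikes[ids], function(s) sum(s >= lo & s < hi), 0L)
}

#' Per-unit windowed ROC value and rank-sum p
#'
#' Computes the area under the ROC curve separating the two spike-count
#' distributions -- `P(a > b) + 0.5 P(a = b)` with midrank tie handling --
#' together with the two-sided rank-sum p-value on the raw counts.
#'
#' @param counts_a,counts_b per-trial spike counts for the two stimulus
#'   classes (typically preferred first, so AUC >= 0.5).
#' @return a list with `auc` and `p`.
#' @export
unit_auc <- function(counts_a, counts_b) {
  if (length(counts_a) == 0 || length(counts_b) == 0)
    stop("unit_auc: both count vectors must be non-empty", call. = FALSE)
  list(auc = auc_cross(counts_a, counts_b),
       p = ranksum_test(counts_a, counts_b)$p.value)
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending, finds the largest rank `i` with
#' `p_(i) <= (i/m) * fdr`, and flags every p-value at or below that
#' `p_(i)`, which is reported as the effective cutoff (`NA` when nothing is
#' selected).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param fdr target false-discovery rate.
#' @return a list with logical `selected` (same order as `pvals`) and
#'   `cutoff`.
#' @export
bh_select <- function(pvals, fdr = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("bh_select: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  if (m == 0) return(list(selected = logical(0), cutoff = NA_real_))
  ord <- sort(pvals)
  ok <- which(ord <= seq_len(m) / m * fdr)
  if (length(ok) == 0)
    return(list(selected = rep(FALSE, m), cutoff = NA_real_))
  cutoff <- ord[max(ok)]
  list(selected = pvals <= cutoff, cutoff = cutoff)
}

#' Low-rate unit exclusion
#'
#' Excludes units that fired fewer than 1 spike every `1/rate_threshold`
#' trials over the initial 300 ms from cortical onset (default threshold
#' 1/6 spikes/trial, pooled across all trials), since the rank-sum ROC
#' analysis is insensitive at such rates.
#'
#' @param units list of [unit_recording()] objects.
#' @param onset_ms cortical onset, ms.
#' @param rate_threshold minimum mean spikes/trial over 300 ms.
#' @param window_ms length of the assessment window (default 300).
#' @return a list with `retained` and `excluded` unit lists and
#'   `mean_counts` (named, all units).
#' @export
exclusion_filter <- function(units, onset_ms, rate_threshold = 1 / 6,
                             window_ms = 300) {
  mean_counts <- vapply(units, function(u) {
    mean(count_in_window(u, onset_ms = onset_ms, interval_ms = window_ms))
  }, 0)
  names(mean_counts) <- vapply(units, `[[`, "", "unit_id")
  keep <- mean_counts >= rate_threshold
  list(retained = units[keep], excluded = units[!keep],
       mean_counts = mean_counts)
}

#' Windowed discrimination analysis of a population
#'
#' For every retained unit and every interval of the grid, computes the
#' spike-count ROC value (oriented to the unit's preferred stimulus, so
#' AUC >= 0.5 at the 300 ms window) and the two-sided rank-sum p-value.
#' A unit is *discriminating* if its 300 ms p-value survives
#' Benjamini-Hochberg selection across units; the selection's effective
#' cutoff is then reused at the earlier intervals, so a discriminating
#' unit counts as discriminating at interval `t` iff its rank-sum p at `t`
#' falls below that same cutoff. By construction the fraction of
#' discriminating units that discriminate at 300 ms is 1. Preference is
#' the sign of the target-minus-distractor mean count difference at
#' 300 ms, ties assigned to target.
#'
#' @param units list of [unit_recording()] objects (apply
#'   [exclusion_filter()] first if desired).
#' @param trials a [trial_table()].
#' @param onset_ms cortical onset, ms from stimulus onset.
#' @param interval_grid increasing window ends in ms; must contain 300.
#' @param fdr Benjamini-Hochberg false-discovery rate.
#' @return a list of class `discrimination_result` with elements `table`
#'   (data.frame: unit_id, interval_ms, auc, p, discriminating_at,
#'   mean_count_target, mean_count_distractor), `units` (per-unit summary
#'   with preference and discriminating flag), `fraction_discriminating`
#'   (data.frame interval_ms, fraction over discriminating units),
#'   `effective_cutoff` and `onset_ms`.
#' @export
discrimination_curve <- function(units, trials, onset_ms,
                                 interval_grid = seq(20, 300, by = 20),
                                 fdr = 0.05) {
  if (!300 %in% interval_grid)
    stop("interval_grid must contain the 300 ms defining window",
         call. = FALSE)
  trials <- validate_trial_table(trials)
  check_units_trials(units, trials)
  tgt_ids <- as.character(trials$trial_id[trials$stimulus == "target"])
  dst_ids <- as.character(trials$trial_id[trials$stimulus == "distractor"])
  if (length(tgt_ids) == 0 || length(dst_ids) == 0)
    stop("both stimulus classes must be present", call. = FALSE)

  n_u <- length(units)
  unit_ids <- vapply(units, `[[`, "", "unit_id")

  # preference from the 300 ms window
  c300_t <- lapply(units, count_in_window, trial_ids = tgt_ids,
                   onset_ms = onset_ms, interval_ms = 300)
  c300_d <- lapply(units, count_in_window, trial_ids = dst_ids,
                   onset_ms = onset_ms, interval_ms = 300)
  pref <- ifelse(vapply(c300_t, mean, 0) >= vapply(c300_d, mean, 0),
                 "target", "distractor")

  rows <- vector("list", n_u * length(interval_grid))
  p300 <- numeric(n_u)
  k <- 1L
  for (i in seq_len(n_u)) {
    for (iv in interval_grid) {
      ct <- count_in_window(units[[i]], tgt_ids, onset_ms, iv)
      cd <- count_in_window(units[[i]], dst_ids, onset_ms, iv)
      res <- if (pref[i] == "target") unit_auc(ct, cd) else unit_auc(cd, ct)
      if (iv == 300) p300[i] <- res$p
      rows[[k]] <- data.frame(
        unit_id = unit_ids[i], interval_ms = iv, auc = res$auc, p = res$p,
        mean_count_target = mean(ct), mean_count_distractor = mean(cd),
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  tab <- do.call(rbind, rows)

  sel <- bh_select(p300, fdr)
  discriminating <- stats::setNames(sel$selected, unit_ids)
  tab$discriminating_at <- discriminating[tab$unit_id] &
    !is.na(sel$cutoff) & tab$p <= sel$cutoff

  frac <- vapply(interval_grid, function(iv) {
    sub <- tab[tab$interval_ms == iv, ]
    if (sum(discriminating) == 0) return(0)
    sum(sub$discriminating_at) / sum(discriminating)
  }, 0)

  structure(list(
    table = tab,
    units = data.frame(unit_id = unit_ids, preference = pref,
                       p300 = p300, discriminating = unname(discriminating),
                       stringsAsFactors = FALSE),
    fraction_discriminating = data.frame(interval_ms = interval_grid,
                                         fraction = frac),
    effective_cutoff = sel$cutoff,
    onset_ms = onset_ms,
    fdr = fdr
  ), class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  nd <- sum(x$units$discriminating)
  cat(sprintf(paste0("<discrimination_result> %d units, %d discriminating ",
                     "(%.0f%%), BH cutoff p <= %s\n"),
              nrow(x$units), nd, 100 * nd / nrow(x$units),
              format(x$effective_cutoff, digits = 3)))
  invisible(x)
}

#' Reduce a unit to its first post-onset spike per trial
#'
#' Removes baseline spikes (before cortical onset) and keeps at most the
#' first spike at or after the onset in each trial, for the first-spike
#' variant of the ROC analysis. Idempotent.
#'
#' @param unit a [unit_recording()].
#' @param onset_ms cortical onset, ms from stimulus onset.
#' @return a [unit_recording()] whose trials hold at most one spike.
#' @export
first_spike_reduce <- function(unit, onset_ms) {
  lo <- onset_ms / 1000
  spikes <- lapply(unit$spikes, function(s) {
    s <- s[s >= lo]
    if (length(s) > 0) s[1] else numeric(0)
  })
  unit_recording(unit$unit_id, spikes, unit$putative_type, unit$layer)
}
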