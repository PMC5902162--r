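#' Build a count pool for the pooling-neuron analysis
#'
#' Reduces units to per-trial spike counts in the analysis window, split
#' by stimulus class and oriented to each unit's preferred stimulus
#' (distractor-preferring units have their class labels swapped, see
#' [flip_preference()]), so that pooling sums signal rather than
#' cancelling it.
#'
#' @param units list of [unit_recording()] objects.
#' @param trials a [trial_table()].
#' @param onset_ms cortical onset, ms.
#' @param window_ms analysis window length, ms (e.g. 80).
#' @param preferences named character vector of preferred stimuli per unit
#'   id (from [discrimination_curve()]); units with unknown preference are
#'   treated as target-preferring.
#' @return a list of class `count_pool`; each element has `pref` and
#'   `nonpref` count vectors plus `source_id` and `copy` provenance.
#' @export
pool_counts <- function(units, trials, onset_ms, window_ms,
                        preferences = NULL) {
  trials <- validate_trial_table(trials)
  tgt <- as.character(trials$trial_id[trials$stimulus == "target"])
  dst <- as.character(trials$trial_id[trials$stimulus == "distractor"])
  pool <- lapply(units, function(u) {
    ct <- count_in_window(u, tgt, onset_ms, window_ms)
    cd <- count_in_window(u, dst, onset_ms, window_ms)
    pref <- if (!is.null(preferences)) preferences[[u$unit_id]] else "target"
    pu <- list(pref = unname(ct), nonpref = unname(cd),
               source_id = u$unit_id, copy = 0L)
    if (identical(pref, "distractor")) pu <- flip_preference(pu)
    pu
  })
  class(pool) <- "count_pool"
  pool
}

#' Swap the stimulus classes of a pooled unit
#'
#' For units preferring the distractor, the target and distractor
#' responses are switched before pooling, so every pooled unit is oriented
#' the same way. Applying the flip twice restores the original.
#'
#' @param pool_unit one element of a [pool_counts()] pool.
#' @return the unit with `pref` and `nonpref` swapped.
#' @export
flip_preference <- function(pool_unit) {
  tmp <- pool_unit$pref
  pool_unit$pref <- pool_unit$nonpref
  pool_unit$nonpref <- tmp
  pool_unit
}

#' Shuffle-augment a pool of units
#'
#' Artificially enlarges the pool by creating `n_copies` surrogate units
#' per source unit, each obtained by randomly permuting the source's
#' trials. By default the permutation acts within each stimulus class
#' (target trials shuffled among target trials, distractor among
#' distractor), which preserves every unit's stimulus-conditioned
#' count distribution exactly while breaking trial-to-trial noise
#' alignment across units; `within_class = FALSE` permutes trials across
#' classes instead. The augmented pool has `(n_copies + 1) * length(pool)`
#' units: 72 sources with 6 copies give 504.
#'
#' @param pool a [pool_counts()] pool.
#' @param n_copies surrogate copies per source unit (default 6).
#' @param seed integer seed.
#' @param within_class permute within stimulus class (default `TRUE`).
#' @return the augmented `count_pool`.
#' @export
augment_pool <- function(pool, n_copies = 6, seed = 1L,
                         within_class = TRUE) {
  stopifnot(n_copies >= 0)
  withr::with_seed(seed, {
    out <- vector("list", (n_copies + 1) * length(pool))
    k <- 1L
    for (u in pool) {
      out[[k]] <- u
      k <- k + 1L
      for (cp in seq_len(n_copies)) {
        v <- u
        if (within_class) {
          v$pref <- sample(u$pref)
          v$nonpref <- sample(u$nonpref)
        } else {
          all_counts <- sample(c(u$pref, u$nonpref))
          v$pref <- all_counts[seq_along(u$pref)]
          v$nonpref <- all_counts[-seq_along(u$pref)]
        }
        v$copy <- cp
        out[[k]] <- v
        k <- k + 1L
      }
    }
    class(out) <- "count_pool"
    out
  })
}

#' @export
print.count_pool <- function(x, ...) {
  cat(sprintf("<count_pool> %d units (%d sources), %d + %d trials/unit\n",
              length(x), length(unique(vapply(x, `[[`, "", "source_id"))),
              length(x[[1]]$pref), length(x[[1]]$nonpref)))
  invisible(x)
}

#' Mean pooled ROC value at a fixed pool size
#'
#' Repeatedly samples `N` units without replacement, forms the "pooling
#' neuron" whose per-trial count is the sum of the sampled units' counts
#' on that trial, computes the count ROC value for the pooling neuron, and
#' averages over samples.
#'
#' @param pool a [pool_counts()] pool (all units must share the trial
#'   structure).
#' @param N pool size, `1 <= N <= length(pool)`.
#' @param n_samples number of random samples (default 1000).
#' @param seed integer seed.
#' @return mean AUC, with attribute `sample_aucs`.
#' @export
pooled_auc <- function(pool, N, n_samples = 1000, seed = 1L) {
  if (N < 1 || N > length(pool))
    stop(sprintf("N must lie in [1, %d]", length(pool)), call. = FALSE)
  pref_mat <- vapply(pool, `[[`, numeric(length(pool[[1]]$pref)), "pref")
  non_mat <- vapply(pool, `[[`, numeric(length(pool[[1]]$nonpref)),
                    "nonpref")
  withr::with_seed(seed, {
    aucs <- vapply(seq_len(n_samples), function(s) {
      idx <- sample.int(length(pool), N)
      auc_cross(rowSums(pref_mat[, idx, drop = FALSE]),
                rowSums(non_mat[, idx, drop = FALSE]))
    }, 0)
  })
  structure(mean(aucs), sample_aucs = aucs)
}

#' Pooled ROC value as a function of pool size
#'
#' Runs [pooled_auc()] at each pool size over `n_repeats` repetitions of
#' the whole sampling procedure; reports the mean and the standard error
#' of the mean across repetitions. When a behavioral accuracy (as a
#' proportion) is supplied, also reports the smallest pool size whose mean
#' AUC reaches it -- the "how many neurons explain behavior" readout.
#'
#' @param pool a [pool_counts()] pool.
#' @param Ns pool sizes (default `c(2, 5, 10, 20, 50, 100, 200)`), values
#'   exceeding the pool size are dropped with a warning.
#' @param n_samples random samples per repetition (default 1000).
#' @param n_repeats repetitions of the procedure (default 10).
#' @param seed integer seed; each repetition uses a derived sub-seed.
#' @param behavior_accuracy optional behavioral accuracy as a proportion
#'   in `[0.5, 1]` to locate on the curve.
#' @return a list of class `pooling_curve`: `curve` (data.frame `N`,
#'   `mean_auc`, `sem`), `n_samples`, `n_repeats`, `readout_N` (`NA` when
#'   no tested N reaches the accuracy or none was supplied).
#' @export
pooling_curve <- function(pool, Ns = c(2, 5, 10, 20, 50, 100, 200),
                          n_samples = 1000, n_repeats = 10, seed = 1L,
                          behavior_accuracy = NULL) {
  if (length(Ns) == 0) stop("Ns must be non-empty", call. = FALSE)
  drop <- Ns > length(pool)
  if (any(drop)) {
    warning(sprintf("dropping pool size(s) beyond the pool (%d units): %s",
                    length(pool), paste(Ns[drop], collapse = ", ")),
            call. = FALSE)
    Ns <- Ns[!drop]
  }
  means <- matrix(NA_real_, n_repeats, length(Ns))
  for (r in seq_len(n_repeats)) {
    for (j in seq_along(Ns)) {
      means[r, j] <- pooled_auc(pool, Ns[j], n_samples,
                                seed = derive_seed(seed, r * 1000 + j))
    }
  }
  curve <- data.frame(N = Ns,
                      mean_auc = colMeans(means),
                      sem = apply(means, 2, stats::sd) / sqrt(n_repeats))
  readout <- NA_real_
  if (!is.null(behavior_accuracy)) {
    hit <- which(curve$mean_auc >= behavior_accuracy)
    if (length(hit) > 0) readout <- curve$N[min(hit)]
  }
  structure(list(curve = curve, n_samples = n_samples,
                 n_repeats = n_repeats, readout_N = readout,
                 behavior_accuracy = behavior_accuracy),
            class = "pooling_curve")
}

#' @export
print.pooling_curve <- function(x, ...) {
  cat("<pooling_curve>\n")
  print(x$curve, row.names = FALSE, digits = 4)
  if (!is.na(x$readout_N))
    cat(sprintf("  smallest N reaching accuracy %.2f: %d\n",
                x$behavior_accuracy, x$readout_N))
  invisible(x)
}
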