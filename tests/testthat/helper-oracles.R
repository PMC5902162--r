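# Independent oracles, written from the definitions rather than the package
# implementation, for cross-checking the analysis code paths.

# AUC by literal enumeration of all cross pairs.
brute_auc <- function(x, y) {
  wins <- 0
  for (a in x) for (b in y) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(x) * length(y))
}

# Benjamini-Hochberg step-up, straight from the definition: the selected set
# is all p <= p_(i*) where i* is the largest sorted index with
# p_(i) <= i/m * q.
brute_bh <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  istar <- 0
  for (i in seq_len(m)) if (s[i] <= i / m * q) istar <- i
  if (istar == 0) rep(FALSE, m) else p <= s[istar]
}

# Exact Poisson-vs-Poisson AUC by a plain truncated double sum (independent
# of the cumulative-sum formulation used in the package).
brute_poisson_auc <- function(l1, l2, kmax = 200) {
  s <- 0
  for (i in 0:kmax) for (j in 0:kmax)
    s <- s + dpois(i, l1) * dpois(j, l2) * ((i > j) + 0.5 * (i == j))
  s
}

# A minimal hand-built physiology fixture: n units with given per-class
# counts converted to spike-time lists (one spike at fixed offsets), plus a
# matching trial table.
fixture_unit <- function(id, times_by_trial) {
  unit_recording(id, times_by_trial)
}

fixture_trials <- function(n_target, n_distractor) {
  trial_table(seq_len(n_target + n_distractor),
              rep(c("target", "distractor"), c(n_target, n_distractor)),
              hold_time = 0.5)
}

# Build a unit whose windowed counts are exactly the given integers by
# placing that many spikes at 10 ms spacing from `onset_ms`.
unit_from_counts <- function(id, counts, onset_ms = 40) {
  spikes <- lapply(counts, function(k) {
    if (k == 0) numeric(0) else (onset_ms + 10 * (seq_len(k) - 1)) / 1000
  })
  names(spikes) <- as.character(seq_along(counts))
  unit_recording(id, spikes)
}
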