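# homogeneous Poisson pool built directly from counts
poisson_pool <- function(n_units, n_trials, l_pref = 0.6, l_non = 0.22,
                         seed = 1) {
  withr::with_seed(seed, {
    pool <- lapply(seq_len(n_units), function(i) {
      list(pref = rpois(n_trials, l_pref), nonpref = rpois(n_trials, l_non),
           source_id = paste0("u", i), copy = 0L)
    })
  })
  class(pool) <- "count_pool"
  pool
}

test_that("augmentation arithmetic and count-multiset conservation hold", {
  pool <- poisson_pool(72, 40)
  aug <- augment_pool(pool, n_copies = 6, seed = 2)
  expect_length(aug, 504)
  expect_length(augment_pool(pool[1], 6, seed = 2), 7)
  # 46% of 72 = 33 discriminating sources -> 231
  expect_length(augment_pool(pool[1:33], 6, seed = 2), 231)
  # shuffled copies preserve each source's per-class count multisets
  for (k in sample(length(aug), 30)) {
    src <- pool[[match(aug[[k]]$source_id,
                       vapply(pool, `[[`, "", "source_id"))]]
    expect_equal(sort(aug[[k]]$pref), sort(src$pref))
    expect_equal(sort(aug[[k]]$nonpref), sort(src$nonpref))
  }
})

test_that("unrestricted shuffling mixes classes; within-class does not", {
  pool <- list(list(pref = rep(5L, 10), nonpref = rep(0L, 10),
                    source_id = "u1", copy = 0L))
  class(pool) <- "count_pool"
  within <- augment_pool(pool, 1, seed = 3, within_class = TRUE)
  expect_equal(within[[2]]$pref, rep(5L, 10))
  across <- augment_pool(pool, 1, seed = 3, within_class = FALSE)
  expect_equal(sort(c(across[[2]]$pref, across[[2]]$nonpref)),
               sort(c(rep(5L, 10), rep(0L, 10))))
  expect_true(any(across[[2]]$pref != 5L))  # classes actually mixed
})

test_that("flip_preference is an involution and reorients the unit", {
  u <- list(pref = c(0L, 1L), nonpref = c(3L, 4L), source_id = "u1",
            copy = 0L)
  f <- flip_preference(u)
  expect_equal(f$pref, c(3L, 4L))
  expect_identical(flip_preference(f), u)
  # flipped distractor-preferring unit has AUC >= 0.5 toward target
  expect_gte(unit_auc(f$pref, f$nonpref)$auc, 0.5)
})

test_that("pooled_auc respects its contracts", {
  pool <- poisson_pool(30, 200, seed = 4)
  expect_error(pooled_auc(pool, 31), "N must lie")
  # N = pool size: every sample is the whole pool -> zero variance
  full <- pooled_auc(pool, 30, n_samples = 5, seed = 1)
  expect_equal(sd(attr(full, "sample_aucs")), 0)
  # stimulus-blind pool stays at chance
  blind <- poisson_pool(20, 300, l_pref = 0.4, l_non = 0.4, seed = 5)
  expect_lt(abs(pooled_auc(blind, 10, n_samples = 100, seed = 2) - 0.5),
            0.05)
})

test_that("pooled AUC follows the exact pooled-Poisson oracle over N", {
  oracle <- vapply(c(1, 2, 5, 10), function(N)
    brute_poisson_auc(0.6 * N, 0.22 * N, kmax = 80), 0)
  reps <- vapply(1:8, function(r) {
    pool <- poisson_pool(25, 120, seed = 100 + r)
    vapply(c(1, 2, 5, 10), function(N)
      as.numeric(pooled_auc(pool, N, n_samples = 120,
                            seed = 200 + r)), 0)
  }, numeric(4))
  means <- rowMeans(reps)
  sems <- apply(reps, 1, sd) / sqrt(ncol(reps))
  for (j in seq_along(oracle))
    expect_lt(abs(means[j] - oracle[j]), 3 * sems[j] + 0.01)
  # mean AUC non-decreasing in N (within Monte-Carlo noise)
  expect_true(all(diff(means) > -2 * sems[-1]))
})

test_that("pooling_curve summarizes repeats and locates the behavior
           readout", {
  pool <- poisson_pool(40, 100, seed = 6)
  pc <- pooling_curve(pool, Ns = c(2, 5, 10), n_samples = 50,
                      n_repeats = 4, seed = 3, behavior_accuracy = 0.5)
  expect_equal(pc$readout_N, 2)  # chance is reached by any pool
  expect_true(all(pc$curve$sem >= 0))
  pc2 <- pooling_curve(pool, Ns = c(2, 5, 10), n_samples = 50,
                       n_repeats = 4, seed = 3, behavior_accuracy = 0.76)
  expect_true(is.na(pc2$readout_N) || pc2$readout_N >= 2)
  expect_warning(pooling_curve(pool, Ns = c(2, 500), n_samples = 10,
                               n_repeats = 2, seed = 1), "dropping")
})

test_that("pool_counts orients units by preference from spike data", {
  # a distractor-preferring unit: more spikes on distractor trials
  trials <- fixture_trials(5, 5)
  u <- unit_from_counts("u1", c(rep(0, 5), rep(3, 5)))
  pool <- pool_counts(list(u), trials, onset_ms = 40, window_ms = 80,
                      preferences = c(u1 = "distractor"))
  expect_equal(pool[[1]]$pref, rep(3, 5))
  expect_gte(unit_auc(pool[[1]]$pref, pool[[1]]$nonpref)$auc, 0.5)
})
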