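test_that("windowed counts use half-open windows", {
  u <- unit_recording("u1", list(`1` = c(0.05, 0.10, 0.25),
                                 `2` = numeric(0),
                                 `3` = c(0.12)))
  counts <- count_in_window(u, onset_ms = 40, interval_ms = 80)
  # window [0.04, 0.12): trial 1 catches 0.05 and 0.10; the spike exactly
  # at onset + interval (trial 3) is excluded
  expect_equal(unname(counts), c(2L, 0L, 0L))
  empty <- unit_recording("u2", list(`1` = numeric(0), `2` = numeric(0)))
  expect_equal(unname(count_in_window(empty, onset_ms = 40,
                                      interval_ms = 80)), c(0L, 0L))
})

test_that("unit_auc matches the brute-force cross-pair oracle", {
  expect_equal(unit_auc(c(2, 2), c(0, 1))$auc, 1)
  expect_equal(unit_auc(c(1, 1, 2), c(1, 1, 2))$auc, 0.5)
  withr::with_seed(5, {
    for (i in 1:300) {
      x <- rpois(sample(1:8, 1), 1)
      y <- rpois(sample(1:8, 1), 0.5)
      expect_equal(unit_auc(x, y)$auc, brute_auc(x, y))
    }
  })
  expect_error(unit_auc(numeric(0), 1), "non-empty")
})

test_that("simulated Poisson counts converge to the analytic AUC 0.634", {
  oracle <- brute_poisson_auc(0.6, 0.22, kmax = 40)
  expect_equal(poisson_auc(0.6, 0.22), oracle, tolerance = 1e-10)
  expect_equal(oracle, 0.6343, tolerance = 1e-4)
  withr::with_seed(8, {
    aucs <- vapply(1:60, function(i) {
      auc_cross(rpois(400, 0.6), rpois(400, 0.22))
    }, 0)
  })
  expect_lt(abs(mean(aucs) - oracle), 3 * sd(aucs) / sqrt(length(aucs)))
})

test_that("BH step-up agrees with the definitional oracle", {
  res <- bh_select(c(0.001, 0.01, 0.02, 0.04), fdr = 0.05)
  expect_true(all(res$selected))
  expect_equal(res$cutoff, 0.04)
  expect_false(any(bh_select(rep(1, 6), 0.05)$selected))
  expect_true(all(bh_select(rep(0, 6), 0.05)$selected))
  withr::with_seed(9, {
    for (i in 1:500) {
      m <- sample(1:12, 1)
      p <- round(runif(m)^sample(1:3, 1), 3)
      q <- sample(c(0.01, 0.05, 0.1), 1)
      res <- bh_select(p, q)
      expect_identical(res$selected, brute_bh(p, q))
      # flags agree with stats::p.adjust thresholding
      expect_identical(unname(res$selected),
                       unname(stats::p.adjust(p, "BH") <= q))
    }
  })
})

test_that("low-rate exclusion uses the 1-in-6-trials rule", {
  silent <- unit_from_counts("silent", rep(0, 12))
  steady <- unit_from_counts("steady", rep(1, 12))
  # 10 spikes over 90 trials: mean 0.111 < 1/6 -> excluded
  sparse <- unit_from_counts("sparse", c(rep(1, 10), rep(0, 80)))
  res <- exclusion_filter(list(silent, steady, sparse), onset_ms = 40)
  expect_equal(vapply(res$retained, `[[`, "", "unit_id"), "steady")
  expect_setequal(vapply(res$excluded, `[[`, "", "unit_id"),
                  c("silent", "sparse"))
  expect_equal(unname(res$mean_counts["sparse"]), 10 / 90)
})

test_that("discrimination_curve flags designed discriminators and fixes the
           300 ms fraction at 1", {
  spec <- population_spec(n_units = 40, n_trials_per_stimulus = 100,
                          fraction_nondiscriminating = 0.25)
  pop <- generate_population(spec, seed = 17)
  filt <- exclusion_filter(pop$units, pop$onset_ms)
  disc <- discrimination_curve(filt$retained, pop$trials, pop$onset_ms)
  frac <- disc$fraction_discriminating
  expect_equal(frac$fraction[frac$interval_ms == 300], 1)
  expect_true(all(frac$fraction >= 0 & frac$fraction <= 1))
  # >= 90% of discriminating-by-design units flagged at 300 ms
  designed <- names(pop$preferences)[pop$preferences != "none"]
  flagged <- disc$units$unit_id[disc$units$discriminating]
  expect_gte(sum(designed %in% flagged) / length(designed), 0.9)
  # significance implies p at or below the effective cutoff
  expect_true(all(disc$units$p300[disc$units$discriminating]
                  <= disc$effective_cutoff))
  # preference consistent with the 300 ms mean-count difference
  at300 <- disc$table[disc$table$interval_ms == 300, ]
  sign_pref <- ifelse(at300$mean_count_target >= at300$mean_count_distractor,
                      "target", "distractor")
  expect_identical(disc$units$preference, sign_pref)
  # AUC oriented to preference: >= 0.5 at the defining window
  expect_true(all(at300$auc >= 0.5))
})

test_that("an all-silent population has zero discriminating units", {
  units <- lapply(1:5, function(i) unit_from_counts(paste0("u", i),
                                                    rep(0, 20)))
  trials <- fixture_trials(10, 10)
  disc <- discrimination_curve(units, trials, onset_ms = 40,
                               interval_grid = c(80, 300))
  expect_equal(sum(disc$units$discriminating), 0)
  expect_true(is.na(disc$effective_cutoff))
})

test_that("first_spike_reduce keeps only the first post-onset spike", {
  u <- unit_recording("u1", list(`1` = c(0.01, 0.05, 0.09),
                                 `2` = numeric(0),
                                 `3` = c(0.07)))
  r <- first_spike_reduce(u, onset_ms = 40)
  expect_equal(r$spikes[["1"]], 0.05)   # baseline spike at 10 ms dropped
  expect_length(r$spikes[["2"]], 0)
  expect_equal(r$spikes[["3"]], 0.07)
  # idempotent
  expect_identical(first_spike_reduce(r, 40)$spikes, r$spikes)
  # downstream counts never exceed 1
  expect_true(all(count_in_window(r, onset_ms = 40, interval_ms = 300) <= 1))
})
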