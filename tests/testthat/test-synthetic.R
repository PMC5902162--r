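test_that("generators are pure functions of (spec, seed)", {
  a <- generate_population(population_spec(n_units = 3,
                                           n_trials_per_stimulus = 8),
                           seed = 11)
  b <- generate_population(population_spec(n_units = 3,
                                           n_trials_per_stimulus = 8),
                           seed = 11)
  expect_identical(lapply(a$units, `[[`, "spikes"),
                   lapply(b$units, `[[`, "spikes"))
  expect_identical(a$trials, b$trials)

  expect_identical(generate_behavior(seed = 4), generate_behavior(seed = 4))
  expect_identical(generate_lfp(seed = 4)$traces,
                   generate_lfp(seed = 4)$traces)
})

test_that("zero-rate population produces empty spike trains", {
  pop <- generate_population(
    population_spec(n_units = 3, n_trials_per_stimulus = 5,
                    preferred_mean_80ms = 0, nonpreferred_mean_80ms = 0,
                    baseline_rate_hz = 0),
    seed = 1)
  expect_true(all(vapply(pop$units,
                         function(u) sum(lengths(u$spikes)), 0) == 0))
})

test_that("window counts match the spec'd Poisson means within 3 SE", {
  n_tr <- 300
  pop <- generate_population(
    population_spec(n_units = 12, n_trials_per_stimulus = n_tr,
                    fraction_nondiscriminating = 0,
                    fraction_preferring_target = 1),
    seed = 21)
  tgt <- as.character(pop$trials$trial_id[pop$trials$stimulus == "target"])
  dst <- as.character(pop$trials$trial_id[pop$trials$stimulus == "distractor"])
  pref_counts <- unlist(lapply(pop$units, count_in_window, trial_ids = tgt,
                               onset_ms = pop$onset_ms, interval_ms = 80))
  non_counts <- unlist(lapply(pop$units, count_in_window, trial_ids = dst,
                              onset_ms = pop$onset_ms, interval_ms = 80))
  se_p <- sqrt(0.6 / length(pref_counts))
  se_n <- sqrt(0.22 / length(non_counts))
  expect_lt(abs(mean(pref_counts) - 0.6), 3 * se_p)
  expect_lt(abs(mean(non_counts) - 0.22), 3 * se_n)
  # counts in the window pass a Poisson goodness-of-fit check
  expect_gt(poisson_fit(pref_counts)$r2, 0.9)
  expect_gt(poisson_fit(non_counts)$r2, 0.9)
})

test_that("behavior generator hits its target fraction and stop structure", {
  spec <- behavior_spec(n_trials = 10000, p_target = 0.25)
  tt <- generate_behavior(spec, seed = 31)
  p_hat <- mean(tt$stimulus == "target")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(p_hat - 0.25), 3 * se)
  # stop flag recomputable from hold time and threshold
  expect_identical(tt$stop, tt$hold_time >= spec$hold_threshold)
  # stop probabilities land near their spec'd values
  expect_lt(abs(mean(tt$stop[tt$stimulus == "target"]) - 0.9), 0.03)
  expect_lt(abs(mean(tt$stop[tt$stimulus == "distractor"]) - 0.1), 0.03)
})

test_that("deterministic stopping gives 100% accuracy", {
  tt <- generate_behavior(behavior_spec(n_trials = 400,
                                        stop_prob_target = 1,
                                        stop_prob_distractor = 0),
                          seed = 2)
  expect_equal(choice_accuracy(tt), 100)
})

test_that("zero-amplitude LFP has no ground-truth onset; traces repeat", {
  lfp <- generate_lfp(lfp_spec(deflection_amplitude = 0), seed = 9)
  expect_true(is.na(lfp$ground_truth_onset_ms))
  lfp2 <- generate_lfp(lfp_spec(deflection_amplitude = 0), seed = 9)
  expect_identical(lfp$traces, lfp2$traces)
})

test_that("passive responses are tuned around each unit's assignment", {
  spec <- population_spec(n_units = 30, fraction_nondiscriminating = 0)
  passive <- generate_passive(spec, seed = 41)
  assigned <- attr(passive, "assigned_preferred")
  ts <- tuning_summary(passive)
  # circular error modulo 180
  err <- abs(ts$preferred - assigned[ts$unit_id])
  err <- pmin(err, 180 - err)
  expect_lt(stats::median(err), 10)
})

test_that("LED truncation removes all spikes after silencing takes effect", {
  spec <- population_spec(n_units = 4, n_trials_per_stimulus = 30,
                          led_truncation_ms = 80, baseline_rate_hz = 0)
  pop <- generate_population(spec, seed = 13)
  cutoff <- (pop$onset_ms + 80 + 8) / 1000
  all_spikes <- unlist(lapply(pop$units, function(u) unlist(u$spikes)))
  expect_true(all(all_spikes < cutoff))
  expect_true(all(pop$trials$led == "on"))
})
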