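test_that("stop classification is boundary-inclusive", {
  tt <- trial_table(1:3, c("target", "target", "distractor"),
                    c(0.2, 0.7, 1.1))
  out <- classify_stops(tt, 0.9)
  expect_equal(out$stop, c(FALSE, FALSE, TRUE))
  expect_true(classify_stops(trial_table(1, "target", 0.9), 0.9)$stop)
  expect_false(classify_stops(trial_table(1, "target", 0), 0.9)$stop)
})

test_that("accuracy follows the two-class average definition", {
  # 8/10 targets stopped, 6/10 distractors non-stop -> 70%
  tt <- trial_table(1:20, rep(c("target", "distractor"), each = 10),
                    hold_time = c(rep(1, 8), rep(0.1, 2),    # targets
                                  rep(0.1, 6), rep(1, 4)))   # distractors
  tt <- classify_stops(tt, 0.9)
  expect_equal(choice_accuracy(tt), 70)

  perfect <- classify_stops(
    trial_table(1:4, c("target", "target", "distractor", "distractor"),
                c(1, 1, 0.1, 0.1)), 0.9)
  expect_equal(choice_accuracy(perfect), 100)

  only_t <- classify_stops(trial_table(1:2, c("target", "target"),
                                       c(1, 1)), 0.9)
  expect_error(choice_accuracy(only_t), "distractor")
})

test_that("stimulus-blind stopping yields 50% accuracy in expectation", {
  # property over stop rates q: per-class rates are complementary, so the
  # definition returns exactly 50 whenever the empirical stop rate is equal
  # across classes; statistically it stays within binomial error otherwise.
  for (q in c(0.1, 0.3, 0.5, 0.8)) {
    tt <- generate_behavior(
      behavior_spec(n_trials = 4000, p_target = 0.5,
                    stop_prob_target = q, stop_prob_distractor = q,
                    hold_meanlog = c(target = log(0.5),
                                     distractor = log(0.5)),
                    hold_sdlog = c(target = 0.5, distractor = 0.5)),
      seed = 100 + round(10 * q))
    se_pct <- 100 * sqrt(q * (1 - q) / 2000)
    expect_lt(abs(choice_accuracy(tt) - 50), 3 * se_pct + 1e-9)
  }
})

test_that("ideal-observer AUC equals the brute-force cross-pair oracle", {
  expect_equal(ideal_observer_auc(c(1, 2), c(1, 3)), 0.375)
  expect_equal(ideal_observer_auc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(ideal_observer_auc(c(5, 6), c(1, 2)), 1)
  withr::with_seed(7, {
    for (i in 1:200) {
      x <- sample(0:4, sample(1:8, 1), replace = TRUE)
      y <- sample(0:4, sample(1:8, 1), replace = TRUE)
      expect_equal(ideal_observer_auc(x, y), brute_auc(x, y))
      # complement symmetry
      expect_equal(ideal_observer_auc(x, y) + ideal_observer_auc(y, x), 1)
    }
  })
  expect_error(ideal_observer_auc(numeric(0), 1), "empty")
})

test_that("rank-sum p-values match exact enumeration and behave at scale", {
  # most extreme labeling of C(6,3)=20: two-sided p = 2/20
  expect_equal(ranksum_test(c(5, 6, 7), c(1, 2, 3))$p.value, 0.1)
  # identical samples: p = 1 in both regimes
  expect_equal(ranksum_test(1:5, 1:5)$p.value, 1)
  expect_equal(ranksum_test(rep(1, 30), rep(1, 30))$p.value, 1)
  # agreement with wilcox.test's exact p on tie-free small samples
  withr::with_seed(12, {
    for (i in 1:50) {
      x <- sample(1:100, 5)
      y <- sample(101:200, 6) - sample(0:120, 1)
      if (anyDuplicated(c(x, y)) > 0) next
      expect_equal(ranksum_test(x, y)$p.value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  # large separated samples
  expect_lt(ranksum_test(rnorm(100, 10), rnorm(100, 0))$p.value, 1e-6)
  tt <- classify_stops(trial_table(1:4, rep(c("target", "distractor"), 2),
                                   c(1, 0.2, 1.2, 0.1)), 0.9)
  expect_true(choice_ranksum(tt) <= 1)
})

test_that("binomial CI is exact Clopper-Pearson", {
  ci <- binomial_ci95(5, 10)
  expect_equal(unname(ci), c(0.187086, 0.812914), tolerance = 1e-5)
  expect_equal(unname(binomial_ci95(10, 10))[2], 1)
  expect_equal(unname(binomial_ci95(0, 10))[1], 0)
  k <- 7; n <- 19
  expect_true(ci[1] <= 0.5 && ci[2] >= 0.5)
  expect_equal(unname(binomial_ci95(k, n)),
               c(qbeta(0.025, k, n - k + 1), qbeta(0.975, k + 1, n - k)),
               tolerance = 1e-12)
  expect_error(binomial_ci95(1, 0), "n")
})

test_that("behavior_summary assembles a coherent session report", {
  tt <- generate_behavior(behavior_spec(n_trials = 500), seed = 6)
  s <- behavior_summary(tt, 0.9)
  expect_gt(s$accuracy, 80)
  expect_gt(s$ideal_observer_auc, 0.9)
  expect_lt(s$ranksum_p, 1e-6)
  expect_true(s$stop_prob_target_ci[1] <= s$stop_prob_target)
  expect_true(s$stop_prob_target <= s$stop_prob_target_ci[2])
})
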