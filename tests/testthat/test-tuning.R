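make_passive <- function(rates_by_theta, reps = 1) {
  thetas <- seq(0, 165, by = 15)
  data.frame(orientation = rep(thetas, each = reps),
             count = rep(rates_by_theta, each = reps))
}

test_that("tuning curves are max-normalized and scale-invariant", {
  r <- c(1, rep(0, 11)); r[7] <- 4   # peak at 90 degrees
  tc <- tuning_curve(make_passive(r))
  expect_equal(max(tc$rates), 1)
  expect_equal(tc$rates[tc$thetas == 90], 1)
  tc2 <- tuning_curve(make_passive(2 * r))
  expect_equal(tc2$rates, tc$rates)
  flat <- tuning_curve(make_passive(rep(3, 12)))
  expect_true(all(flat$rates == 1))
  zero <- tuning_curve(make_passive(rep(0, 12)))
  expect_true(zero$degenerate)
  expect_error(tuning_curve(data.frame(orientation = c(0, 15),
                                       count = c(1, 2))), "missing")
})

test_that("preferred orientation follows the doubled-angle vector average", {
  only90 <- rep(0, 12); only90[7] <- 1
  expect_equal(preferred_orientation(tuning_curve(make_passive(only90))), 90)
  # r = [2 at 0, 1 at 90]: x = 2 - 1 = 1, y = 0 -> 0 degrees
  mix <- rep(0, 12); mix[1] <- 2; mix[7] <- 1
  expect_equal(preferred_orientation(tuning_curve(make_passive(mix))), 0)
  expect_error(preferred_orientation(tuning_curve(make_passive(rep(1, 12)))),
               "degenerate")
  # invariance under uniform scaling
  tc1 <- tuning_curve(make_passive(mix))
  tc5 <- tuning_curve(make_passive(5 * mix))
  expect_equal(preferred_orientation(tc1), preferred_orientation(tc5))
})

test_that("OSI is the doubled-angle vector strength", {
  only45 <- rep(0, 12); only45[4] <- 2
  expect_equal(osi(tuning_curve(make_passive(only45))), 1)
  expect_equal(osi(tuning_curve(make_passive(rep(2, 12)))), 0,
               tolerance = 1e-12)
  mix <- rep(0, 12); mix[1] <- 2; mix[7] <- 1
  expect_equal(osi(tuning_curve(make_passive(mix))), 1 / 3,
               tolerance = 1e-12)
  expect_error(osi(tuning_curve(make_passive(rep(0, 12)))), "zero")
})

test_that("receptive-field center of mass recovers known structure", {
  grid <- expand.grid(azimuth = 0:4 * 3.6, elevation = 0:4 * 3.6,
                      polarity = c("white", "black"), channel = 1:2)
  grid$response <- 0
  hot <- grid$azimuth == 7.2 & grid$elevation == 3.6
  grid$response[hot] <- 5
  rf <- rf_center(grid)
  expect_equal(unname(rf$center), c(7.2, 3.6), tolerance = 1e-12)
  # two equal hot spots at (0, 0) and (7.2, 0) -> midpoint (3.6, 0)
  g2 <- grid; g2$response <- 0
  g2$response[g2$azimuth == 0 & g2$elevation == 0] <- 3
  g2$response[g2$azimuth == 7.2 & g2$elevation == 0] <- 3
  expect_equal(unname(rf_center(g2)$center), c(3.6, 0), tolerance = 1e-12)
  # Gaussian bump centered on a grid point, recovered within half a step
  g3 <- expand.grid(azimuth = 0:8 * 3.6, elevation = 0:8 * 3.6,
                    polarity = c("white", "black"), channel = 1)
  g3$response <- exp(-((g3$azimuth - 14.4)^2 + (g3$elevation - 18)^2) / 30)
  ctr <- rf_center(g3)$center
  expect_lt(abs(ctr["azimuth"] - 14.4), 1.8)
  expect_lt(abs(ctr["elevation"] - 18), 1.8)
  g0 <- grid; g0$response <- 0
  expect_error(rf_center(g0), "all-zero")
})

test_that("the ROC-vs-count-difference fit recovers a known slope", {
  withr::with_seed(14, {
    x <- rnorm(50, 0, 2)
    y <- 0.5 + 0.1 * x + rnorm(50, 0, 0.05)
  })
  fit <- auc_vs_dspikes_fit(x, y)
  expect_lt(abs(fit$slope - 0.1), 3 * fit$se_slope)
  expect_lt(fit$p_slope_positive, 0.001)
  expect_gt(fit$r2, 0.8)
  # collinear points: r2 = 1, vanishing SEs
  fitc <- suppressWarnings(auc_vs_dspikes_fit(1:10, 0.3 + 0.02 * (1:10)))
  expect_equal(fitc$r2, 1)
  expect_lt(fitc$se_slope, 1e-10)
  # null case: slope CI covers 0
  withr::with_seed(15, yn <- rnorm(50, 0.6, 0.1))
  fitn <- auc_vs_dspikes_fit(x, yn)
  expect_true(abs(fitn$slope) < 2 * fitn$se_slope)
  expect_error(auc_vs_dspikes_fit(1:2, 1:2), "3 points")
  expect_error(auc_vs_dspikes_fit(rep(1, 5), 1:5), "variance")
})
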