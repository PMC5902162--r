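#' Specification of a synthetic recorded population
#'
#' Parameters of the generative model for one simulated recording session.
#' Defaults are the study conditions the analyses assume: discriminating
#' units fire on average 0.6 spikes in the initial 80 ms window after
#' cortical response onset for their preferred stimulus and 0.22 for the
#' non-preferred one; the cortical response begins 40 ms after stimulus
#' onset with a 5 ms across-session standard deviation; and the mean
#' first-spike time for the preferred stimulus precedes the non-preferred
#' one by 12 ms (70 vs 82 ms from cortical onset).
#'
#' @param n_units number of units in the session.
#' @param n_trials_per_stimulus trials per stimulus class.
#' @param preferred_mean_80ms,nonpreferred_mean_80ms mean spike count in
#'   the initial 80 ms window for the preferred / non-preferred stimulus.
#' @param onset_latency_ms,onset_sd_ms cortical onset latency mean and
#'   across-session sd, ms.
#' @param first_spike_mean_ms target conditional mean first-spike time for
#'   the preferred stimulus, ms from cortical onset.
#' @param first_spike_latency_shift_ms how much later (ms) the mean first
#'   spike falls for the non-preferred stimulus.
#' @param latency_shape gamma shape of the spike-latency density.
#' @param response_horizon_ms extent of the evoked response, ms.
#' @param baseline_rate_hz spontaneous rate before stimulus onset.
#' @param fraction_preferring_target proportion of discriminating units
#'   whose preferred stimulus is the target.
#' @param fraction_nondiscriminating proportion of units with equal means
#'   for both stimuli.
#' @param led_truncation_ms when not `NA`, cortical silencing onset in ms
#'   from cortical onset: all spikes after `onset + led_truncation_ms +
#'   8 ms` (the silencing delay) are removed and trials are flagged LED-on.
#' @param trial_span_s two-element vector, trial extent in seconds around
#'   stimulus onset.
#' @param tuning_kappa concentration of the circular-Gaussian orientation
#'   tuning profile used by [generate_passive()] (period 180 degrees).
#' @param passive_n_reps repetitions per orientation in passive viewing.
#' @param passive_peak_rate_hz,passive_baseline_rate_hz peak and offset of
#'   the passive tuning profile, spikes/s over the 330 ms response window.
#' @return a validated list of class `population_spec`.
#' @export
population_spec <- function(n_units = 72,
                            n_trials_per_stimulus = 100,
                            preferred_mean_80ms = 0.6,
                            nonpreferred_mean_80ms = 0.22,
                            onset_latency_ms = 40,
                            onset_sd_ms = 5,
                            first_spike_mean_ms = 70,
                            first_spike_latency_shift_ms = 12,
                            latency_shape = 6,
                            response_horizon_ms = 300,
                            baseline_rate_hz = 2,
                            fraction_preferring_target = 0.5,
                            fraction_nondiscriminating = 0.3,
                            led_truncation_ms = NA_real_,
                            trial_span_s = c(-0.1, 0.4),
                            tuning_kappa = 1,
                            passive_n_reps = 30,
                            passive_peak_rate_hz = 7.5,
                            passive_baseline_rate_hz = 0.5) {
  spec <- as.list(environment())
  class(spec) <- "population_spec"
  validate_population_spec(spec)
}

validate_population_spec <- function(spec) {
  stopifnot(spec$n_units >= 1, spec$n_trials_per_stimulus >= 1)
  if (spec$preferred_mean_80ms < 0 || spec$nonpreferred_mean_80ms < 0)
    stop("window count means must be >= 0", call. = FALSE)
  if (spec$fraction_preferring_target < 0 || spec$fraction_preferring_target > 1 ||
      spec$fraction_nondiscriminating < 0 || spec$fraction_nondiscriminating > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (spec$baseline_rate_hz < 0) stop("baseline_rate_hz must be >= 0",
                                      call. = FALSE)
  stopifnot(length(spec$trial_span_s) == 2, spec$trial_span_s[1] < 0,
            spec$trial_span_s[2] > spec$response_horizon_ms / 1000)
  spec
}

# ---- evoked-response model -------------------------------------------------
#
# Evoked spiking after cortical onset is an inhomogeneous Poisson process on
# (0, H] ms: the total evoked count is Poisson(lambda_H) and spike times are
# iid draws from a gamma latency density truncated to (0, H]. Two quantities
# are pinned analytically:
#   * the count in the initial 80 ms window is Poisson with the spec'd mean,
#     because thinning gives lambda_80 = lambda_H * F(80) and we set
#     lambda_H = window_mean / F(80);
#   * the conditional mean first-spike time E[T1 | >=1 spike in (0, H]]
#     equals the spec'd target, by calibrating the gamma mean numerically
#     (the first-spike survival is exp(-lambda_H * F(t)), so the mean is a
#     smooth monotone-enough function of the density mean for a root find).

trunc_gamma_cdf <- function(t, shape, mean, horizon) {
  stats::pgamma(t, shape = shape, scale = mean / shape) /
    stats::pgamma(horizon, shape = shape, scale = mean / shape)
}

# E[first spike | >=1 spike in (0, horizon]] for the model above, ms.
mean_first_spike <- function(dens_mean, shape, window_mean, window_ms,
                             horizon) {
  tt <- seq(0, horizon, by = 0.1)
  Ft <- trunc_gamma_cdf(tt, shape, dens_mean, horizon)
  lambda <- window_mean / trunc_gamma_cdf(window_ms, shape, dens_mean, horizon)
  surv <- exp(-lambda * Ft)
  s_end <- exp(-lambda)
  sum((surv - s_end) * 0.1) / (1 - s_end)
}

# Find the latency-density mean whose conditional mean first-spike time hits
# `target_ms`. Returns list(dens_mean, lambda).
calibrate_latency <- function(target_ms, shape, window_mean, window_ms = 80,
                              horizon = 300) {
  f <- function(m) mean_first_spike(m, shape, window_mean, window_ms,
                                    horizon) - target_ms
  lo <- 5; hi <- 200
  while (f(lo) > 0 && lo > 0.5) lo <- lo / 2
  while (f(hi) < 0 && hi < 5000) hi <- hi * 2
  m <- stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
  list(dens_mean = m,
       lambda = window_mean / trunc_gamma_cdf(window_ms, shape, m, horizon))
}

# Inverse-CDF sampler for the truncated gamma latency density (ms).
rlatency <- function(n, shape, dens_mean, horizon) {
  pmax_h <- stats::pgamma(horizon, shape = shape, scale = dens_mean / shape)
  stats::qgamma(stats::runif(n) * pmax_h, shape = shape,
                scale = dens_mean / shape)
}

# Hold times for a simulated trained animal: stop with the given
# probability, then draw the hold time from the stimulus's lognormal
# conditioned on the correct side of the threshold (inverse-CDF).
draw_holds <- function(stimulus, stop_prob_target = 0.9,
                       stop_prob_distractor = 0.1, threshold = 0.9,
                       meanlog = c(target = log(1.1), distractor = log(0.3)),
                       sdlog = c(target = 0.35, distractor = 0.6)) {
  n <- length(stimulus)
  p_stop <- ifelse(stimulus == "target", stop_prob_target,
                   stop_prob_distractor)
  stops <- stats::runif(n) < p_stop
  ml <- meanlog[stimulus]
  sl <- sdlog[stimulus]
  f_thr <- stats::plnorm(threshold, ml, sl)
  u <- ifelse(stops,
              f_thr + stats::runif(n) * (1 - f_thr),
              stats::runif(n) * f_thr)
  stats::qlnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), ml, sl)
}

#' Generate a synthetic recorded population
#'
#' Simulates one recording session: a trial table with
#' `2 * n_trials_per_stimulus` interleaved target/distractor trials and a
#' list of units with per-trial spike times aligned to stimulus onset.
#' Baseline spikes are homogeneous Poisson before stimulus onset; evoked
#' spikes follow the calibrated inhomogeneous-Poisson model described in
#' [population_spec()], so spike counts in the initial 80 ms window after
#' cortical onset are exactly Poisson with the spec'd means and the
#' preferred-stimulus mean first-spike time leads by the spec'd shift.
#' Non-discriminating units use the average of the two means for both
#' stimuli. The generator is a pure function of `(spec, seed)`.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return a list of class `population` with elements `units` (list of
#'   [unit_recording()]), `trials` (a [trial_table()]), `onset_ms` (the
#'   session's true cortical onset latency), `preferences` (named character
#'   vector, assigned preferred stimulus per unit; `"none"` for
#'   non-discriminating units) and `spec`.
#' @export
generate_population <- function(spec = population_spec(), seed = 1L) {
  spec <- validate_population_spec(spec)
  if (spec$n_trials_per_stimulus < 1) stop("zero trials", call. = FALSE)
  withr::with_seed(seed, {
    n_tr <- 2L * spec$n_trials_per_stimulus
    stimulus <- rep(c("target", "distractor"), spec$n_trials_per_stimulus)
    onset_ms <- max(1, stats::rnorm(1, spec$onset_latency_ms,
                                    spec$onset_sd_ms))
    hold <- draw_holds(stimulus, threshold = 0.9)
    led_on <- !is.na(spec$led_truncation_ms)
    trials <- trial_table(seq_len(n_tr), stimulus, hold,
                          led = if (led_on) "on" else "off",
                          led_onset_ms = if (led_on) spec$led_truncation_ms
                                         else NA_real_)

    H <- spec$response_horizon_ms
    shp <- spec$latency_shape
    cal_pref <- if (spec$preferred_mean_80ms > 0)
      calibrate_latency(spec$first_spike_mean_ms, shp,
                        spec$preferred_mean_80ms, horizon = H) else NULL
    cal_non <- if (spec$nonpreferred_mean_80ms > 0)
      calibrate_latency(spec$first_spike_mean_ms +
                          spec$first_spike_latency_shift_ms, shp,
                        spec$nonpreferred_mean_80ms, horizon = H) else NULL
    mid_mean <- (spec$preferred_mean_80ms + spec$nonpreferred_mean_80ms) / 2
    cal_mid <- if (mid_mean > 0)
      calibrate_latency(spec$first_spike_mean_ms, shp, mid_mean,
                        horizon = H) else NULL

    n_nondisc <- round(spec$fraction_nondiscriminating * spec$n_units)
    discriminating <- rep(c(FALSE, TRUE),
                          c(n_nondisc, spec$n_units - n_nondisc))
    prefers_target <- stats::runif(spec$n_units) <
      spec$fraction_preferring_target
    preferences <- ifelse(discriminating,
                          ifelse(prefers_target, "target", "distractor"),
                          "none")

    span <- spec$trial_span_s
    onset_s <- onset_ms / 1000
    cut_s <- if (led_on)
      onset_s + (spec$led_truncation_ms + 8) / 1000 else Inf

    units <- vector("list", spec$n_units)
    for (i in seq_len(spec$n_units)) {
      spikes <- vector("list", n_tr)
      for (tr in seq_len(n_tr)) {
        cal <- if (!discriminating[i]) cal_mid
               else if ((stimulus[tr] == "target") == prefers_target[i])
                 cal_pref else cal_non
        evoked <- numeric(0)
        if (!is.null(cal)) {
          n_ev <- stats::rpois(1, cal$lambda)
          if (n_ev > 0)
            evoked <- onset_s + rlatency(n_ev, shp, cal$dens_mean, H) / 1000
        }
        base <- numeric(0)
        if (spec$baseline_rate_hz > 0) {
          n_b <- stats::rpois(1, spec$baseline_rate_hz * (0 - span[1]))
          if (n_b > 0) base <- stats::runif(n_b, span[1], 0)
        }
        s <- sort(c(base, evoked))
        spikes[[tr]] <- s[s < cut_s]
      }
      names(spikes) <- as.character(seq_len(n_tr))
      units[[i]] <- unit_recording(sprintf("u%03d", i), spikes)
    }
    names(preferences) <- vapply(units, `[[`, "", "unit_id")
    structure(list(units = units, trials = trials, onset_ms = onset_ms,
                   preferences = preferences, spec = spec),
              class = "population")
  })
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(paste0("<population> %d units, %d trials, cortical onset ",
                     "%.1f ms\n"),
              length(x$units), nrow(x$trials), x$onset_ms))
  invisible(x)
}

#' Specification of synthetic behavioral sessions
#'
#' @param n_trials number of trials.
#' @param p_target probability a trial's stimulus is the target.
#' @param stop_prob_target,stop_prob_distractor probability the simulated
#'   animal holds the stimulus past threshold, per stimulus class.
#' @param hold_threshold minimum hold time for a stop, seconds.
#' @param hold_meanlog,hold_sdlog named vectors (`target`, `distractor`)
#'   of lognormal location/scale for the hold-time distributions.
#' @return a validated list of class `behavior_spec`.
#' @export
behavior_spec <- function(n_trials = 200, p_target = 0.375,
                          stop_prob_target = 0.9,
                          stop_prob_distractor = 0.1,
                          hold_threshold = 0.9,
                          hold_meanlog = c(target = log(1.1),
                                           distractor = log(0.3)),
                          hold_sdlog = c(target = 0.35, distractor = 0.6)) {
  spec <- as.list(environment())
  probs <- c(p_target, stop_prob_target, stop_prob_distractor)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(n_trials >= 1, hold_threshold > 0)
  class(spec) <- "behavior_spec"
  spec
}

#' Generate a synthetic behavioral session
#'
#' Draws stimulus identity Bernoulli(`p_target`), decides stopping with the
#' stimulus-specific stop probability, and draws the hold time from the
#' stimulus's lognormal distribution conditioned on the corresponding side
#' of the hold threshold, so the stop flag is exactly recomputable from the
#' hold time. With equal stop probabilities and identical hold
#' distributions for both stimuli the observer is stimulus-blind and its
#' expected accuracy is 50%.
#'
#' @param spec a [behavior_spec()].
#' @param seed integer seed.
#' @return a [trial_table()] with stop flags set.
#' @export
generate_behavior <- function(spec = behavior_spec(), seed = 1L) {
  withr::with_seed(seed, {
    stimulus <- ifelse(stats::runif(spec$n_trials) < spec$p_target,
                       "target", "distractor")
    hold <- draw_holds(stimulus, spec$stop_prob_target,
                       spec$stop_prob_distractor, spec$hold_threshold,
                       spec$hold_meanlog, spec$hold_sdlog)
    tt <- trial_table(seq_along(stimulus), stimulus, hold)
    classify_stops(tt, spec$hold_threshold)
  })
}

#' Specification of synthetic LFP blocks
#'
#' @param n_channels recording channels.
#' @param fs sampling rate, Hz (must exceed 600 for the 300 Hz filter).
#' @param noise_sd white-noise standard deviation of the trial-averaged
#'   trace, volts.
#' @param deflection_amplitude evoked deflection peak, in multiples of
#'   `noise_sd` (negative-going; 0 gives pure noise).
#' @param deflection_onset_ms deflection onset, ms from stimulus onset.
#' @param rise_ms,decay_ms rise time to peak and exponential decay constant
#'   of the deflection, ms.
#' @param trace_span_ms two-element vector, trace extent in ms around
#'   stimulus onset (must cover at least [-80, +300]).
#' @return a validated list of class `lfp_spec`.
#' @export
lfp_spec <- function(n_channels = 4, fs = 1250, noise_sd = 5e-6,
                     deflection_amplitude = 10, deflection_onset_ms = 40,
                     rise_ms = 10, decay_ms = 80,
                     trace_span_ms = c(-100, 400)) {
  spec <- as.list(environment())
  check_positive_scalar(fs, "fs")
  stopifnot(trace_span_ms[1] <= -80, trace_span_ms[2] >= 300)
  if (deflection_amplitude > 0 &&
      (deflection_onset_ms <= trace_span_ms[1] ||
       deflection_onset_ms >= trace_span_ms[2]))
    stop("deflection_onset_ms must lie inside the trace span", call. = FALSE)
  class(spec) <- "lfp_spec"
  spec
}

#' Generate a synthetic trial-averaged LFP block
#'
#' Each channel is band-limited Gaussian noise (white noise low-pass
#' filtered at 300 Hz, like the LFP band itself, then rescaled to
#' `noise_sd`) plus, when `deflection_amplitude > 0`, a smooth
#' negative-going deflection starting at `deflection_onset_ms`: a
#' smoothstep ramp over `rise_ms` to the peak, then exponential relaxation
#' with constant `decay_ms`. Band-limiting the noise makes `noise_sd`
#' commensurate with the baseline standard deviation that [detect_onset()]
#' thresholds against, so `deflection_amplitude` is an honest multiple of
#' the criterion's noise floor. The ground-truth onset is recorded in the
#' block's metadata (absent for pure noise).
#'
#' @param spec an [lfp_spec()].
#' @param seed integer seed.
#' @return an [lfp_block()].
#' @export
generate_lfp <- function(spec = lfp_spec(), seed = 1L) {
  withr::with_seed(seed, {
    t_ms <- seq(spec$trace_span_ms[1], spec$trace_span_ms[2],
                by = 1000 / spec$fs)
    n <- length(t_ms)
    defl <- numeric(n)
    has_defl <- spec$deflection_amplitude > 0
    if (has_defl) {
      u <- (t_ms - spec$deflection_onset_ms) / spec$rise_ms
      shape <- ifelse(u <= 0, 0,
                      ifelse(u < 1, u^2 * (3 - 2 * u),
                             exp(-(u - 1) * spec$rise_ms / spec$decay_ms)))
      defl <- -spec$deflection_amplitude * spec$noise_sd * shape
    }
    noise <- matrix(stats::rnorm(n * spec$n_channels), nrow = n)
    noise <- apply(noise, 2, function(ch) {
      ch <- lowpass_filter(ch, spec$fs)
      ch / stats::sd(ch) * spec$noise_sd
    })
    traces <- noise + defl
    lfp_block(traces, fs = spec$fs, t_start = t_ms[1] / 1000,
              ground_truth_onset_ms = if (has_defl) spec$deflection_onset_ms
                                      else NA_real_)
  })
}

#' Generate passive-viewing orientation responses
#'
#' Simulates the passive-viewing protocol: drifting gratings at 12
#' orientations in 15 degree steps, ~30 repetitions each, spike counts
#' taken over the initial 330 ms from cortical onset. Each unit gets an
#' assigned preferred orientation (target-preferring units near 90
#' degrees, distractor-preferring near 45, non-discriminating uniform) and
#' a circular-Gaussian tuning profile with period 180 degrees; counts are
#' Poisson around the profile.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @param preferences optional named character vector of per-unit preferred
#'   stimuli (as produced by [generate_population()]); when omitted a fresh
#'   assignment is drawn.
#' @return a `data.frame` with columns `unit_id`, `orientation`, `rep`,
#'   `count`, and an attribute `assigned_preferred` giving each unit's true
#'   preferred orientation in degrees.
#' @export
generate_passive <- function(spec = population_spec(), seed = 1L,
                             preferences = NULL) {
  spec <- validate_population_spec(spec)
  withr::with_seed(seed, {
    if (is.null(preferences)) {
      n_nondisc <- round(spec$fraction_nondiscriminating * spec$n_units)
      disc <- rep(c(FALSE, TRUE), c(n_nondisc, spec$n_units - n_nondisc))
      pt <- stats::runif(spec$n_units) < spec$fraction_preferring_target
      preferences <- ifelse(disc, ifelse(pt, "target", "distractor"), "none")
      names(preferences) <- sprintf("u%03d", seq_len(spec$n_units))
    }
    n_units <- length(preferences)
    theta_pref <- vapply(preferences, function(p) {
      switch(p,
             target = (stats::rnorm(1, 100, 15)) %% 180,
             distractor = (stats::rnorm(1, 35, 15)) %% 180,
             stats::runif(1, 0, 180))
    }, 0)
    thetas <- seq(0, 165, by = 15)
    window_s <- 0.33
    rows <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      d2 <- 2 * (thetas - theta_pref[i]) * pi / 180
      rate <- spec$passive_baseline_rate_hz +
        (spec$passive_peak_rate_hz - spec$passive_baseline_rate_hz) *
        exp(spec$tuning_kappa * (cos(d2) - 1))
      counts <- stats::rpois(length(thetas) * spec$passive_n_reps,
                             rep(rate * window_s, each = spec$passive_n_reps))
      rows[[i]] <- data.frame(
        unit_id = names(preferences)[i],
        orientation = rep(thetas, each = spec$passive_n_reps),
        rep = rep(seq_len(spec$passive_n_reps), times = length(thetas)),
        count = counts, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "assigned_preferred") <- stats::setNames(theta_pref,
                                                       names(preferences))
    out
  })
}
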