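#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth low-pass at 300 Hz, applied bidirectionally
#' (forward and reverse) so the filtered trace has zero phase shift. At the
#' cutoff frequency each pass attenuates the amplitude by 1/sqrt(2), so the
#' two-pass gain is 0.5.
#'
#' @param trace numeric vector, one channel's voltage trace.
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff_hz low-pass cutoff (default 300).
#' @return filtered trace of the same length.
#' @export
lowpass_filter <- function(trace, fs, cutoff_hz = 300) {
  check_positive_scalar(fs, "fs")
  if (fs <= 2 * cutoff_hz)
    stop(sprintf("fs (%g Hz) must exceed twice the cutoff (%g Hz)",
                 fs, cutoff_hz), call. = FALSE)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, trace))
}

#' Detect the onset of the cortical response in a trial-averaged LFP
#'
#' Each channel's trace is low-pass filtered ([lowpass_filter()]); the
#' baseline mean and standard deviation are computed per channel over
#' [-80, +20) ms around stimulus onset on the filtered trace. The onset is
#' the earliest post-onset sample (search window `(0, 300]` ms) at which
#' the absolute deviation from the baseline mean exceeds 3 baseline
#' standard deviations and stays above threshold for `sustain_ms`
#' (consecutive samples), minimized over channels. The sustained-exceedance
#' requirement rejects single-sample noise excursions on otherwise flat
#' baselines. The deflection criterion is sign-agnostic.
#'
#' @param lfp an [lfp_block()].
#' @param n_sd threshold in baseline standard deviations (default 3).
#' @param search_ms end of the search window, ms after stimulus onset.
#' @param sustain_ms minimum duration the trace must remain beyond
#'   threshold for a crossing to count (default 10 ms).
#' @return a list of class `onset_result` with `onset_ms` (`NA` when no
#'   channel ever exceeds threshold), `channel`, and per-channel
#'   `baseline_sd`.
#' @export
detect_onset <- function(lfp, n_sd = 3, search_ms = 300, sustain_ms = 10) {
  stopifnot(inherits(lfp, "lfp_block"))
  base_idx <- which(lfp$time >= -0.080 & lfp$time < 0.020)
  search_idx <- which(lfp$time > 0 & lfp$time <= search_ms / 1000)
  if (length(base_idx) < 2 || length(search_idx) < 1)
    stop("trace too short for baseline/search windows", call. = FALSE)
  n_sustain <- max(1L, round(sustain_ms / 1000 * lfp$fs))

  n_ch <- ncol(lfp$traces)
  onset_per_ch <- rep(NA_real_, n_ch)
  baseline_sd <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    filt <- lowpass_filter(lfp$traces[, ch], lfp$fs)
    mu <- mean(filt[base_idx])
    sd_ch <- stats::sd(filt[base_idx])
    baseline_sd[ch] <- sd_ch
    dev <- abs(filt[search_idx] - mu)
    over <- dev > n_sd * sd_ch
    if (any(over)) {
      runs <- rle(over)
      ends <- cumsum(runs$lengths)
      hit <- which(runs$values & runs$lengths >= n_sustain)
      if (length(hit) > 0) {
        first <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
        onset_per_ch[ch] <- 1000 * lfp$time[search_idx[first]]
      }
    }
  }
  best <- if (all(is.na(onset_per_ch))) NA_integer_
          else which.min(onset_per_ch)
  structure(list(onset_ms = if (is.na(best)) NA_real_
                            else onset_per_ch[best],
                 channel = best,
                 baseline_sd = baseline_sd,
                 onset_per_channel_ms = onset_per_ch),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_ms)) {
    cat("<onset_result> no onset detected\n")
  } else {
    cat(sprintf("<onset_result> onset %.1f ms (channel %d)\n",
                x$onset_ms, x$channel))
  }
  invisible(x)
}
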