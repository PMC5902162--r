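#' Construct and validate a behavioral trial table
#'
#' One row per trial of the visual foraging task. `stimulus` is the trial's
#' grating identity (`"target"` or `"distractor"`), `orientation` its angle in
#' degrees, `hold_time` the time in seconds the stimulus spent in the reward
#' zone (0 for trials in which it never entered), `led` whether visual cortex
#' was optogenetically silenced on that trial, and `led_onset_ms` the silencing
#' onset latency relative to cortical response onset (present iff `led == "on"`).
#' The `stop` flag is derived from `hold_time` by [classify_stops()].
#'
#' @param trial_id integer trial indices (unique).
#' @param stimulus character, `"target"` or `"distractor"`.
#' @param hold_time non-negative numeric, seconds in the reward zone.
#' @param orientation stimulus orientation in degrees (defaults: 90 for
#'   targets, 45 for distractors).
#' @param led `"off"` or `"on"` per trial.
#' @param led_onset_ms LED onset latency in ms from cortical onset; `NA`
#'   when `led == "off"`.
#' @param stop optional logical stop flags (normally derived, not supplied).
#' @return a `data.frame` of class `trial_table`.
#' @export
trial_table <- function(trial_id, stimulus, hold_time,
                        orientation = ifelse(stimulus == "target", 90, 45),
                        led = "off", led_onset_ms = NA_real_, stop = NA) {
  tt <- data.frame(
    trial_id = as.integer(trial_id),
    stimulus = as.character(stimulus),
    orientation = as.numeric(orientation),
    hold_time = as.numeric(hold_time),
    led = as.character(led),
    led_onset_ms = as.numeric(led_onset_ms),
    stop = as.logical(stop),
    stringsAsFactors = FALSE
  )
  class(tt) <- c("trial_table", "data.frame")
  validate_trial_table(tt)
}

#' @rdname trial_table
#' @param tt object to validate.
#' @export
validate_trial_table <- function(tt) {
  required <- c("trial_id", "stimulus", "hold_time", "led")
  missing <- setdiff(required, names(tt))
  if (length(missing) > 0)
    stop("trial table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tt$trial_id))
    stop("trial table: duplicate trial_id", call. = FALSE)
  bad_stim <- !tt$stimulus %in% c("target", "distractor")
  if (any(bad_stim))
    stop("trial table: stimulus must be 'target' or 'distractor' (rows ",
         paste(utils::head(which(bad_stim), 5), collapse = ", "), ")",
         call. = FALSE)
  neg <- which(is.na(tt$hold_time) | tt$hold_time < 0)
  if (length(neg) > 0)
    stop("trial table: negative or missing hold_time at row(s) ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  if (any(!tt$led %in% c("off", "on")))
    stop("trial table: led must be 'off' or 'on'", call. = FALSE)
  if (!"led_onset_ms" %in% names(tt)) tt$led_onset_ms <- NA_real_
  on <- tt$led == "on"
  if (any(on & is.na(tt$led_onset_ms)))
    stop("trial table: led_onset_ms required when led == 'on'", call. = FALSE)
  if (any(!on & !is.na(tt$led_onset_ms)))
    stop("trial table: led_onset_ms must be absent when led == 'off'",
         call. = FALSE)
  if (!"stop" %in% names(tt)) tt$stop <- NA
  if (!"orientation" %in% names(tt))
    tt$orientation <- ifelse(tt$stimulus == "target", 90, 45)
  class(tt) <- unique(c("trial_table", class(tt)))
  tt
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> %d trials (%d target, %d distractor; %d LED-on)\n",
              nrow(x), sum(x$stimulus == "target"),
              sum(x$stimulus == "distractor"), sum(x$led == "on")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Construct a per-unit spike-train record
#'
#' Holds, for one sorted unit, the spike times of every trial aligned to
#' stimulus onset (seconds; negative values are pre-stimulus baseline
#' spikes). Spike times are stored sorted ascending; unsorted input is
#' normalized with a warning.
#'
#' @param unit_id identifier for the unit.
#' @param spikes named list mapping trial id to a numeric vector of spike
#'   times in seconds relative to stimulus onset (may be empty).
#' @param putative_type optional cell class, `"regular"` or `"fast-spiking"`.
#' @param layer optional cortical layer label.
#' @return an object of class `unit_recording`.
#' @export
unit_recording <- function(unit_id, spikes, putative_type = NA_character_,
                           layer = NA_character_) {
  stopifnot(is.list(spikes))
  if (is.null(names(spikes)) || any(names(spikes) == ""))
    stop("unit_recording: spikes must be a named list (names = trial ids)",
         call. = FALSE)
  unsorted <- FALSE
  spikes <- lapply(spikes, function(s) {
    s <- as.numeric(s)
    if (is.unsorted(s)) {
      unsorted <<- TRUE
      s <- sort(s)
    }
    s
  })
  if (unsorted)
    warning(sprintf("unit %s: unsorted spike times normalized to ascending order",
                    as.character(unit_id)), call. = FALSE)
  structure(
    list(unit_id = as.character(unit_id), spikes = spikes,
         putative_type = putative_type, layer = layer),
    class = "unit_recording"
  )
}

#' @export
print.unit_recording <- function(x, ...) {
  nsp <- sum(lengths(x$spikes))
  cat(sprintf("<unit_recording> %s: %d trials, %d spikes%s\n",
              x$unit_id, length(x$spikes), nsp,
              if (!is.na(x$putative_type)) paste0(" (", x$putative_type, ")")
              else ""))
  invisible(x)
}

# Check that every trial id referenced by the units resolves in the table.
check_units_trials <- function(units, trials) {
  ids <- as.character(trials$trial_id)
  for (u in units) {
    unknown <- setdiff(names(u$spikes), ids)
    if (length(unknown) > 0)
      stop(sprintf("unit %s references unknown trial id(s): %s", u$unit_id,
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a trial-averaged LFP block
#'
#' Trial-averaged voltage traces, one column per recording channel, sampled
#' at `fs` Hz and aligned so that time 0 is stimulus onset. The trace must
#' span at least -80 ms to +300 ms around onset (the baseline and search
#' windows of [detect_onset()]).
#'
#' @param traces numeric matrix, time x channel (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param t_start time of the first sample in seconds relative to stimulus
#'   onset (negative).
#' @param ground_truth_onset_ms optional known onset latency in ms
#'   (synthetic blocks only).
#' @return an object of class `lfp_block` with a `time` vector in seconds.
#' @export
lfp_block <- function(traces, fs, t_start, ground_truth_onset_ms = NA_real_) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1)
  check_positive_scalar(fs, "fs")
  time <- t_start + (seq_len(nrow(traces)) - 1) / fs
  if (time[1] > -0.080 || time[length(time)] < 0.300)
    stop("lfp_block: trace must span at least [-80, +300] ms around onset",
         call. = FALSE)
  structure(
    list(traces = traces, fs = fs, time = time,
         ground_truth_onset_ms = ground_truth_onset_ms),
    class = "lfp_block"
  )
}

#' @export
print.lfp_block <- function(x, ...) {
  cat(sprintf("<lfp_block> %d channel(s), %d samples @ %g Hz, span [%.0f, %.0f] ms\n",
              ncol(x$traces), nrow(x$traces), x$fs,
              1000 * x$time[1], 1000 * x$time[length(x$time)]))
  invisible(x)
}
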