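#' Read and write trial tables as CSV
#'
#' The on-disk format is a plain CSV with header columns `trial_id`,
#' `stimulus`, `orientation`, `hold_time`, `led`, `led_onset_ms`, `stop`.
#' Times are stored in seconds (`hold_time`) or milliseconds
#' (`led_onset_ms`); missing LED onsets are empty fields.
#'
#' @param path file path.
#' @return [read_trial_table()] returns a validated [trial_table()];
#'   [write_trial_table()] invisibly returns `path`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("trial table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "stimulus", "hold_time", "led")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("trial table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"led_onset_ms" %in% names(df)) df$led_onset_ms <- NA_real_
  if (!"stop" %in% names(df)) df$stop <- NA
  if (!"orientation" %in% names(df))
    df$orientation <- ifelse(df$stimulus == "target", 90, 45)
  trial_table(df$trial_id, df$stimulus, df$hold_time, df$orientation,
              df$led, as.numeric(df$led_onset_ms), as.logical(df$stop))
}

#' @rdname read_trial_table
#' @param trials a [trial_table()].
#' @export
write_trial_table <- function(trials, path) {
  trials <- validate_trial_table(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write unit spike records as JSON lines
#'
#' One unit per line, each line a JSON object
#' `{"unit_id": ..., "putative_type": ..., "layer": ...,
#'   "spikes": {"<trial_id>": [t1, t2, ...], ...}}` with spike times in
#' seconds relative to stimulus onset. The round trip preserves spike times
#' bit-for-bit (times are serialized at full precision).
#'
#' @param path file path.
#' @param trials optional [trial_table()]; when given, every trial id
#'   referenced by a unit must resolve in it.
#' @return [read_units()] returns a list of [unit_recording()] objects.
#' @export
read_units <- function(path, trials = NULL) {
  if (!file.exists(path)) stop("units file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  units <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    spikes <- lapply(obj$spikes, as.numeric)
    if (length(spikes) == 0) spikes <- stats::setNames(list(), character(0))
    unit_recording(obj$unit_id, spikes,
                   putative_type = obj$putative_type %||% NA_character_,
                   layer = obj$layer %||% NA_character_)
  })
  if (!is.null(trials)) check_units_trials(units, trials)
  units
}

#' @rdname read_units
#' @param units list of [unit_recording()] objects.
#' @export
write_units <- function(units, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (u in units) {
    obj <- list(unit_id = u$unit_id,
                putative_type = u$putative_type,
                layer = u$layer,
                spikes = u$spikes)
    writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read and write LFP blocks as CSV plus a JSON sidecar
#'
#' The trace matrix is stored as a CSV with one column per channel; the
#' sidecar (`<path>.json`) records the sampling rate, the time of the first
#' sample relative to stimulus onset, and the ground-truth onset for
#' synthetic blocks.
#'
#' @param path CSV file path (sidecar is `paste0(path, ".json")`).
#' @return [read_lfp()] returns an [lfp_block()].
#' @export
read_lfp <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("LFP CSV or sidecar JSON not found for: ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  traces <- as.matrix(utils::read.csv(path))
  lfp_block(traces, fs = meta$fs, t_start = meta$t_start,
            ground_truth_onset_ms = meta$ground_truth_onset_ms %||% NA_real_)
}

#' @rdname read_lfp
#' @param lfp an [lfp_block()].
#' @export
write_lfp <- function(lfp, path) {
  df <- as.data.frame(lfp$traces)
  names(df) <- paste0("ch", seq_len(ncol(lfp$traces)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = lfp$fs, t_start = lfp$time[1],
               ground_truth_onset_ms = lfp$ground_truth_onset_ms)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
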