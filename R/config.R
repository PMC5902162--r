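#' Analysis configuration
#'
#' Bundles the task and analysis constants shared across pipeline stages.
#' Defaults follow the task as run with trained animals: a ~0.9 s minimum
#' hold time for reward, a 90 degree target versus a 45 degree distractor,
#' spike-count windows laid out on a 20 ms grid from 20 to 300 ms after
#' cortical response onset, a Benjamini-Hochberg false-discovery rate of
#' 0.05, the low-rate exclusion threshold of 1 spike per 6 trials over the
#' initial 300 ms, and a 300 ms first-spike horizon.
#'
#' @param hold_time_threshold minimum hold time for a stop trial, seconds.
#' @param target_orientation,distractor_orientation degrees.
#' @param cortical_onset_override onset latency in ms to use instead of LFP
#'   detection, or `NA` to detect it from data.
#' @param interval_grid strictly increasing spike-count window ends, ms
#'   from cortical onset; must include 300.
#' @param bh_fdr false-discovery rate for the step-up correction.
#' @param exclusion_rate_threshold minimum mean spike count over the
#'   initial 300 ms for a unit to be analyzed (spikes/trial).
#' @param first_spike_horizon latency horizon in ms.
#' @param rng_seed integer seed driving all stochastic stages.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(hold_time_threshold = 0.9,
                            target_orientation = 90,
                            distractor_orientation = 45,
                            cortical_onset_override = NA_real_,
                            interval_grid = seq(20, 300, by = 20),
                            bh_fdr = 0.05,
                            exclusion_rate_threshold = 1 / 6,
                            first_spike_horizon = 300,
                            rng_seed = 1L) {
  cfg <- list(hold_time_threshold = hold_time_threshold,
              target_orientation = target_orientation,
              distractor_orientation = distractor_orientation,
              cortical_onset_override = cortical_onset_override,
              interval_grid = interval_grid,
              bh_fdr = bh_fdr,
              exclusion_rate_threshold = exclusion_rate_threshold,
              first_spike_horizon = first_spike_horizon,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

#' @rdname analysis_config
#' @param cfg object to validate.
#' @export
validate_config <- function(cfg) {
  check_positive_scalar(cfg$hold_time_threshold, "hold_time_threshold")
  g <- cfg$interval_grid
  if (length(g) == 0)
    stop("interval_grid must be non-empty", call. = FALSE)
  if (any(g <= 0) || is.unsorted(g, strictly = TRUE))
    stop("interval_grid must be strictly increasing and positive",
         call. = FALSE)
  if (!is.numeric(cfg$bh_fdr) || cfg$bh_fdr <= 0 || cfg$bh_fdr >= 1)
    stop("bh_fdr must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$exclusion_rate_threshold < 0)
    stop("exclusion_rate_threshold must be >= 0", call. = FALSE)
  check_positive_scalar(cfg$first_spike_horizon, "first_spike_horizon")
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Unspecified fields take the [analysis_config()] defaults; unknown fields
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg an `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
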