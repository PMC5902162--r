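#' Run the full analysis pipeline
#'
#' Executes every stage on supplied or synthetic inputs and writes the
#' result bundle to `out_dir`: the behavioral summary, the per-unit
#' discrimination table with the fraction-discriminating curve, the
#' first-spike latency test, per-unit Poisson fits, the tuning summary,
#' the pooling curve, the merged configuration and a run log with
#' per-stage record counts. Two runs with the same config and seed
#' produce identical outputs; every stochastic stage draws from a
#' sub-seed derived from `config$rng_seed`.
#'
#' @param config an [analysis_config()].
#' @param inputs optional named list with `trials`, `units`, `lfp`,
#'   `passive`; missing pieces are generated synthetically from
#'   `pop_spec` / `beh_spec` / `lfp_spec`.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param pop_spec,beh_spec,lfp_spec_obj specs for synthetic generation.
#' @param pool_sizes pool sizes for the pooling stage.
#' @param n_pool_samples,n_pool_repeats pooling Monte-Carlo effort.
#' @return a list of class `pipeline_result` with all stage outputs and
#'   the run log.
#' @export
run_pipeline <- function(config = analysis_config(), inputs = list(),
                         out_dir = NULL,
                         pop_spec = population_spec(),
                         beh_spec = behavior_spec(),
                         lfp_spec_obj = lfp_spec(),
                         pool_sizes = c(2, 5, 10, 20, 50),
                         n_pool_samples = 200, n_pool_repeats = 5) {
  config <- validate_config(config)
  seed <- config$rng_seed
  log <- list(seed = seed, stages = list(), warnings = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs (observed or synthetic) --------------------------------------
  pop <- NULL
  if (is.null(inputs$units) || is.null(inputs$trials)) {
    pop <- stage("simulate",
                 generate_population(pop_spec, seed = derive_seed(seed, 1)))
    units <- pop$units
    phys_trials <- pop$trials
  } else {
    units <- inputs$units
    phys_trials <- validate_trial_table(inputs$trials)
  }
  beh_trials <- if (!is.null(inputs$behavior_trials)) {
    validate_trial_table(inputs$behavior_trials)
  } else {
    stage("simulate", generate_behavior(beh_spec, seed = derive_seed(seed, 2)))
  }
  lfp <- inputs$lfp
  if (is.null(lfp))
    lfp <- stage("simulate", generate_lfp(lfp_spec_obj,
                                          seed = derive_seed(seed, 3)))
  log$stages$inputs <- list(n_units = length(units),
                            n_phys_trials = nrow(phys_trials),
                            n_behavior_trials = nrow(beh_trials))

  # --- behavior ------------------------------------------------------------
  behavior <- stage("behavior",
                    behavior_summary(beh_trials, config$hold_time_threshold))

  # --- cortical onset ------------------------------------------------------
  onset_ms <- config$cortical_onset_override
  onset <- NULL
  if (is.na(onset_ms)) {
    onset <- stage("onset", detect_onset(lfp))
    onset_ms <- onset$onset_ms
    if (is.na(onset_ms))
      stop("pipeline stage 'onset' failed: no onset detected and no override",
           call. = FALSE)
  }

  # --- discrimination ------------------------------------------------------
  filt <- stage("discriminate",
                exclusion_filter(units, onset_ms,
                                 config$exclusion_rate_threshold))
  disc <- stage("discriminate",
                discrimination_curve(filt$retained, phys_trials, onset_ms,
                                     config$interval_grid, config$bh_fdr))
  log$stages$discriminate <- list(n_retained = length(filt$retained),
                                  n_excluded = length(filt$excluded),
                                  n_discriminating =
                                    sum(disc$units$discriminating))

  # --- first-spike variant -------------------------------------------------
  fs_units <- lapply(filt$retained, first_spike_reduce, onset_ms = onset_ms)
  disc_first <- stage("firstspike",
                      discrimination_curve(fs_units, phys_trials, onset_ms,
                                           config$interval_grid,
                                           config$bh_fdr))

  # --- latency + Poisson stats --------------------------------------------
  prefs <- stats::setNames(disc$units$preference, disc$units$unit_id)
  disc_ids <- disc$units$unit_id[disc$units$discriminating]
  lat_units <- filt$retained[vapply(filt$retained, `[[`, "", "unit_id")
                             %in% disc_ids]
  latency <- NULL
  if (length(lat_units) >= 2) {
    pairs <- collect_latency_pairs(lat_units, phys_trials, prefs, onset_ms,
                                   config$first_spike_horizon)
    latency <- tryCatch(latency_difference_test(pairs),
                        error = function(e) NULL)
  }
  pois <- stage("report", {
    do.call(rbind, lapply(lat_units, function(u) {
      pref_ids <- phys_trials$trial_id[
        phys_trials$stimulus == prefs[[u$unit_id]]]
      counts <- count_in_window(u, as.character(pref_ids), onset_ms, 80)
      pf <- poisson_fit(counts)
      data.frame(unit_id = u$unit_id, lambda = pf$lambda, r2 = pf$r2,
                 stringsAsFactors = FALSE)
    }))
  })

  # --- tuning --------------------------------------------------------------
  passive <- inputs$passive
  if (is.null(passive) && !is.null(pop))
    passive <- generate_passive(pop_spec, seed = derive_seed(seed, 4),
                                preferences = pop$preferences)
  tuning <- if (!is.null(passive)) stage("tuning", tuning_summary(passive))
            else NULL

  # --- pooling -------------------------------------------------------------
  pool <- stage("pooling",
                pool_counts(filt$retained, phys_trials, onset_ms, 80,
                            preferences = prefs))
  pool <- augment_pool(pool, n_copies = 6, seed = derive_seed(seed, 5))
  pcurve <- stage("pooling",
                  pooling_curve(pool, pool_sizes, n_pool_samples,
                                n_pool_repeats, seed = derive_seed(seed, 6),
                                behavior_accuracy = behavior$accuracy / 100))
  log$stages$pooling <- list(pool_size = length(pool),
                             Ns = pcurve$curve$N)

  result <- structure(list(
    config = config, behavior = behavior, onset = onset, onset_ms = onset_ms,
    excluded_units = vapply(filt$excluded, `[[`, "", "unit_id"),
    discrimination = disc, discrimination_first_spike = disc_first,
    latency = latency, poisson_fits = pois, tuning = tuning,
    pooling = pcurve, run_log = log
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @rdname run_pipeline
#' @param result a `pipeline_result`.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_config(result$config, p("config.yaml"))
  utils::write.csv(result$discrimination$table, p("discrimination.csv"),
                   row.names = FALSE)
  utils::write.csv(result$discrimination$fraction_discriminating,
                   p("fraction_discriminating.csv"), row.names = FALSE)
  utils::write.csv(result$poisson_fits, p("poisson_fits.csv"),
                   row.names = FALSE)
  if (!is.null(result$tuning))
    utils::write.csv(result$tuning, p("tuning.csv"), row.names = FALSE)
  utils::write.csv(result$pooling$curve, p("pooling_curve.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = result$run_log$seed,
    onset_ms = result$onset_ms,
    behavior = result$behavior[c("n_trials", "stop_prob_target",
                                 "stop_prob_distractor", "accuracy",
                                 "ideal_observer_auc", "ranksum_p")],
    n_excluded = length(result$excluded_units),
    n_discriminating = sum(result$discrimination$units$discriminating),
    effective_cutoff = result$discrimination$effective_cutoff,
    latency_difference_ms =
      if (!is.null(result$latency)) result$latency$mean_difference_ms
      else NULL,
    pooling_readout_N = result$pooling$readout_N,
    run_log = result$run_log
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cortical onset: %.1f ms\n", x$onset_ms))
  cat(sprintf("  behavior accuracy: %.1f%%\n", x$behavior$accuracy))
  cat(sprintf("  units: %d analyzed (+%d excluded), %d discriminating\n",
              nrow(x$discrimination$units), length(x$excluded_units),
              sum(x$discrimination$units$discriminating)))
  if (!is.null(x$latency))
    cat(sprintf("  first-spike latency difference: %.1f ms (p = %.3g)\n",
                x$latency$mean_difference_ms, x$latency$p))
  invisible(x)
}
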