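#' Orientation tuning curve from passive-viewing responses
#'
#' Averages spike counts (or rates) across repetitions per orientation and
#' normalizes by the maximal mean across orientations. An all-zero
#' responder keeps zero rates and is flagged degenerate.
#'
#' @param passive a `data.frame` with columns `orientation` (degrees) and
#'   `count` (one row per repetition), for a single unit.
#' @param n_orientations expected number of distinct orientations
#'   (default 12, i.e. 15 degree steps); fewer is an error.
#' @return a list of class `tuning_curve`: `thetas`, `rates` (normalized),
#'   `raw` (mean per orientation), `degenerate`.
#' @export
tuning_curve <- function(passive, n_orientations = 12) {
  stopifnot(all(c("orientation", "count") %in% names(passive)))
  agg <- tapply(passive$count, passive$orientation, mean)
  thetas <- as.numeric(names(agg))
  if (length(thetas) < n_orientations)
    stop(sprintf("missing orientation(s): expected %d, got %d",
                 n_orientations, length(thetas)), call. = FALSE)
  raw <- as.numeric(agg)
  mx <- max(raw)
  structure(list(thetas = thetas,
                 rates = if (mx > 0) raw / mx else raw,
                 raw = raw,
                 degenerate = mx <= 0),
            class = "tuning_curve")
}

# doubled-angle tuning vector (x, y); rates may be raw or normalized --
# the derived angle and OSI are invariant to uniform scaling.
tuning_vector <- function(tc) {
  rad2 <- 2 * tc$thetas * pi / 180
  c(x = sum(tc$rates * cos(rad2)), y = sum(tc$rates * sin(rad2)))
}

#' Preferred orientation of a tuning curve
#'
#' The circular vector average in doubled-angle space:
#' `0.5 * atan2(sum r sin 2theta, sum r cos 2theta)`, mapped to
#' `[0, 180)` degrees. A curve whose tuning vector vanishes (e.g. uniform
#' rates) has no defined preference and raises an error.
#'
#' @param tc a [tuning_curve()].
#' @return preferred orientation in degrees, in `[0, 180)`.
#' @export
preferred_orientation <- function(tc) {
  v <- tuning_vector(tc)
  if (sqrt(sum(v^2)) < 1e-9)
    stop("degenerate tuning: zero tuning vector", call. = FALSE)
  unname((0.5 * atan2(v["y"], v["x"]) * 180 / pi) %% 180)
}

#' Orientation selectivity index
#'
#' Vector strength of the tuning curve in doubled-angle space:
#' `sqrt((sum r sin 2theta)^2 + (sum r cos 2theta)^2) / sum r`.
#' 0 for an untuned (uniform) curve, 1 for a unit responding to a single
#' orientation.
#'
#' @param tc a [tuning_curve()].
#' @return OSI in `[0, 1]`.
#' @export
osi <- function(tc) {
  tot <- sum(tc$rates)
  if (tot <= 0) stop("all-zero tuning curve", call. = FALSE)
  v <- tuning_vector(tc)
  unname(sqrt(sum(v^2)) / tot)
}

#' Receptive-field center of mass
#'
#' From sparse-noise grid responses: responses are peak-normalized,
#' averaged across channels, the white- and black-square maps averaged,
#' and the center of the receptive field taken as the center of mass of
#' the resulting map in stimulus-grid degrees.
#'
#' @param grid a `data.frame` with columns `azimuth`, `elevation`
#'   (degrees), `polarity` (`"white"`/`"black"`), `channel`, `response`
#'   (baseline-subtracted counts; negative values are floored at 0).
#' @return a list of class `rf_map`: `center` (named vector
#'   azimuth/elevation), `map` (aggregated data.frame).
#' @export
rf_center <- function(grid) {
  stopifnot(all(c("azimuth", "elevation", "polarity", "response") %in%
                  names(grid)))
  g <- grid
  g$response <- pmax(g$response, 0)
  mx <- max(g$response)
  if (mx <= 0) stop("all-zero receptive-field map", call. = FALSE)
  g$response <- g$response / mx
  # average across channels within location x polarity, then across polarity
  by_pol <- stats::aggregate(response ~ azimuth + elevation + polarity,
                             data = g, FUN = mean)
  map <- stats::aggregate(response ~ azimuth + elevation, data = by_pol,
                          FUN = mean)
  w <- map$response / sum(map$response)
  structure(list(center = c(azimuth = sum(w * map$azimuth),
                            elevation = sum(w * map$elevation)),
                 map = map),
            class = "rf_map")
}

#' Linear fit of windowed ROC value against passive count difference
#'
#' Ordinary least-squares fit of each unit's 80 ms ROC value during the
#' task against its passive-viewing spike-count difference between the
#' target and distractor orientations (signed so target-preferring units
#' sit at positive x). Standard errors of slope and intercept come from
#' the inverse of the information matrix (the standard OLS covariance);
#' `r2` is the fraction of variance explained, and a one-sided test of
#' slope > 0 is reported.
#'
#' @param dcount_passive per-unit passive count differences (x).
#' @param auc_task per-unit ROC values (y).
#' @return a list of class `roc_fit`: `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `r2`, `p_slope_positive`, `n`.
#' @export
auc_vs_dspikes_fit <- function(dcount_passive, auc_task) {
  x <- as.numeric(dcount_passive)
  y <- as.numeric(auc_task)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  t_slope <- co["x", "t value"]
  structure(list(slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 se_slope = co["x", "Std. Error"],
                 se_intercept = co["(Intercept)", "Std. Error"],
                 r2 = sm$r.squared,
                 p_slope_positive = stats::pt(t_slope, df = fit$df.residual,
                                              lower.tail = FALSE),
                 n = length(x)),
            class = "roc_fit")
}

#' @export
print.roc_fit <- function(x, ...) {
  cat(sprintf(paste0("<roc_fit> auc = %.3f + %.3f * dcount (SEs %.3f / ",
                     "%.3f), R^2 = %.2f, one-sided p(slope>0) = %.3g\n"),
              x$intercept, x$slope, x$se_intercept, x$se_slope, x$r2,
              x$p_slope_positive))
  invisible(x)
}

#' Per-unit tuning summary table
#'
#' Applies [tuning_curve()], [preferred_orientation()] and [osi()] to every
#' unit in a passive-response table.
#'
#' @param passive output of [generate_passive()] or a table with columns
#'   `unit_id`, `orientation`, `count`.
#' @return a `data.frame` with `unit_id`, `preferred`, `osi`,
#'   `peak_orientation`, `degenerate` (degenerate/uniform units get `NA`
#'   preference and OSI).
#' @export
tuning_summary <- function(passive) {
  ids <- unique(passive$unit_id)
  rows <- lapply(ids, function(id) {
    tc <- tuning_curve(passive[passive$unit_id == id, ])
    pref <- tryCatch(preferred_orientation(tc), error = function(e) NA_real_)
    o <- tryCatch(osi(tc), error = function(e) NA_real_)
    data.frame(unit_id = id, preferred = pref, osi = o,
               peak_orientation = tc$thetas[which.max(tc$rates)],
               degenerate = tc$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
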