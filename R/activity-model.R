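#' Calibration point: one reference compound
#'
#' Pairs a summarized conformational distance (mean +/- SEM over blocks or
#' replicates) with the in vitro activity that compound induces, expressed
#' as percent of the no-PAM control (100 = control level).
#'
#' @param compound_id compound identifier.
#' @param distance a `replicate_summary`, or a bare number (then `unit`
#'   must be given).
#' @param activity_pct activity as percent of control (> 0).
#' @param activity_sem optional SEM of the activity (percent).
#' @param unit distance unit when `distance` is a bare number.
#' @return object of class `calibration_point`.
#' @export
calibration_point <- function(compound_id, distance, activity_pct,
                              activity_sem = NA_real_, unit = NULL) {
  if (inherits(distance, "replicate_summary")) {
    d_mean <- distance$mean; d_sem <- distance$sem; d_unit <- distance$unit
  } else {
    if (is.null(unit)) stop("unit required when distance is a bare number")
    d_mean <- as.numeric(distance); d_sem <- NA_real_; d_unit <- unit
  }
  if (!is.finite(d_mean) || d_mean <= 0) stop("distance mean must be > 0")
  if (!is.finite(activity_pct) || activity_pct <= 0)
    stop("activity_pct must be > 0 (percent of control)")
  structure(list(compound_id = compound_id, distance_mean = d_mean,
                 distance_sem = d_sem, unit = d_unit,
                 activity_pct = activity_pct, activity_sem = activity_sem),
            class = "calibration_point")
}

#' Fit the linear distance-to-activity calibration
#'
#' Ordinary least squares of activity (percent of control) on the mean
#' residue-pair distance. Unweighted by default: the reference analysis
#' fits a plain slope through points that carry SEMs on both axes without a
#' stated weighting scheme; inverse-variance weighting by the activity SEM
#' is available behind `weighted = TRUE`.
#'
#' @param points list of [calibration_point] objects (>= 3, distances not
#'   all equal, one common distance unit).
#' @param weighted use 1/activity_sem^2 weights (requires finite SEMs).
#' @return object of class `calibration_model` with slope (percent per
#'   distance unit), intercept (percent), Pearson r, R^2, residual standard
#'   error (n-2 dof), n, and the leverage terms needed for prediction
#'   intervals.
#' @export
fit_calibration <- function(points, weighted = FALSE) {
  if (length(points) < 3L) stop("need >= 3 calibration points")
  stopifnot(all(vapply(points, inherits, logical(1L), "calibration_point")))
  units <- unique(vapply(points, `[[`, character(1L), "unit"))
  if (length(units) != 1L)
    stop("calibration points carry mixed distance units: ",
         paste(units, collapse = ", "))
  x <- vapply(points, `[[`, numeric(1L), "distance_mean")
  y <- vapply(points, `[[`, numeric(1L), "activity_pct")
  if (stats::var(x) == 0) stop("degenerate calibration: all distances equal")
  w <- NULL
  if (weighted) {
    sems <- vapply(points, `[[`, numeric(1L), "activity_sem")
    if (any(!is.finite(sems)) || any(sems <= 0))
      stop("weighted fit requires positive finite activity_sem on every point")
    w <- 1 / sems^2
  }
  fit <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  structure(list(
    slope = unname(co[2L]), intercept = unname(co[1L]),
    r = r, r_squared = r^2,
    residual_se = suppressWarnings(summary(fit)$sigma), n = length(x),
    distance_unit = units,
    x_mean = mean(x), sxx = sum((x - mean(x))^2),
    compound_ids = vapply(points, `[[`, character(1L), "compound_id"),
    x = x, y = y, fitted = unname(stats::fitted(fit)),
    weighted = weighted
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> activity%% = %.4g * distance(%s) ",
                     "%+.4g\n  r = %.4f, R^2 = %.4f, residual SE = %.3g%%, n = %d\n"),
              x$slope, x$distance_unit, x$intercept, x$r, x$r_squared,
              x$residual_se, x$n))
  invisible(x)
}

#' Serialize a calibration model to JSON
#' @param model a `calibration_model`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
calibration_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- model[c("slope", "intercept", "r", "r_squared", "residual_se",
                 "n", "distance_unit")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Predict activity from a distance summary
#'
#' Point prediction `slope * x + intercept` with a t-based prediction
#' interval (n-2 dof) accounting for the x-leverage of the new point, and a
#' margin over a supplied reference activity (e.g. 230 for the benchmark
#' activator, or 100 for the no-PAM control).
#'
#' @param model a fitted `calibration_model`.
#' @param distance a `replicate_summary` (or bare number with `unit`).
#' @param reference_activity_pct reference activity percent (default 100,
#'   the no-PAM control level).
#' @param level prediction-interval level (default 0.95).
#' @param compound_id identifier carried through to the output.
#' @param unit distance unit when `distance` is a bare number.
#' @return object of class `activity_prediction`.
#' @export
predict_activity <- function(model, distance, reference_activity_pct = 100,
                             level = 0.95, compound_id = "",
                             unit = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(distance, "replicate_summary")) {
    x0 <- distance$mean; d_unit <- distance$unit
  } else {
    if (is.null(unit)) stop("unit required when distance is a bare number")
    x0 <- as.numeric(distance); d_unit <- unit
  }
  if (!identical(d_unit, model$distance_unit))
    stop(sprintf("distance unit '%s' does not match model unit '%s'",
                 d_unit, model$distance_unit))
  pred <- model$slope * x0 + model$intercept
  se_pred <- model$residual_se *
    sqrt(1 + 1 / model$n + (x0 - model$x_mean)^2 / model$sxx)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = model$n - 2L)
  structure(list(
    compound_id = compound_id,
    distance_mean = x0, distance_unit = d_unit,
    predicted_activity_pct = pred,
    interval_low = pred - tcrit * se_pred,
    interval_high = pred + tcrit * se_pred,
    level = level,
    reference_activity_pct = reference_activity_pct,
    reference_margin = pred - reference_activity_pct
  ), class = "activity_prediction")
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(sprintf("<activity_prediction> %s: %.1f%% [%.1f, %.1f] (%d%% PI), margin %+.1f vs reference %.0f%%\n",
              x$compound_id, x$predicted_activity_pct, x$interval_low,
              x$interval_high, round(100 * x$level), x$reference_margin,
              x$reference_activity_pct))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used throughout the calibration module; errors on
#' degenerate input instead of returning NA.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  stats::cor(x, y)
}

#' Rank predicted activities and flag activators
#'
#' @param predictions list of [predict_activity()] results.
#' @param threshold_pct activator flag threshold (default 100, the no-PAM
#'   control level).
#' @return data.frame sorted descending by predicted activity with a
#'   logical `activator` column.
#' @export
rank_candidates <- function(predictions, threshold_pct = 100) {
  if (length(predictions) < 1L) stop("need >= 1 prediction")
  stopifnot(all(vapply(predictions, inherits, logical(1L),
                       "activity_prediction")))
  df <- do.call(rbind, lapply(predictions, function(p) data.frame(
    compound_id = p$compound_id,
    distance_mean = p$distance_mean,
    predicted_activity_pct = p$predicted_activity_pct,
    interval_low = p$interval_low, interval_high = p$interval_high,
    reference_margin = p$reference_margin,
    stringsAsFactors = FALSE)))
  df <- df[order(-df$predicted_activity_pct, df$compound_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$activator <- df$predicted_activity_pct >= threshold_pct
  rownames(df) <- NULL
  df
}
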