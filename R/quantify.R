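#' @title Duration quantification
#' @description Converts probability rasters into the pipeline's headline
#'   quantity: seconds of each vocalization type per minute (s/min). A
#'   0.7 probability threshold filters out uncertain detections; the number
#'   of detected 240 ms frames times the frame duration gives the duration.
#'   Per-minute values are aggregated hourly and binned into the four
#'   diurnal periods and three rearing phases for the statistical stage.
#' @name quantify
NULL

#' Per-minute vocalization durations from a probability raster
#'
#' For each vocalization type and wall-clock minute, counts the prediction
#' frames whose score reaches the threshold (inclusive) and multiplies by
#' the 0.24 s frame duration. Because the six scores in a row sum to one
#' and the threshold exceeds 0.5, at most one class can be detected per
#' frame, so per-minute durations over the five types sum to at most 60 s.
#' The background class is not reported.
#'
#' @param raster A `prob_raster` (see [infer()]), or a plain `T x 6` score
#'   matrix with columns `MODEL_CLASSES`. Rows must sum to 1 (tolerance
#'   1e-4); others are rejected.
#' @param threshold Detection threshold on the probability score
#'   (default 0.7).
#' @return `data.frame` with columns `minute` (wall-clock minute index,
#'   from `start_clock`), `clock_hour`, and one duration column per
#'   `CALL_TYPES`, each in `[0, 60]`.
#' @export
threshold_durations <- function(raster, threshold = 0.7) {
  if (inherits(raster, "prob_raster")) {
    scores <- raster$scores
    start_clock <- raster$start_clock
    frame_s <- raster$frame_duration
  } else {
    scores <- raster
    start_clock <- 0
    frame_s <- PRED_FRAME_S
  }
  stopifnot(is.matrix(scores), ncol(scores) == 6)
  if (nrow(scores) &&
      max(abs(rowSums(scores) - 1)) > 1e-4)
    stop("raster rows must sum to 1")
  if (is.null(colnames(scores))) colnames(scores) <- MODEL_CLASSES
  n <- nrow(scores)
  t_mid <- start_clock + (seq_len(n) - 0.5) * frame_s
  minute <- floor(t_mid / 60)
  out <- data.frame(minute = sort(unique(minute)))
  for (type in CALL_TYPES) {
    det <- scores[, type] >= threshold
    out[[type]] <- vapply(out$minute, function(m)
      sum(det[minute == m]) * frame_s, 0)
  }
  out$clock_hour <- (out$minute / 60) %% 24
  out[, c("minute", "clock_hour", CALL_TYPES)]
}

#' Hourly aggregation of per-minute durations
#'
#' Arithmetic mean of the per-minute durations within each wall-clock hour,
#' in s/min. Minutes missing from the input are excluded from the
#' denominator; an hour with no recorded minutes yields no row (missing
#' value, never zero, which would bias diurnal means).
#'
#' @param minutes Output of [threshold_durations()] (or any data frame with
#'   a `minute` column and `CALL_TYPES` columns).
#' @return `data.frame` with `hour` (wall-clock hour index), `clock_hour`
#'   (0-23), `n_minutes`, and mean s/min per type.
#' @export
aggregate_hourly <- function(minutes) {
  stopifnot(nrow(minutes) >= 1)
  hour <- floor(minutes$minute / 60)
  out <- data.frame(hour = sort(unique(hour)))
  out$clock_hour <- out$hour %% 24
  out$n_minutes <- vapply(out$hour, function(h) sum(hour == h), 0)
  for (type in CALL_TYPES)
    out[[type]] <- vapply(out$hour, function(h)
      mean(minutes[[type]][hour == h]), 0)
  out
}

#' Diurnal time-of-day bin of a clock hour
#'
#' Night spans 10 PM to 4 AM, morning 4 AM to 10 AM, midday 10 AM to 4 PM,
#' evening 4 PM to 10 PM; each bin is half-open `[start, end)` so the four
#' bins partition the 24 h clock.
#'
#' @param hour_of_day Integer or fractional clock hour in `[0, 24)`.
#' @return Factor with levels `night, morning, midday, evening`.
#' @export
bin_time_of_day <- function(hour_of_day) {
  if (any(hour_of_day < 0 | hour_of_day >= 24))
    stop("hour_of_day must be in [0, 24)")
  lab <- ifelse(hour_of_day >= 4 & hour_of_day < 10, "morning",
         ifelse(hour_of_day >= 10 & hour_of_day < 16, "midday",
         ifelse(hour_of_day >= 16 & hour_of_day < 22, "evening", "night")))
  factor(lab, levels = c("night", "morning", "midday", "evening"))
}

#' Rearing phase of an age
#'
#' Starter covers days 0-9, grower days 10-22, finisher days 23-41
#' (following the feed-phase definitions; the phases partition days 0-41).
#'
#' @param age_days Integer age in days, 0-41.
#' @return Factor with levels `starter, grower, finisher`.
#' @export
assign_phase <- function(age_days) {
  if (any(age_days < 0 | age_days > 41))
    stop("age_days must be in [0, 41]")
  lab <- ifelse(age_days <= 9, "starter",
         ifelse(age_days <= 22, "grower", "finisher"))
  factor(lab, levels = c("starter", "grower", "finisher"))
}

#' Diurnal-bin means of hourly aggregates
#'
#' Mean s/min per call type within each diurnal bin (weighting each hour by
#' its recorded minutes).
#'
#' @param hourly Output of [aggregate_hourly()].
#' @return `data.frame` with `bin` and one column per call type.
#' @export
bin_means <- function(hourly) {
  bin <- bin_time_of_day(hourly$clock_hour)
  out <- data.frame(bin = levels(bin))
  for (type in CALL_TYPES)
    out[[type]] <- vapply(out$bin, function(b) {
      i <- bin == b
      if (!any(i)) return(NA_real_)
      sum(hourly[[type]][i] * hourly$n_minutes[i]) /
        sum(hourly$n_minutes[i])
    }, 0)
  out
}
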