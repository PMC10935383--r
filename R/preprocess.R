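# Modality-specific missing-data definitions, wear-time rules and exclusions.

#' Resample a CGM series onto a uniform 15-min grid
#'
#' The grid is anchored at the first raw sample and each grid value is
#' linearly interpolated from the bracketing raw samples. Under the default
#' `"both_neighbors"` rule a grid point is missing when the nearest raw
#' sample before it *and* the nearest raw sample after it are each more than
#' `missing_threshold_minutes` (18) away; a boundary grid point with a
#' neighbour on one side only is missing when that neighbour is further than
#' the threshold. Under `"long_interval"` a grid point is missing when it
#' lies inside a raw inter-sample interval longer than
#' `long_interval_minutes` (19) and further than half a grid step from the
#' nearest raw sample - the reading motivated by the fact that
#' nearly all intact sampling intervals are shorter than that, so any longer
#' interval indicates lost readings. The `"both_neighbors"` rule is more
#' conservative: it cannot mark any grid point inside an interval shorter
#' than about `2 * threshold + grid step`, so it never resolves gaps of one
#' or two grid samples.
#'
#' @param raw a glucose [raw_series()] with at least 2 samples.
#' @param config an [analysis_config()].
#' @return A [recording()] on the uniform grid.
#' @export
resample_glucose <- function(raw, config = analysis_config()) {
  stopifnot(inherits(raw, "wm_raw_series"), inherits(config, "wm_config"))
  if (raw$modality != "glucose") stop("resample_glucose expects a glucose series")
  n <- length(raw$values)
  if (n < 2L) stop("glucose series has fewer than 2 raw samples")
  step_s <- config$grid_minutes * 60
  t_raw <- as.numeric(raw$timestamps)
  t0 <- t_raw[1L]
  k_max <- floor((t_raw[n] - t0) / step_s)
  grid <- t0 + (0:k_max) * step_s
  vals <- stats::approx(t_raw, raw$values, xout = grid, ties = "ordered")$y
  i <- findInterval(grid, t_raw)                 # t_raw[i] <= grid point
  d_prev <- (grid - t_raw[i]) / 60
  d_next <- ifelse(i < n, (t_raw[i + 1L] - grid) / 60, NA_real_)
  thr <- config$missing_threshold_minutes
  if (config$cgm_missing_rule == "both_neighbors") {
    miss <- ifelse(is.na(d_next), d_prev > thr, d_prev > thr & d_next > thr)
  } else {
    # interior of a long raw interval, excluding grid points that sit within
    # half a grid step of a surviving raw sample
    half <- config$grid_minutes / 2
    miss <- !is.na(d_next) & pmin(d_prev, d_next) > half &
      (d_prev + d_next) > config$long_interval_minutes
  }
  vals[miss] <- NA_real_
  recording(raw$subject_id, "glucose", raw$timestamps[1L], config$grid_minutes,
            0:k_max, vals, miss)
}

# fill a 1/min grid spanning the raw series; absent minutes get the device's
# zero coding
fill_minute_grid <- function(raw) {
  t_raw <- as.numeric(raw$timestamps)
  t0 <- floor(t_raw[1L] / 60) * 60
  idx_all <- 0:floor((t_raw[length(t_raw)] - t0) / 60)
  vals <- numeric(length(idx_all))
  vals[floor((t_raw - t0) / 60) + 1L] <- raw$values
  list(start = as.POSIXct(t0, tz = "UTC", origin = "1970-01-01"),
       index = idx_all, values = vals)
}

#' Define heart-rate missingness
#'
#' The tracker codes absent measurements as zero, so zero heart-rate values
#' (including minutes absent from the export, which are filled as zero) are
#' classified as missing.
#'
#' @param raw an hr [raw_series()].
#' @return A [recording()] on the 1-min grid with `missing` true exactly
#'   where the heart rate is zero.
#' @export
define_hr_missing <- function(raw) {
  stopifnot(inherits(raw, "wm_raw_series"))
  if (raw$modality != "hr") stop("define_hr_missing expects an hr series")
  if (any(raw$values < 0)) stop("negative heart rate values")
  g <- fill_minute_grid(raw)
  miss <- g$values == 0
  vals <- g$values
  vals[miss] <- NA_real_
  recording(raw$subject_id, "hr", g$start, 1, g$index, vals, miss)
}

#' Define step-count missingness
#'
#' A minute is missing when both steps and heart rate are zero (the device
#' measured neither channel). Additionally, any maximal run of at least
#' `zero_step_run_minutes` (2 h) consecutive zero-step minutes whose span
#' intersects the day window (08:00-22:00) is marked missing in full,
#' including any portion outside the window. Zero steps with heart rate
#' present outside such runs remain observed zeros (a worn but idle device).
#'
#' @param steps_raw a steps [raw_series()].
#' @param hr_rec the subject's hr [recording()] on the same minute grid.
#' @param config an [analysis_config()].
#' @return A steps [recording()].
#' @export
define_steps_missing <- function(steps_raw, hr_rec, config = analysis_config()) {
  stopifnot(inherits(steps_raw, "wm_raw_series"), inherits(hr_rec, "wm_recording"))
  if (steps_raw$modality != "steps") stop("define_steps_missing expects a steps series")
  if (any(steps_raw$values < 0)) stop("negative step counts")
  g <- fill_minute_grid(steps_raw)
  if (!identical(as.numeric(g$start), as.numeric(hr_rec$grid_start)) ||
      length(g$index) != length(hr_rec$index) ||
      hr_rec$grid_step_min != 1) {
    stop("steps grid does not match the hr recording grid")
  }
  zero <- g$values == 0
  miss <- zero & hr_rec$missing

  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  clock_min <- (as.POSIXlt(g$start)$hour * 60L + as.POSIXlt(g$start)$min +
                  g$index) %% 1440L
  win <- config$day_window * 60
  in_window <- clock_min >= win[1] & clock_min < win[2]
  for (j in which(r$values & r$lengths >= config$zero_step_run_minutes)) {
    span <- starts[j]:ends[j]
    if (any(in_window[span])) miss[span] <- TRUE
  }
  vals <- g$values
  vals[miss] <- NA_real_
  recording(steps_raw$subject_id, "steps", g$start, 1, g$index, vals, miss)
}

#' Remove non-wear days
#'
#' Days are segmented by the local calendar. A day counts as non-wear when
#' observed heart-rate minutes fall below `hr_wear_fraction` (70%) of the
#' day's covered minutes, or when at most `min_daily_steps` (1000) observed
#' steps were recorded inside the day window. Thresholds are pro-rated for
#' partially covered first/last days. Non-wear days are excised from both
#' recordings (their samples are removed, not marked missing) and logged.
#'
#' @param hr_rec hr [recording()].
#' @param steps_rec steps [recording()] on the same grid, or `NULL` (then
#'   only the heart-rate criterion applies).
#' @param config an [analysis_config()].
#' @return List with elements `hr`, `steps` (filtered recordings) and
#'   `exclusions` (log data frame).
#' @export
filter_wear_days <- function(hr_rec, steps_rec = NULL, config = analysis_config()) {
  stopifnot(inherits(hr_rec, "wm_recording"))
  clk <- rec_clock(hr_rec)
  days <- unique(clk$daynum)
  drop <- logical(length(hr_rec$index))
  log <- empty_exclusion_log()
  win <- config$day_window * 60
  for (d in days) {
    sel <- clk$daynum == d
    covered <- sum(sel)
    hr_obs <- sum(!hr_rec$missing[sel])
    hr_ok <- hr_obs >= config$hr_wear_fraction * covered
    steps_ok <- TRUE
    steps_total <- NA_real_
    if (!is.null(steps_rec)) {
      in_win <- sel & clk$minute_of_day >= win[1] & clk$minute_of_day < win[2]
      covered_win <- sum(in_win)
      if (covered_win > 0) {
        steps_total <- sum(steps_rec$values[in_win & !steps_rec$missing], na.rm = TRUE)
        steps_ok <- steps_total > config$min_daily_steps * covered_win /
          (win[2] - win[1])
      }
    }
    if (!hr_ok || !steps_ok) {
      drop[sel] <- TRUE
      log <- rbind(log, exclusion_entry(
        hr_rec$subject_id, if (!hr_ok) "hr" else "steps", "day",
        if (!hr_ok) "hr_wear" else "min_steps",
        if (!hr_ok) 100 * hr_obs / covered else steps_total))
    }
  }
  keep <- !drop
  sub_rec <- function(r) {
    recording(r$subject_id, r$modality, r$grid_start, r$grid_step_min,
              r$index[keep], r$values[keep], r$missing[keep])
  }
  list(hr = sub_rec(hr_rec),
       steps = if (is.null(steps_rec)) NULL else sub_rec(steps_rec),
       exclusions = log)
}

#' Exclude recordings with excessive data loss
#'
#' Recordings missing strictly more than `max_recording_loss_fraction` (50%)
#' of their samples are removed and logged with their loss percentage.
#'
#' @param recordings list of [recording()] objects.
#' @param config an [analysis_config()].
#' @return List with `retained` (list of recordings) and `exclusions` (log).
#' @export
exclude_recordings <- function(recordings, config = analysis_config()) {
  log <- empty_exclusion_log()
  keep <- vapply(recordings, function(r) {
    frac <- missing_fraction(r)
    ok <- !is.na(frac) && frac <= config$max_recording_loss_fraction
    if (!ok) {
      log <<- rbind(log, exclusion_entry(r$subject_id, r$modality, "recording",
                                         "recording_loss", 100 * frac))
    }
    ok
  }, logical(1))
  list(retained = recordings[keep], exclusions = log)
}

#' Preprocess a cohort of raw series
#'
#' Applies the full preprocessing chain: CGM resampling and its missing-data
#' rule, zero-coding rules for heart rate and steps, wear-day filtering, and
#' recording-level exclusion.
#'
#' @param raw a `wm_cohort`, a long data frame (columns `subject_id`,
#'   `modality`, `timestamp`, `value`) or a list of [raw_series()].
#' @param config an [analysis_config()].
#' @return List with `recordings` (named `subject.modality` list) and
#'   `exclusions` (log data frame).
#' @export
preprocess_cohort <- function(raw, config = analysis_config()) {
  series <- if (inherits(raw, "wm_cohort")) {
    series_from_long(raw$raw)
  } else if (is.data.frame(raw)) {
    series_from_long(raw)
  } else raw
  log <- empty_exclusion_log()
  by_subject <- split(series, vapply(series, function(s) s$subject_id, character(1)))
  recs <- list()
  for (sid in names(by_subject)) {
    mods <- vapply(by_subject[[sid]], function(s) s$modality, character(1))
    ss <- stats::setNames(by_subject[[sid]], mods)
    hr_rec <- steps_rec <- NULL
    if ("hr" %in% mods) hr_rec <- define_hr_missing(ss$hr)
    if ("steps" %in% mods) {
      if (is.null(hr_rec)) {
        log <- rbind(log, exclusion_entry(sid, "steps", "recording",
                                          "no_hr_for_steps", NA_real_))
      } else {
        steps_rec <- define_steps_missing(ss$steps, hr_rec, config)
      }
    }
    if (!is.null(hr_rec)) {
      f <- filter_wear_days(hr_rec, steps_rec, config)
      hr_rec <- f$hr; steps_rec <- f$steps
      log <- rbind(log, f$exclusions)
    }
    if ("glucose" %in% mods) {
      glu <- tryCatch(resample_glucose(ss$glucose, config), error = function(e) {
        log <<- rbind(log, exclusion_entry(sid, "glucose", "recording",
                                           "too_few_samples", length(ss$glucose$values)))
        NULL
      })
      if (!is.null(glu)) recs[[paste(sid, "glucose", sep = ".")]] <- glu
    }
    if (!is.null(hr_rec)) recs[[paste(sid, "hr", sep = ".")]] <- hr_rec
    if (!is.null(steps_rec)) recs[[paste(sid, "steps", sep = ".")]] <- steps_rec
  }
  ex <- exclude_recordings(recs, config)
  list(recordings = ex$retained, exclusions = rbind(log, ex$exclusions))
}
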