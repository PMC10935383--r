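MODALITIES <- c("glucose", "hr", "steps")

#' Raw sensor series
#'
#' A single subject x modality stream as exported by the device: wall-clock
#' timestamps (strictly increasing, no duplicates) and finite values
#' (glucose mmol/L, heart rate beats/min, steps counts/min).
#'
#' @param subject_id subject identifier (coerced to character).
#' @param modality one of `"glucose"`, `"hr"`, `"steps"`.
#' @param timestamps `POSIXct` vector, strictly increasing.
#' @param values numeric vector, finite, same length as `timestamps`.
#' @return An object of class `wm_raw_series`.
#' @export
raw_series <- function(subject_id, modality, timestamps, values) {
  modality <- match.arg(modality, MODALITIES)
  stopifnot(inherits(timestamps, "POSIXct"), is.numeric(values),
            length(timestamps) == length(values))
  if (length(timestamps) > 1L && any(diff(as.numeric(timestamps)) <= 0)) {
    stop("timestamps must be strictly increasing (duplicates are invalid) for subject ",
         subject_id, ", modality ", modality)
  }
  if (!all(is.finite(values))) {
    stop("non-finite values in raw series for subject ", subject_id,
         ", modality ", modality)
  }
  structure(list(subject_id = as.character(subject_id), modality = modality,
                 timestamps = timestamps, values = as.numeric(values)),
            class = "wm_raw_series")
}

#' @export
print.wm_raw_series <- function(x, ...) {
  cat(sprintf("<wm_raw_series> subject %s, %s, %d samples, %s .. %s\n",
              x$subject_id, x$modality, length(x$values),
              format(min(x$timestamps)), format(max(x$timestamps))))
  invisible(x)
}

#' Uniform-grid recording with an explicit missing mask
#'
#' A preprocessed subject x modality series on a uniform time grid. Samples
#' sit at `grid_start + index * grid_step_min * 60` seconds; `index` need not
#' be contiguous because non-wear days are excised from the recording rather
#' than marked missing. `values` is `NA` wherever `missing` is `TRUE`.
#'
#' @param subject_id subject identifier.
#' @param modality one of `"glucose"`, `"hr"`, `"steps"`.
#' @param grid_start `POSIXct` anchor of grid index 0.
#' @param grid_step_min grid step in minutes (15 for glucose, 1 for hr/steps).
#' @param index integer grid indices (0-based), strictly increasing.
#' @param values numeric values (`NA` where missing).
#' @param missing logical mask, `TRUE` = missing.
#' @return An object of class `wm_recording`.
#' @export
recording <- function(subject_id, modality, grid_start, grid_step_min,
                      index, values, missing) {
  modality <- match.arg(modality, MODALITIES)
  index <- as.integer(index)
  stopifnot(inherits(grid_start, "POSIXct"), grid_step_min > 0,
            length(index) == length(values), length(values) == length(missing),
            is.logical(missing))
  if (length(index) > 1L && any(diff(index) <= 0L)) {
    stop("grid indices must be strictly increasing")
  }
  structure(list(subject_id = as.character(subject_id), modality = modality,
                 grid_start = grid_start, grid_step_min = grid_step_min,
                 index = index, values = as.numeric(values),
                 missing = as.logical(missing)),
            class = "wm_recording")
}

#' Sample timestamps of a recording
#'
#' @param rec a `wm_recording`.
#' @return `POSIXct` vector of the sample times.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "wm_recording"))
  rec$grid_start + rec$index * (rec$grid_step_min * 60)
}

#' Fraction of samples missing in a recording
#'
#' @param rec a `wm_recording`.
#' @return A single number in `[0, 1]`.
#' @export
missing_fraction <- function(rec) {
  stopifnot(inherits(rec, "wm_recording"))
  if (length(rec$missing) == 0L) return(NA_real_)
  mean(rec$missing)
}

#' @export
print.wm_recording <- function(x, ...) {
  cat(sprintf("<wm_recording> subject %s, %s, %d samples @ %g min, %.1f%% missing\n",
              x$subject_id, x$modality, length(x$index), x$grid_step_min,
              100 * missing_fraction(x)))
  invisible(x)
}

# local clock-derived fields used by wear rules and dispersion groupings;
# integer arithmetic on UTC-anchored seconds (analysis ignores timezones)
rec_clock <- function(rec) {
  t_num <- as.numeric(rec$grid_start) + rec$index * (rec$grid_step_min * 60)
  sec_of_day <- t_num %% 86400
  daynum <- floor(t_num / 86400)
  list(t_num = t_num,
       hour = as.integer(sec_of_day %/% 3600),
       minute_of_day = as.integer(sec_of_day %/% 60),
       daynum = daynum,
       wday = as.integer((daynum + 4) %% 7)) # 0 = Sunday; epoch day was a Thursday
}
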