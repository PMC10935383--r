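TS_FMT <- "%Y-%m-%d %H:%M:%S"

parse_timestamps <- function(x, context = "timestamp") {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  # drop a trailing timezone designator: analysis runs on local clock time
  x <- sub("(Z|[+-][0-9]{2}:?[0-9]{2})$", "", x)
  out <- as.POSIXct(x, tz = "UTC", format = TS_FMT)
  short <- is.na(out) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  if (any(short)) out[short] <- as.POSIXct(x[short], tz = "UTC")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("malformed ", context, " at row ", bad, ": '", x[bad], "'")
  }
  out
}

format_timestamps <- function(x) format(x, TS_FMT, tz = "UTC")

#' Read raw sensor series from a long-format CSV
#'
#' Expects one row per sample with columns for subject, modality, timestamp
#' and value (names remappable through `schema`). Rows may be unordered;
#' duplicate timestamps within a subject x modality stream are rejected.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical column names
#'   (`subject_id`, `modality`, `timestamp`, `value`) to the file's columns.
#' @return A list of [raw_series()] objects, one per subject x modality.
#' @export
read_raw_series <- function(path,
                            schema = c(subject_id = "subject_id",
                                       modality = "modality",
                                       timestamp = "timestamp",
                                       value = "value")) {
  stopifnot(file.exists(path))
  need <- c("subject_id", "modality", "timestamp", "value")
  stopifnot(all(need %in% names(schema)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(schema[need]), names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df <- data.frame(subject_id = as.character(df[[schema[["subject_id"]]]]),
                   modality = as.character(df[[schema[["modality"]]]]),
                   timestamp = parse_timestamps(df[[schema[["timestamp"]]]]),
                   value = as.numeric(df[[schema[["value"]]]]),
                   stringsAsFactors = FALSE)
  series_from_long(df)
}

#' Build raw series objects from a long data frame
#'
#' @param df data frame with columns `subject_id`, `modality`, `timestamp`
#'   (`POSIXct`), `value`.
#' @return A list of [raw_series()] objects named `subject.modality`.
#' @export
series_from_long <- function(df) {
  stopifnot(all(c("subject_id", "modality", "timestamp", "value") %in% names(df)))
  key <- paste(df$subject_id, df$modality, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    sub <- df[i, , drop = FALSE]
    ord <- order(sub$timestamp)
    sub <- sub[ord, , drop = FALSE]
    if (anyDuplicated(sub$timestamp)) {
      stop("duplicate timestamp for subject ", sub$subject_id[1L],
           ", modality ", sub$modality[1L])
    }
    raw_series(sub$subject_id[1L], sub$modality[1L], sub$timestamp, sub$value)
  })
  out[order(names(out))]
}

#' Flatten raw series to a long data frame
#'
#' @param series list of [raw_series()] objects.
#' @return Long data frame with columns `subject_id`, `modality`,
#'   `timestamp`, `value`.
#' @export
series_to_long <- function(series) {
  do.call(rbind, lapply(series, function(s) {
    data.frame(subject_id = s$subject_id, modality = s$modality,
               timestamp = s$timestamps, value = s$values,
               stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Write raw series to a long-format CSV
#'
#' @param series list of [raw_series()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_series <- function(series, path) {
  df <- series_to_long(series)
  df$timestamp <- format_timestamps(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a subject descriptives table
#'
#' @param path CSV with columns `subject_id`, `gender`, `age_years`, `bmi`,
#'   `hba1c_mmol_mol`, `years_since_diagnosis`, `med_oral`, `med_insulin`,
#'   `med_other`.
#' @return A data frame with `subject_id` as character.
#' @export
read_descriptives <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gender", "age_years", "bmi", "hba1c_mmol_mol",
            "years_since_diagnosis", "med_oral", "med_insulin", "med_other")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing descriptives columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write / read preprocessed recordings
#'
#' Recordings are serialised to a long CSV (`subject_id`, `modality`,
#' `timestamp`, `grid_step_min`, `value`, `missing`); reading reconstructs
#' the [recording()] objects exactly.
#'
#' @param recordings list of [recording()] objects.
#' @param path CSV path.
#' @return `write_recordings()` returns `path` invisibly; `read_recordings()`
#'   a named list of recordings.
#' @export
write_recordings <- function(recordings, path) {
  df <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(subject_id = r$subject_id, modality = r$modality,
               timestamp = format_timestamps(recording_times(r)),
               grid_step_min = r$grid_step_min,
               value = ifelse(r$missing, NA_real_, r$values),
               missing = as.integer(r$missing), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- parse_timestamps(df$timestamp)
  key <- paste(df$subject_id, df$modality, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    sub <- df[i, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    step <- sub$grid_step_min[1L]
    start <- sub$timestamp[1L]
    idx <- as.integer(round(as.numeric(difftime(sub$timestamp, start, units = "mins")) / step))
    recording(sub$subject_id[1L], sub$modality[1L], start, step, idx,
              sub$value, sub$missing == 1L)
  })
  out[order(names(out))]
}

#' Write an exclusion log
#'
#' @param log data frame with columns `subject_id`, `modality`, `scope`,
#'   `rule`, `trigger_value`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

empty_exclusion_log <- function() {
  data.frame(subject_id = character(), modality = character(),
             scope = character(), rule = character(),
             trigger_value = numeric(), stringsAsFactors = FALSE)
}

exclusion_entry <- function(subject_id, modality, scope, rule, trigger_value) {
  data.frame(subject_id = subject_id, modality = modality, scope = scope,
             rule = rule, trigger_value = trigger_value,
             stringsAsFactors = FALSE)
}
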