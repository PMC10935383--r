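#' Analysis configuration
#'
#' Bundles every threshold used by the preprocessing rules and the two-step
#' mechanism analysis. Defaults follow common practice for flash CGM and
#' wrist-tracker studies: a 15-min glucose grid with an 18-min interpolation
#' tolerance, heart rate required for 70% of the 24-h day, more than 1000
#' daytime steps for a wear day, a 2-h zero-step rule inside the 08:00-22:00
#' day window, exclusion of recordings losing more than half their samples,
#' and a 0.01 significance level throughout.
#'
#' @param alpha significance level for every statistical test (0 < alpha < 1).
#' @param grid_minutes CGM resampling grid step, minutes.
#' @param missing_threshold_minutes CGM rule: a grid point is missing when the
#'   nearest original sample on each side is further than this, minutes.
#' @param cgm_missing_rule `"both_neighbors"` marks a grid point missing only
#'   when *both* bracketing raw samples are more than
#'   `missing_threshold_minutes` away; `"long_interval"` marks every grid
#'   point lying strictly inside a raw inter-sample interval longer than
#'   `long_interval_minutes`.
#' @param long_interval_minutes interval length (minutes) above which all
#'   interior grid points are missing under the `"long_interval"` rule.
#' @param hr_wear_fraction fraction of the day heart rate must be observed
#'   for the day to count as worn.
#' @param min_daily_steps a wear day must record strictly more than this many
#'   steps inside the day window.
#' @param zero_step_run_minutes minimal length (minutes) of a zero-step run
#'   that is reclassified as missing when it touches the day window.
#' @param day_window two clock hours `c(start, end)` delimiting the daytime
#'   window used by the step rules.
#' @param max_recording_loss_fraction recordings losing strictly more than
#'   this fraction of samples are excluded.
#' @param frequency_cutoff_count gap-frequency truncation: the first gap size
#'   with a count less than or equal to this, and all larger sizes, are
#'   dropped before goodness-of-fit testing.
#' @param subgroup_loss_cuts increasing percentages cutting the data-loss axis
#'   into subgroups (default 0-10, 10-20, >20 %).
#' @param reduce_dof_for_params subtract the number of estimated parameters
#'   from the chi-square degrees of freedom (default `FALSE`: plain one-way
#'   test with `bins - 1` dof, which is conservative for fitted models).
#' @param bonferroni_across_groupings apply the Bonferroni factor across time
#'   groupings as well as within each grouping (default `FALSE`).
#' @param measurement_day_mode `"rolling"` counts 24-h windows from each
#'   subject's recording start; `"calendar"` uses local calendar days.
#' @param rng_seed optional integer seed recorded in the configuration.
#'
#' @return An object of class `wm_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$alpha
analysis_config <- function(alpha = 0.01,
                            grid_minutes = 15,
                            missing_threshold_minutes = 18,
                            cgm_missing_rule = c("both_neighbors", "long_interval"),
                            long_interval_minutes = 19,
                            hr_wear_fraction = 0.70,
                            min_daily_steps = 1000,
                            zero_step_run_minutes = 120,
                            day_window = c(8, 22),
                            max_recording_loss_fraction = 0.50,
                            frequency_cutoff_count = 5,
                            subgroup_loss_cuts = c(10, 20),
                            reduce_dof_for_params = FALSE,
                            bonferroni_across_groupings = FALSE,
                            measurement_day_mode = c("rolling", "calendar"),
                            rng_seed = NULL) {
  cgm_missing_rule <- match.arg(cgm_missing_rule)
  measurement_day_mode <- match.arg(measurement_day_mode)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    grid_minutes > 0, missing_threshold_minutes > 0, long_interval_minutes > 0,
    hr_wear_fraction > 0, hr_wear_fraction <= 1,
    min_daily_steps > 0, zero_step_run_minutes > 0,
    length(day_window) == 2L, day_window[1] >= 0, day_window[2] <= 24,
    day_window[1] < day_window[2],
    max_recording_loss_fraction > 0, max_recording_loss_fraction <= 1,
    frequency_cutoff_count >= 0,
    length(subgroup_loss_cuts) >= 1L, all(subgroup_loss_cuts > 0),
    !is.unsorted(subgroup_loss_cuts, strictly = TRUE)
  )
  structure(list(
    alpha = alpha,
    grid_minutes = grid_minutes,
    missing_threshold_minutes = missing_threshold_minutes,
    cgm_missing_rule = cgm_missing_rule,
    long_interval_minutes = long_interval_minutes,
    hr_wear_fraction = hr_wear_fraction,
    min_daily_steps = min_daily_steps,
    zero_step_run_minutes = zero_step_run_minutes,
    day_window = day_window,
    max_recording_loss_fraction = max_recording_loss_fraction,
    frequency_cutoff_count = frequency_cutoff_count,
    subgroup_loss_cuts = subgroup_loss_cuts,
    reduce_dof_for_params = reduce_dof_for_params,
    bonferroni_across_groupings = bonferroni_across_groupings,
    measurement_day_mode = measurement_day_mode,
    rng_seed = rng_seed
  ), class = "wm_config")
}

#' Read / write an analysis configuration
#'
#' The configuration is a flat YAML document; every key of
#' [analysis_config()] is a valid entry and omitted keys fall back to the
#' defaults.
#'
#' @param path file path of the YAML document.
#' @param config a `wm_config` object.
#' @return `read_config()` returns a `wm_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "wm_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.wm_config <- function(x, ...) {
  cat("<wm_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "NULL"
    cat(sprintf("  %-28s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
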