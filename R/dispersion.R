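# Step 2: missing-data dispersion over time groupings, Kruskal-Wallis +
# Dunn post hoc with Bonferroni correction, and the MAR decision.

GROUPINGS <- c("hour_of_day", "weekday", "business_vs_weekend", "measurement_day")

WDAY_LABELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Assign a time-group label to every sample of a recording
#'
#' Groupings follow the local clock: `hour_of_day` (24 one-hour groups),
#' `weekday` (Monday through Sunday), `business_vs_weekend`, and
#' `measurement_day` (day 1, day 2, ... from the start of the recording;
#' rolling 24-h windows by default, local calendar days when the
#' configuration says so).
#'
#' @param rec a [recording()].
#' @param grouping one of `"hour_of_day"`, `"weekday"`,
#'   `"business_vs_weekend"`, `"measurement_day"`.
#' @param config an [analysis_config()].
#' @param n_days level count for `measurement_day` (defaults to the
#'   recording's own span; supply the cohort maximum when building matrices).
#' @return A factor with one label per sample.
#' @export
assign_groups <- function(rec, grouping = GROUPINGS, config = analysis_config(),
                          n_days = NULL) {
  grouping <- match.arg(grouping)
  clk <- rec_clock(rec)
  codes_factor <- function(codes, levels) {
    structure(as.integer(codes), levels = levels, class = "factor")
  }
  switch(grouping,
    hour_of_day = codes_factor(clk$hour + 1L, sprintf("h%02d", 0:23)),
    weekday = {
      # wday: 0 = Sunday
      idx <- ifelse(clk$wday == 0L, 7L, clk$wday)
      codes_factor(idx, WDAY_LABELS)
    },
    business_vs_weekend = {
      wk <- clk$wday == 0L | clk$wday == 6L
      codes_factor(wk + 1L, c("business", "weekend"))
    },
    measurement_day = {
      day <- if (config$measurement_day_mode == "rolling") {
        1L + as.integer(floor((clk$t_num - clk$t_num[1L]) / 86400))
      } else {
        as.integer(clk$daynum - clk$daynum[1L]) + 1L
      }
      nd <- max(n_days %||% max(day), max(day))
      codes_factor(day, sprintf("day%02d", seq_len(nd)))
    }
  )
}

#' Percentage of missing samples per time group for one recording
#'
#' @param rec a [recording()].
#' @param labels factor from [assign_groups()], aligned to the samples.
#' @return Named numeric vector (one entry per factor level, percent in
#'   `[0, 100]`); groups with no samples are `NA` (undefined, never zero).
#' @export
percent_missing_by_group <- function(rec, labels) {
  stopifnot(inherits(rec, "wm_recording"), length(labels) == length(rec$missing))
  k <- nlevels(labels)
  code <- as.integer(labels)
  cnt <- tabulate(code, nbins = k)
  mis <- tabulate(code[rec$missing], nbins = k)
  out <- 100 * mis / cnt    # 0/0 -> NaN for empty groups
  out[cnt == 0L] <- NA_real_
  names(out) <- levels(labels)
  out
}

#' Per-subject missing-data dispersion over a time grouping
#'
#' @param recordings list of [recording()] objects of one modality.
#' @param grouping see [assign_groups()].
#' @param config an [analysis_config()].
#' @return An object of class `wm_dispersion_table`: `grouping`, `matrix`
#'   (subjects x groups, percent missing, `NA` for empty groups), `median`,
#'   `iqr_low`, `iqr_high`, `n_subjects` per group.
#' @export
dispersion_table <- function(recordings, grouping = GROUPINGS,
                             config = analysis_config()) {
  grouping <- match.arg(grouping)
  stopifnot(length(recordings) >= 1L)
  n_days <- NULL
  if (grouping == "measurement_day") {
    n_days <- max(vapply(recordings, function(r) {
      1L + floor(diff(range(r$index)) * r$grid_step_min / 1440)
    }, numeric(1)))
  }
  rows <- lapply(recordings, function(r) {
    percent_missing_by_group(r, assign_groups(r, grouping, config, n_days = n_days))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(recordings, function(r) r$subject_id, character(1))
  structure(list(
    grouping = grouping,
    matrix = mat,
    median = apply(mat, 2, stats::median, na.rm = TRUE),
    iqr_low = apply(mat, 2, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE),
    iqr_high = apply(mat, 2, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE),
    n_subjects = apply(mat, 2, function(x) sum(!is.na(x)))
  ), class = "wm_dispersion_table")
}

#' @export
print.wm_dispersion_table <- function(x, ...) {
  cat(sprintf("<wm_dispersion_table> %s: %d subjects x %d groups\n",
              x$grouping, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# pooled ranks, group sizes and the tie correction shared by KW and Dunn
rank_summary <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep.int(seq_along(groups), lengths(groups))
  keep <- !is.na(x)
  x <- x[keep]; g <- g[keep]
  n_i <- tabulate(g, nbins = length(groups))
  r <- rank(x)
  ties <- table(x)
  list(N = length(x), n_i = n_i,
       rbar = vapply(seq_along(groups), function(i) {
         if (n_i[i] == 0L) NA_real_ else mean(r[g == i])
       }, numeric(1)),
       tie_sum = sum(ties^3 - ties))
}

as_group_list <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(ncol(x)), function(j) x[, j])
  } else if (inherits(x, "wm_dispersion_table")) {
    as_group_list(x$matrix)
  } else if (is.list(x)) x
  else stop("expected a matrix, list of vectors, or dispersion table")
}

group_names <- function(x) {
  if (is.matrix(x)) colnames(x)
  else if (inherits(x, "wm_dispersion_table")) colnames(x$matrix)
  else names(x)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based omnibus test for a location difference of the per-subject
#' percent-missing values among time groups, with tie correction; the
#' statistic is referred to a chi-square distribution with `groups - 1`
#' degrees of freedom. `NA` entries (subjects without samples in a group)
#' are dropped.
#'
#' @param x subjects x groups matrix, `wm_dispersion_table`, or list of
#'   group vectors.
#' @return List with `statistic` (H), `p`, `dof`.
#' @export
kruskal_wallis <- function(x) {
  groups <- as_group_list(x)
  rs <- rank_summary(groups)
  nonempty <- rs$n_i > 0L
  k <- sum(nonempty)
  if (k < 2L) stop("need at least 2 nonempty groups")
  N <- rs$N
  H_raw <- 12 / (N * (N + 1)) *
    sum(rs$n_i[nonempty] * rs$rbar[nonempty]^2) - 3 * (N + 1)
  corr <- 1 - rs$tie_sum / (N^3 - N)
  H <- if (corr <= 0) 0 else H_raw / corr
  H <- max(H, 0)
  list(statistic = H, p = stats::pchisq(H, k - 1L, lower.tail = FALSE),
       dof = k - 1L)
}

#' Dunn post hoc analysis with Bonferroni correction
#'
#' Pairwise rank-based follow-up to the Kruskal-Wallis test: z statistics on
#' the pooled-rank means with tie correction, two-sided p-values multiplied
#' by the number of pairwise comparisons (Bonferroni) and clipped at 1.
#'
#' @param x subjects x groups matrix, `wm_dispersion_table`, or list of
#'   group vectors.
#' @param config an [analysis_config()].
#' @return An object of class `wm_dispersion_test`: `kw_statistic`, `kw_p`,
#'   `z` and `p_adj` (symmetric group x group matrices, unit diagonal),
#'   `significant_pairs` (data frame of pairs with `p_adj < alpha`),
#'   `grouping` (filled by [analyze_dispersion()]).
#' @export
dunn_posthoc <- function(x, config = analysis_config()) {
  groups <- as_group_list(x)
  gnames <- group_names(x) %||% paste0("g", seq_along(groups))
  kw <- kruskal_wallis(x)
  rs <- rank_summary(groups)
  k <- length(groups)
  N <- rs$N
  var_base <- N * (N + 1) / 12 - rs$tie_sum / (12 * (N - 1))
  z <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  p_adj <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  diag(z) <- 0
  diag(p_adj) <- 1
  nonempty <- which(rs$n_i > 0L)
  m <- choose(length(nonempty), 2)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      if (rs$n_i[a] == 0L || rs$n_i[b] == 0L) next
      se2 <- var_base * (1 / rs$n_i[a] + 1 / rs$n_i[b])
      zz <- if (se2 <= 0) 0 else (rs$rbar[a] - rs$rbar[b]) / sqrt(se2)
      pp <- min(1, 2 * stats::pnorm(-abs(zz)) * m)
      z[a, b] <- z[b, a] <- zz
      p_adj[a, b] <- p_adj[b, a] <- pp
    }
  }
  ut <- upper.tri(p_adj)
  sig <- which(ut & !is.na(p_adj) & p_adj < config$alpha, arr.ind = TRUE)
  structure(list(
    kw_statistic = kw$statistic, kw_p = kw$p,
    z = z, p_adj = p_adj, n_comparisons = m,
    significant_pairs = data.frame(
      group_a = gnames[sig[, 1]], group_b = gnames[sig[, 2]],
      z = z[sig], p_adj = p_adj[sig], stringsAsFactors = FALSE),
    grouping = NA_character_
  ), class = "wm_dispersion_test")
}

#' @export
print.wm_dispersion_test <- function(x, ...) {
  cat(sprintf("<wm_dispersion_test> %s: KW H = %.3f (p = %.4g), %d significant pair(s)\n",
              x$grouping, x$kw_statistic, x$kw_p, nrow(x$significant_pairs)))
  invisible(x)
}

#' Dispersion table and tests for one modality and grouping
#'
#' @param recordings list of [recording()] objects of one modality.
#' @param grouping see [assign_groups()].
#' @param config an [analysis_config()].
#' @return List with `table` (`wm_dispersion_table`) and `test`
#'   (`wm_dispersion_test`).
#' @export
analyze_dispersion <- function(recordings, grouping = GROUPINGS,
                               config = analysis_config()) {
  grouping <- match.arg(grouping)
  tab <- dispersion_table(recordings, grouping, config)
  test <- dunn_posthoc(tab, config)
  test$grouping <- grouping
  list(table = tab, test = test)
}

#' Step-2 decision: is missingness dispersed unevenly over time?
#'
#' The missing data are labelled MAR when, for any time grouping, at least
#' one Dunn pair remains significant after Bonferroni correction (adjusted
#' p below `alpha`, strict); otherwise MCAR. The post hoc result governs: a
#' significant omnibus test without a surviving pair stays MCAR.
#'
#' @param tests list of `wm_dispersion_test` objects (one or more groupings).
#' @param config an [analysis_config()].
#' @return `"MAR"` or `"MCAR"`.
#' @export
classify_step2 <- function(tests, config = analysis_config()) {
  if (inherits(tests, "wm_dispersion_test")) tests <- list(tests)
  stopifnot(length(tests) >= 1L)
  extra <- if (config$bonferroni_across_groupings) length(tests) else 1L
  any_sig <- any(vapply(tests, function(t) {
    p <- t$p_adj[upper.tri(t$p_adj)]
    any(!is.na(p) & pmin(1, p * extra) < config$alpha)
  }, logical(1)))
  if (any_sig) "MAR" else "MCAR"
}
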