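# Machine-readable analysis reports: verdict/fit JSON plus per-figure CSVs.

#' Write an analysis report
#'
#' Emits `report.json` (verdicts, fitted parameters, test p-values,
#' correlations) and one CSV per table: gap frequencies
#' (`gap_frequency_<modality>.csv`), dispersion summaries
#' (`dispersion_<modality>_<grouping>.csv`) and post hoc pairs
#' (`posthoc_<modality>_<grouping>.csv`). Values round-trip through
#' [read_report()] bit-exactly for integers and to at least 12 significant
#' digits for reals.
#'
#' @param analysis a `wm_analysis` from [analyze_cohort()].
#' @param dir output directory (created if needed).
#' @param exclusions optional exclusion log to include as `exclusions.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir, exclusions = NULL) {
  stopifnot(inherits(analysis, "wm_analysis"))
  if (!length(analysis$per_modality)) stop("empty analysis: nothing to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modalities <- lapply(analysis$per_modality, function(pm) {
    fits <- NULL
    if (!is.null(pm$models)) {
      fits <- lapply(pm$models$fits, function(f) {
        list(family = f$family, params = as.list(f$params), loglik = f$loglik,
             chi2_stat = f$chi2_stat, chi2_p = f$chi2_p, sse = f$sse,
             dof = f$dof, converged = f$converged, degenerate = f$degenerate)
      })
    }
    list(mechanism = pm$verdict$final, step1 = pm$step1, step2 = pm$step2,
         n_recordings = pm$n_recordings,
         total_gaps = pm$gap_frequency$total_gaps,
         cutoff_size = pm$gap_frequency$cutoff_size,
         best_family_by_sse = pm$verdict$evidence$best_family_by_sse,
         planck = if (is.null(pm$planck)) NULL else list(
           lambda = unname(pm$planck$params[["lambda"]]),
           loglik = pm$planck$loglik, chi2_stat = pm$planck$chi2_stat,
           chi2_p = pm$planck$chi2_p, sse = pm$planck$sse, dof = pm$planck$dof),
         fits = fits)
  })
  report <- list(modalities = modalities,
                 correlations = analysis$correlations,
                 alpha = analysis$config$alpha)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  for (m in names(analysis$per_modality)) {
    pm <- analysis$per_modality[[m]]
    fq <- pm$gap_frequency
    utils::write.csv(data.frame(size = fq$sizes, count = fq$counts,
                                retained = as.integer(fq$retained)),
                     file.path(dir, paste0("gap_frequency_", m, ".csv")),
                     row.names = FALSE)
    for (g in names(pm$dispersion)) {
      tab <- pm$dispersion[[g]]$table
      utils::write.csv(data.frame(group = colnames(tab$matrix),
                                  median_pct = unname(tab$median),
                                  iqr_low = unname(tab$iqr_low),
                                  iqr_high = unname(tab$iqr_high),
                                  n_subjects = unname(tab$n_subjects)),
                       file.path(dir, paste0("dispersion_", m, "_", g, ".csv")),
                       row.names = FALSE)
      test <- pm$dispersion[[g]]$test
      pairs <- which(upper.tri(test$p_adj) & !is.na(test$p_adj), arr.ind = TRUE)
      utils::write.csv(data.frame(
        group_a = rownames(test$p_adj)[pairs[, 1]],
        group_b = colnames(test$p_adj)[pairs[, 2]],
        z = test$z[pairs], p_adj = test$p_adj[pairs]),
        file.path(dir, paste0("posthoc_", m, "_", g, ".csv")),
        row.names = FALSE)
    }
  }
  if (!is.null(exclusions)) {
    utils::write.csv(exclusions, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read back an analysis report directory
#'
#' @param dir directory written by [write_report()].
#' @return List with `report` (parsed JSON) and `tables` (named list of the
#'   CSV data frames).
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  stopifnot(file.exists(path))
  csvs <- setdiff(list.files(dir, pattern = "\\.csv$"), character())
  tables <- lapply(csvs, function(f) utils::read.csv(file.path(dir, f)))
  names(tables) <- sub("\\.csv$", "", csvs)
  list(report = jsonlite::read_json(path, simplifyVector = TRUE),
       tables = tables)
}

#' Bar chart of a missing-data dispersion table
#'
#' Median percent missing per time group with interquartile-range error bars.
#'
#' @param table a `wm_dispersion_table`.
#' @return A ggplot object.
#' @export
plot_dispersion <- function(table) {
  stopifnot(inherits(table, "wm_dispersion_table"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dispersion requires ggplot2")
  }
  df <- data.frame(group = factor(colnames(table$matrix),
                                  levels = colnames(table$matrix)),
                   median = unname(table$median),
                   lo = unname(table$iqr_low), hi = unname(table$iqr_high))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3, colour = "red") +
    ggplot2::labs(x = table$grouping, y = "missing data (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Heatmap of Dunn post hoc adjusted p-values
#'
#' @param test a `wm_dispersion_test`.
#' @return A ggplot object.
#' @export
plot_posthoc_heatmap <- function(test) {
  stopifnot(inherits(test, "wm_dispersion_test"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_posthoc_heatmap requires ggplot2")
  }
  p <- test$p_adj
  df <- expand.grid(a = factor(rownames(p), levels = rownames(p)),
                    b = factor(colnames(p), levels = colnames(p)))
  df$p <- as.vector(p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkred", high = "white",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "adj. p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
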