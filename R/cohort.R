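# Cohort-level synthesis: the two-step mechanism verdict, cross-modality
# loss correlation, and subgroup analyses.

#' Combine the two steps into a mechanism verdict
#'
#' MNAR dominates: a gap-size distribution that is not an exponential
#' decline settles the verdict regardless of time dispersion. Otherwise the
#' dispersion step decides between MAR and MCAR. An insufficient Step 1
#' yields an indeterminate verdict.
#'
#' @param step1 `"MNAR"`, `"M(C)AR"` or `"insufficient"` ([classify_step1()]).
#' @param step2 `"MAR"` or `"MCAR"` ([classify_step2()]).
#' @param modality optional modality label.
#' @param evidence optional list stored alongside the verdict (Planck p,
#'   best family by SSE, significant dispersion pairs).
#' @return An object of class `wm_verdict` with `final` in
#'   `{"MCAR", "MAR", "MNAR", "indeterminate"}`.
#' @export
classify_mechanism <- function(step1, step2, modality = NA_character_,
                               evidence = list()) {
  step1 <- match.arg(step1, c("MNAR", "M(C)AR", "insufficient"))
  step2 <- match.arg(step2, c("MAR", "MCAR"))
  final <- if (step1 == "insufficient") "indeterminate"
  else if (step1 == "MNAR") "MNAR"
  else step2
  structure(list(modality = modality, step1 = step1, step2 = step2,
                 final = final, evidence = evidence),
            class = "wm_verdict")
}

#' @export
print.wm_verdict <- function(x, ...) {
  cat(sprintf("<wm_verdict> %s: step1 = %s, step2 = %s -> %s\n",
              x$modality, x$step1, x$step2, x$final))
  invisible(x)
}

#' Per-subject data loss by modality
#'
#' @param recordings named list of [recording()] objects.
#' @return Data frame `subject_id`, `modality`, `loss_pct`.
#' @export
loss_by_subject <- function(recordings) {
  do.call(rbind, lapply(recordings, function(r) {
    data.frame(subject_id = r$subject_id, modality = r$modality,
               loss_pct = 100 * missing_fraction(r), stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Spearman correlation of data loss between modalities
#'
#' For every modality pair, the rank correlation of per-subject percent data
#' loss over subjects present in both modalities (two-sided p); pairs with
#' fewer than 3 common subjects are flagged undefined.
#'
#' @param loss data frame from [loss_by_subject()].
#' @return Data frame with `modality_a`, `modality_b`, `rho`, `p`, `n`.
#' @export
correlate_modal_loss <- function(loss) {
  stopifnot(all(c("subject_id", "modality", "loss_pct") %in% names(loss)))
  mods <- sort(unique(loss$modality))
  out <- list()
  for (a_i in seq_along(mods)) for (b_i in seq_along(mods)) {
    if (b_i <= a_i) next
    a <- mods[a_i]; b <- mods[b_i]
    la <- loss[loss$modality == a, ]
    lb <- loss[loss$modality == b, ]
    common <- intersect(la$subject_id, lb$subject_id)
    if (length(common) < 3L) {
      out[[paste(a, b)]] <- data.frame(modality_a = a, modality_b = b,
                                       rho = NA_real_, p = NA_real_,
                                       n = length(common))
      next
    }
    xa <- la$loss_pct[match(common, la$subject_id)]
    xb <- lb$loss_pct[match(common, lb$subject_id)]
    ct <- suppressWarnings(stats::cor.test(xa, xb, method = "spearman",
                                           exact = FALSE))
    out[[paste(a, b)]] <- data.frame(modality_a = a, modality_b = b,
                                     rho = unname(ct$estimate), p = ct$p.value,
                                     n = length(common))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

SUBGROUP_AXES <- c("loss_amount", "gender", "age", "bmi", "hba1c",
                   "years_diagnosis", "med_oral", "med_insulin", "med_other")

#' Split subjects into subgroups along a covariate axis
#'
#' Bin conventions (the interval edges are left-closed unless noted): data
#' loss 0-10 / 10-20 / >20 percent; age <50, 50-60, 60-70 (70 included),
#' >70; BMI <30 vs >=30; HbA1c <=53 vs >53 mmol/mol; years since diagnosis
#' <10, 10-20, >=20 (labelled >20); medication flags yes/no. Subjects with a
#' missing covariate get `NA` and are excluded from tests.
#'
#' @param descriptives descriptives data frame (see [read_descriptives()]).
#' @param axis one of `r paste(SUBGROUP_AXES, collapse = ", ")`.
#' @param loss optional named vector of percent data loss by `subject_id`
#'   (required for `axis = "loss_amount"`).
#' @param config an [analysis_config()].
#' @return Factor of bin labels aligned to `descriptives$subject_id`.
#' @export
split_subgroups <- function(descriptives, axis = SUBGROUP_AXES, loss = NULL,
                            config = analysis_config()) {
  axis <- match.arg(axis)
  n <- nrow(descriptives)
  bin <- switch(axis,
    loss_amount = {
      stopifnot(!is.null(loss))
      x <- unname(loss[descriptives$subject_id])
      cuts <- config$subgroup_loss_cuts
      labs <- c(paste0("<", cuts[1], "%"),
                paste0(cuts[1], "-", cuts[2], "%"),
                paste0(">", cuts[2], "%"))
      f <- ifelse(is.na(x), NA,
                  ifelse(x < cuts[1], labs[1],
                         ifelse(x < cuts[2], labs[2], labs[3])))
      factor(f, levels = labs)
    },
    gender = factor(descriptives$gender, levels = c("male", "female")),
    age = {
      x <- descriptives$age_years
      f <- ifelse(is.na(x), NA,
                  ifelse(x < 50, "<50",
                         ifelse(x < 60, "50-60",
                                ifelse(x <= 70, "60-70", ">70"))))
      factor(f, levels = c("<50", "50-60", "60-70", ">70"))
    },
    bmi = {
      x <- descriptives$bmi
      factor(ifelse(is.na(x), NA, ifelse(x < 30, "<30", ">=30")),
             levels = c("<30", ">=30"))
    },
    hba1c = {
      x <- descriptives$hba1c_mmol_mol
      factor(ifelse(is.na(x), NA, ifelse(x <= 53, "<=53", ">53")),
             levels = c("<=53", ">53"))
    },
    years_diagnosis = {
      x <- descriptives$years_since_diagnosis
      f <- ifelse(is.na(x), NA,
                  ifelse(x < 10, "<10", ifelse(x < 20, "10-20", ">20")))
      factor(f, levels = c("<10", "10-20", ">20"))
    },
    med_oral = ,
    med_insulin = ,
    med_other = {
      x <- descriptives[[switch(axis, med_oral = "med_oral",
                                med_insulin = "med_insulin",
                                med_other = "med_other")]]
      factor(ifelse(is.na(x), NA, ifelse(x == 1, "yes", "no")),
             levels = c("no", "yes"))
    })
  names(bin) <- descriptives$subject_id
  bin
}

#' Test whether a variable differs between subject subgroups
#'
#' Continuous variables are compared with the Kruskal-Wallis test and Dunn
#' post hoc analysis; dichotomous variables with a contingency chi-square
#' test (no continuity correction). `bonferroni_m` multiplies the omnibus p
#' for family-wise correction over the covariates screened.
#'
#' @param bins factor of subgroup labels per subject.
#' @param values numeric (continuous) or two-level (dichotomous) vector
#'   aligned to `bins`.
#' @param config an [analysis_config()].
#' @param bonferroni_m family size for the omnibus Bonferroni correction.
#' @return List with `type`, `statistic`, `p`, `p_bonferroni`, `posthoc`
#'   (`wm_dispersion_test` for continuous variables), `unreliable` (expected
#'   cell below 1 in the contingency table).
#' @export
compare_subgroups <- function(bins, values, config = analysis_config(),
                              bonferroni_m = 1L) {
  keep <- !is.na(bins) & !is.na(values)
  bins <- droplevels(factor(bins[keep]))
  values <- values[keep]
  if (nlevels(bins) < 2L) stop("need at least 2 nonempty subgroups")
  dichotomous <- !is.numeric(values) || length(unique(values)) <= 2L
  if (dichotomous) {
    tab <- table(bins, values)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(type = "dichotomous", statistic = unname(ct$statistic),
         p = ct$p.value, p_bonferroni = min(1, ct$p.value * bonferroni_m),
         posthoc = NULL, unreliable = any(ct$expected < 1))
  } else {
    groups <- split(values, bins)
    kw <- kruskal_wallis(groups)
    ph <- dunn_posthoc(groups, config)
    list(type = "continuous", statistic = kw$statistic, p = kw$p,
         p_bonferroni = min(1, kw$p * bonferroni_m), posthoc = ph,
         unreliable = FALSE)
  }
}

#' RMSE between two normalised dispersion profiles
#'
#' Each vector of group medians is normalised to sum to one; the result is
#' the root of the mean squared difference over groups. A metric on
#' normalised profiles: nonnegative, symmetric, zero iff equal.
#'
#' @param a,b numeric vectors of group medians (same grouping and length).
#' @return A single nonnegative number; `NA` with a warning when a vector
#'   sums to zero (undefined).
#' @export
rmse_dispersion <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  if (sum(a, na.rm = TRUE) == 0 || sum(b, na.rm = TRUE) == 0) {
    warning("dispersion vector sums to zero; RMSE undefined")
    return(NA_real_)
  }
  an <- a / sum(a, na.rm = TRUE)
  bn <- b / sum(b, na.rm = TRUE)
  sqrt(mean((an - bn)^2, na.rm = TRUE))
}

#' Compare a subgroup's gap frequency with the pooled fit
#'
#' One-way chi-square of the subgroup's retained gap counts against the
#' expected proportions of the cohort-level fitted pmf, renormalised over
#' the subgroup's retained sizes.
#'
#' @param sub_freq the subgroup's [pool_gap_frequency()] table.
#' @param pooled_fit the cohort-level `wm_pmf_fit`.
#' @param config an [analysis_config()].
#' @return As [chi_square_gof()].
#' @export
compare_gap_frequency <- function(sub_freq, pooled_fit, config = analysis_config()) {
  chi_square_gof(sub_freq, pooled_fit, config)
}

#' Run the full two-step mechanism analysis on preprocessed recordings
#'
#' For every modality present: pool the gap-size frequency, fit the Planck
#' pmf (plus ranking families), run the chi-square Step-1 decision, compute
#' missing-data dispersion over the requested time groupings with
#' Kruskal-Wallis + Dunn (Step 2), and combine both into the mechanism
#' verdict. Cross-modality Spearman correlations of per-subject loss and,
#' when descriptives are supplied, subgroup screening by amount of data loss
#' are added.
#'
#' @param recordings named list of [recording()] objects (or the list
#'   returned by [preprocess_cohort()]).
#' @param config an [analysis_config()].
#' @param descriptives optional descriptives data frame.
#' @param groupings time groupings for Step 2.
#' @param families candidate families for the SSE ranking (the Step-1
#'   decision always uses Planck).
#' @return An object of class `wm_analysis`.
#' @export
analyze_cohort <- function(recordings, config = analysis_config(),
                           descriptives = NULL, groupings = GROUPINGS,
                           families = c("planck", "geometric", "zipf", "zipfian")) {
  if (is.list(recordings) && !is.null(recordings$recordings)) {
    recordings <- recordings$recordings
  }
  if (!length(recordings)) stop("no recordings to analyze")
  groupings <- match.arg(groupings, GROUPINGS, several.ok = TRUE)
  mods <- unique(vapply(recordings, function(r) r$modality, character(1)))
  per_modality <- list()
  for (m in mods) {
    recs <- recordings[vapply(recordings, function(r) r$modality == m, logical(1))]
    freq <- pool_gap_frequency(recs, config)
    if (freq$total_gaps == 0L || freq$insufficient) {
      step1 <- "insufficient"
      planck <- NULL; models <- NULL
    } else {
      models <- fit_gap_models(freq, families, config)
      planck <- models$fits$planck %||% fit_planck(freq, config)
      step1 <- classify_step1(freq, planck, config)
    }
    disp <- lapply(groupings, function(g) analyze_dispersion(recs, g, config))
    names(disp) <- groupings
    tests <- lapply(disp, `[[`, "test")
    step2 <- classify_step2(tests, config)
    verdict <- classify_mechanism(step1, step2, modality = m, evidence = list(
      planck_p = if (is.null(planck)) NA_real_ else planck$chi2_p,
      best_family_by_sse = if (is.null(models)) NA_character_ else models$best_by_sse,
      n_significant_pairs = sum(vapply(tests, function(t) nrow(t$significant_pairs),
                                       numeric(1)))))
    per_modality[[m]] <- list(modality = m, n_recordings = length(recs),
                              gap_frequency = freq, planck = planck,
                              models = models, dispersion = disp,
                              step1 = step1, step2 = step2, verdict = verdict)
  }
  loss <- loss_by_subject(recordings)
  correlations <- if (length(mods) >= 2L) correlate_modal_loss(loss) else NULL
  subgroups <- NULL
  if (!is.null(descriptives)) {
    subgroups <- lapply(stats::setNames(mods, mods), function(m) {
      lm <- loss[loss$modality == m, ]
      lv <- stats::setNames(lm$loss_pct, lm$subject_id)
      bins <- split_subgroups(descriptives, "loss_amount", loss = lv, config)
      covs <- c("age_years", "bmi", "hba1c_mmol_mol", "years_since_diagnosis")
      dich <- c("gender", "med_oral", "med_insulin", "med_other")
      m_total <- length(covs) + length(dich)
      res <- lapply(c(covs, dich), function(v) {
        r <- try(compare_subgroups(bins, descriptives[[v]], config,
                                   bonferroni_m = m_total), silent = TRUE)
        if (inherits(r, "try-error")) NULL else
          data.frame(covariate = v, type = r$type, statistic = r$statistic,
                     p = r$p, p_bonferroni = r$p_bonferroni,
                     unreliable = r$unreliable, stringsAsFactors = FALSE)
      })
      list(bins = bins, tests = do.call(rbind, res))
    })
  }
  structure(list(per_modality = per_modality, loss = loss,
                 correlations = correlations, subgroups = subgroups,
                 config = config),
            class = "wm_analysis")
}

#' @export
print.wm_analysis <- function(x, ...) {
  cat("<wm_analysis>\n")
  for (m in names(x$per_modality)) {
    pm <- x$per_modality[[m]]
    cat(sprintf("  %-8s %3d recordings, %6d gaps, step1 %-8s step2 %-5s -> %s\n",
                m, pm$n_recordings, pm$gap_frequency$total_gaps,
                pm$step1, pm$step2, pm$verdict$final))
  }
  invisible(x)
}
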