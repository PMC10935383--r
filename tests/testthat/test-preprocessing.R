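test_that("CGM resampling interpolates and applies the 18-min rule", {
  # raw every 15 min exactly: identity on values, nothing missing
  raw <- minutes_series("S1", "glucose", seq(0, 60, by = 15), c(5, 6, 7, 8, 9))
  rec <- resample_glucose(raw)
  expect_false(any(rec$missing))
  expect_equal(rec$values, c(5, 6, 7, 8, 9))
  expect_equal(rec$grid_step_min, 15)

  # raw at 0 and 60 min: only the 30-min grid point is 18+ min from both
  rec2 <- resample_glucose(minutes_series("S1", "glucose", c(0, 60), c(5, 9)))
  expect_equal(rec2$missing, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(rec2$values[3]))
  expect_equal(rec2$values[c(2, 4)], c(6, 8))   # still interpolated

  # raw at 0 and 30: midpoint observed with the interpolated value
  rec3 <- resample_glucose(minutes_series("S1", "glucose", c(0, 30), c(5, 9)))
  expect_equal(rec3$missing, c(FALSE, FALSE, FALSE))
  expect_equal(rec3$values[2], 7)

  # the long-interval rule marks every interior point of a long interval
  cfg <- analysis_config(cgm_missing_rule = "long_interval")
  rec4 <- resample_glucose(minutes_series("S1", "glucose", c(0, 60), c(5, 9)), cfg)
  expect_equal(rec4$missing, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  expect_error(resample_glucose(minutes_series("S1", "glucose", 0, 5)),
               "fewer than 2")
  expect_error(resample_glucose(minutes_series("S1", "hr", c(0, 15), c(60, 61))),
               "glucose")
})

test_that("zero heart-rate values (and absent minutes) are missing", {
  rec <- minutes_series("S1", "hr", 0:2, c(72, 0, 70)) |> define_hr_missing()
  expect_equal(rec$missing, c(FALSE, TRUE, FALSE))
  expect_true(is.na(rec$values[2]))

  rec2 <- minutes_series("S1", "hr", 0:3, c(70, 71, 72, 73)) |> define_hr_missing()
  expect_false(any(rec2$missing))

  # a minute absent from the export is filled as zero, hence missing
  rec3 <- minutes_series("S1", "hr", c(0, 2), c(70, 72)) |> define_hr_missing()
  expect_equal(rec3$missing, c(FALSE, TRUE, FALSE))

  expect_error(define_hr_missing(minutes_series("S1", "hr", 0:1, c(-5, 70))),
               "negative")
})

test_that("step-count missingness combines the hr-zero and 2-h-run rules", {
  # one isolated minute with steps = 0 and hr = 0 is missing
  n <- 60
  hr_vals <- rep(70, n); hr_vals[30] <- 0
  hr <- minutes_series("S1", "hr", 0:(n - 1), hr_vals,
                       start = "2019-03-07 10:00:00") |> define_hr_missing()
  st_vals <- rep(20, n); st_vals[30] <- 0
  st <- define_steps_missing(
    minutes_series("S1", "steps", 0:(n - 1), st_vals,
                   start = "2019-03-07 10:00:00"), hr)
  expect_equal(which(st$missing), 30L)

  # 3 h of zero steps spanning 09:00-12:00 with hr present: all 180 min missing
  n <- 6 * 60 # 08:00-14:00
  hr2 <- minutes_series("S1", "hr", 0:(n - 1), rep(70, n),
                        start = "2019-03-07 08:00:00") |> define_hr_missing()
  st_vals <- rep(15, n)
  zero_run <- 61:240   # 09:00 through 11:59
  st_vals[zero_run] <- 0
  st2 <- define_steps_missing(
    minutes_series("S1", "steps", 0:(n - 1), st_vals,
                   start = "2019-03-07 08:00:00"), hr2)
  expect_equal(which(st2$missing), zero_run)

  # a 90-min zero run stays observed (below the 2-h threshold)
  st_vals <- rep(15, n)
  st_vals[61:150] <- 0
  st3 <- define_steps_missing(
    minutes_series("S1", "steps", 0:(n - 1), st_vals,
                   start = "2019-03-07 08:00:00"), hr2)
  expect_false(any(st3$missing))

  # a long zero run entirely inside the night window stays observed
  n_night <- 5 * 60 # 00:00-05:00
  hr3 <- minutes_series("S1", "hr", 0:(n_night - 1), rep(60, n_night)) |>
    define_hr_missing()
  st4 <- define_steps_missing(
    minutes_series("S1", "steps", 0:(n_night - 1), rep(0, n_night)), hr3)
  expect_false(any(st4$missing))

  expect_error(define_steps_missing(
    minutes_series("S1", "steps", 0:9, rep(1, 10)), hr2), "grid")
})

test_that("wear-day filtering applies the 70% hr and 1000-step criteria", {
  day <- function(hr_obs_min, steps_total) {
    n <- 1440
    hr_vals <- rep(0, n); hr_vals[seq_len(hr_obs_min)] <- 70
    hr <- minutes_series("S1", "hr", 0:(n - 1), hr_vals) |> define_hr_missing()
    st_vals <- rep(0, n)
    # spread the steps over the day window so no 2-h zero run intrudes
    win <- which((0:(n - 1)) %/% 60 >= 8 & (0:(n - 1)) %/% 60 < 22)
    put <- win[seq(1, length(win), by = 60)]
    st_vals[put] <- steps_total / length(put)
    st <- define_steps_missing(minutes_series("S1", "steps", 0:(n - 1), st_vals), hr)
    filter_wear_days(hr, st)
  }
  # fully observed day with plenty of steps is retained
  keep <- day(1440, 5000)
  expect_equal(length(keep$hr$index), 1440L)
  expect_equal(nrow(keep$exclusions), 0L)

  # 1007 observed minutes is 69.9% < the 1008-min threshold: removed
  lost <- day(1007, 5000)
  expect_equal(length(lost$hr$index), 0L)
  expect_equal(lost$exclusions$rule, "hr_wear")

  # full heart rate but only 900 steps: removed under the step criterion
  lost2 <- day(1440, 900)
  expect_equal(length(lost2$hr$index), 0L)
  expect_equal(lost2$exclusions$rule, "min_steps")

  # boundary: 1008 observed minutes (exactly 70%) is retained
  expect_equal(nrow(day(1008, 5000)$exclusions), 0L)
})

test_that("day removal excises samples without touching retained masks", {
  n <- 2 * 1440
  hr_vals <- rep(70, n)
  hr_vals[1440 + seq_len(600)] <- 0     # second day fails the 70% rule
  hr_vals[10] <- 0                      # one missing minute on the good day
  hr <- minutes_series("S1", "hr", 0:(n - 1), hr_vals) |> define_hr_missing()
  f <- filter_wear_days(hr)
  expect_equal(length(f$hr$index), 1440L)
  expect_equal(which(f$hr$missing), 10L)
  expect_equal(f$exclusions$scope, "day")
})

test_that("recordings with more than half their samples missing are excluded", {
  make <- function(loss_frac, n = 1000) {
    mask_recording(seq_len(n) <= round(loss_frac * n))
  }
  res <- exclude_recordings(list(a = make(0.553), b = make(0.5), c = make(0)))
  expect_equal(names(res$retained), c("b", "c"))
  expect_equal(res$exclusions$rule, "recording_loss")
  expect_equal(res$exclusions$trigger_value, 55.3, tolerance = 1e-9)
})

test_that("preprocessing recovers injected missingness on simulated cohorts", {
  # heart rate: zero-coding makes recovery exact
  coh <- simulate_cohort(4, days = 3, modalities = "hr",
                         mechanisms = list(hr = mechanism_spec("mcar_iid", rate = 0.08)),
                         seed = 31)
  pp <- preprocess_cohort(coh)
  gt <- coh$ground_truth
  for (sid in unique(gt$subject_id)) {
    rec <- pp$recordings[[paste0(sid, ".hr")]]
    g <- gt[gt$subject_id == sid, ]
    idx <- match(as.numeric(recording_times(rec)), as.numeric(g$timestamp))
    expect_equal(as.integer(rec$missing), g$injected_missing[idx])
  }

  # glucose under the long-interval rule: exact on the nominal grid
  cohg <- simulate_cohort(4, days = 3, modalities = "glucose",
                          mechanisms = list(glucose = mechanism_spec("mcar_iid", rate = 0.10)),
                          seed = 32)
  cfg <- analysis_config(cgm_missing_rule = "long_interval")
  ppg <- preprocess_cohort(cohg, cfg)
  gtg <- cohg$ground_truth
  for (sid in unique(gtg$subject_id)) {
    rec <- ppg$recordings[[paste0(sid, ".glucose")]]
    g <- gtg[gtg$subject_id == sid, ]
    # align computed grid to the nominal grid by rounding to the 15-min step
    t_num <- as.numeric(recording_times(rec))
    k <- round((t_num - as.numeric(g$timestamp[1])) / 900)
    agree <- as.integer(rec$missing) == g$injected_missing[k + 1]
    expect_gte(mean(agree), 0.99)
  }

  # glucose under the default both-neighbors rule: conservative subset
  ppb <- preprocess_cohort(cohg)
  for (sid in unique(gtg$subject_id)) {
    rec <- ppb$recordings[[paste0(sid, ".glucose")]]
    g <- gtg[gtg$subject_id == sid, ]
    t_num <- as.numeric(recording_times(rec))
    k <- round((t_num - as.numeric(g$timestamp[1])) / 900)
    expect_true(all(g$injected_missing[k + 1][rec$missing] == 1L))
  }

  # determinism / idempotence: preprocessing twice gives identical masks
  pp2 <- preprocess_cohort(coh)
  expect_identical(lapply(pp$recordings, `[[`, "missing"),
                   lapply(pp2$recordings, `[[`, "missing"))
})
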