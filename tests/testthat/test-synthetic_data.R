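test_that("iid dropout injects at the requested rate with geometric runs", {
  expect_equal(inject_iid_dropout(100, 0), rep(FALSE, 100))
  expect_error(inject_iid_dropout(10, 1), "rate")
  expect_identical(inject_iid_dropout(4, 0.5, seed = 11),
                   inject_iid_dropout(4, 0.5, seed = 11))

  # consecutive-missing run lengths follow geometric(p = 1 - rate)
  mask <- inject_iid_dropout(1e5, 0.2, seed = 42)
  runs <- extract_gaps(mask)
  tab <- tabulate(runs, nbins = max(runs))
  keep <- 1:6
  p_exp <- 0.8 * 0.2^(keep - 1)
  p_exp <- c(p_exp, 1 - sum(p_exp))
  obs <- c(tab[keep], length(runs) - sum(tab[keep]))
  gof <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.001)
})

test_that("gap process unions gaps drawn from the requested family", {
  expect_equal(inject_gap_process(50, 0, list(name = "geometric", p = 0.5)),
               rep(FALSE, 50))
  mask <- inject_gap_process(20, 0, list(name = "deterministic", size = 3),
                             starts = 5)
  expect_equal(which(mask), 5:7)
  # overlap is merged: two overlapping deterministic gaps
  mask2 <- inject_gap_process(20, 0, list(name = "deterministic", size = 4),
                              starts = c(5, 7))
  expect_equal(which(mask2), 5:10)
  # gaps are clipped at the end of the grid
  mask3 <- inject_gap_process(6, 0, list(name = "deterministic", size = 10),
                              starts = 4)
  expect_equal(which(mask3), 4:6)
  expect_error(inject_gap_process(10, 0.1, list(name = "cauchy")), "unknown")
})

test_that("zipf gap sizes match the sampling pmf across seeds", {
  a <- 2
  K <- 15
  p_ref <- (1:K)^(-a) / pracma::zeta(a)
  p_ref <- c(p_ref, 1 - sum(p_ref))
  ok <- vapply(1:100, function(s) {
    x <- with_seed_local(s, rzipf(1e4, a))
    obs <- c(tabulate(pmin(x, K + 1), nbins = K + 1)[1:K],
             sum(x > K))
    suppressWarnings(chisq.test(obs, p = p_ref))$p.value > 0.01
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("buffer loss reproduces hand-traced FIFO event sequences", {
  t_h <- seq(0, 14, by = 0.25)                       # 14 h of 15-min samples
  miss <- inject_buffer_loss(t_h, 8, sync_times = 10)
  expect_equal(t_h[miss], t_h[t_h < 2])              # [0, 2 h) lost, rest kept
  # no syncs except the terminal one: first 6 h lost
  miss2 <- inject_buffer_loss(t_h, 8)
  expect_equal(t_h[miss2], t_h[t_h < 6])
  # hourly syncs: capacity never exceeded
  expect_false(any(inject_buffer_loss(t_h, 8, sync_times = 1:14)))
  expect_error(inject_buffer_loss(numeric(), 8), "empty")
})

test_that("buffer observation equals independent interval-union coverage", {
  set.seed(5)
  for (i in 1:20) {
    t_h <- sort(runif(200, 0, 14 * 24))
    syncs <- sort(runif(sample(1:6, 1), 0, 14 * 24))
    cap <- runif(1, 2, 48)
    miss <- inject_buffer_loss(t_h, cap, syncs)
    expect_equal(!miss, buffer_coverage_oracle(t_h, cap, syncs))
  }
})

test_that("stop-when-full buffer records until capacity and resumes at syncs", {
  t_h <- seq(0, 14 * 24, by = 1)
  cap <- 5.5 * 24
  sync <- 6 * 24 + 14                     # day-7 visit at 14:00
  miss <- inject_buffer_loss(t_h, cap, sync, policy = "stop_when_full")
  lost <- t_h[miss]
  expect_equal(min(lost), cap + 1)        # first lost sample after capacity
  # observed again right after the sync, until the buffer refills
  expect_true(all(t_h[t_h > sync & t_h <= sync + cap] %in% t_h[!miss]))
  expect_true(all(lost %in% c(t_h[t_h > cap & t_h <= sync],
                              t_h[t_h > sync + cap])))
})

test_that("scan times form a waking-hours Poisson stream", {
  sl <- sleep_model(onset_hour = 23, onset_sd = 0, duration_hours = 8,
                    duration_sd = 0)
  expect_length(simulate_scan_times(sl, 0, 14, seed = 1), 0L)
  # awake 16 h/day at 0.5 scans/h over 14 days: expect 112 +- 3 sqrt(112)
  n <- length(simulate_scan_times(sl, 0.5, 14, seed = 7))
  expect_true(abs(n - 112) <= 3 * sqrt(112))
  # no scan ever falls inside a sleep interval
  for (s in 1:10) {
    sched <- simulate_sleep_schedule(sleep_model(), 7, seed = s)
    scans <- simulate_scan_times(sched, 2, 7, seed = s + 100)
    inside <- vapply(scans, function(t) {
      any(sched$onset_h <= t & t < sched$wake_h)
    }, logical(1))
    expect_false(any(inside))
  }
})

test_that("hour-profile dropout hits only the configured hours", {
  hours <- rep(0:23, each = 60)
  prof <- rep(0, 24); prof[24] <- 0.5    # only 23:00-00:00
  mask <- inject_time_dependent_dropout(hours, prof, seed = 3)
  expect_true(all(hours[mask] == 23))
  expect_gt(sum(mask), 0)
  expect_error(inject_time_dependent_dropout(hours, rep(0.1, 23)), "24")
  # a flat profile reduces to iid dropout in distribution
  flat <- inject_time_dependent_dropout(rep(0:23, each = 600), rep(0.2, 24),
                                        seed = 9)
  expect_true(abs(mean(flat) - 0.2) < 0.02)
})

test_that("simulate_cohort is deterministic and honours mechanism specs", {
  a <- simulate_cohort(2, days = 1, seed = 99)
  b <- simulate_cohort(2, days = 1, seed = 99)
  expect_identical(a$raw, b$raw)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$descriptives, b$descriptives)

  # no mechanism: zero injected missingness
  clean <- simulate_cohort(1, days = 1, seed = 5)
  expect_equal(sum(clean$ground_truth$injected_missing), 0L)

  # unsupported mechanism kinds are refused at construction
  expect_error(mechanism_spec("mcar_iid", rate = 1.2), "rate")
  expect_error(mechanism_spec("mar_time", hour_profile = rep(0.1, 10)), "24")
  expect_error(mechanism_spec("nonsense"))
})

test_that("pooled realized missing fraction matches the configured iid rate", {
  coh <- simulate_cohort(50, days = 14, modalities = "glucose",
                         mechanisms = list(glucose = mechanism_spec("mcar_iid", rate = 0.10)),
                         seed = 21)
  gt <- coh$ground_truth
  frac <- mean(gt$injected_missing[gt$modality == "glucose"])
  expect_true(abs(frac - 0.10) <= 0.01)
})

test_that("descriptive covariates stay inside plausible cohort ranges", {
  d <- simulate_cohort(200, days = 1, modalities = "hr", seed = 3)$descriptives
  expect_true(all(d$age_years >= 35 & d$age_years <= 88))
  expect_true(all(d$bmi >= 19 & d$bmi <= 48))
  expect_true(all(d$hba1c_mmol_mol >= 38 & d$hba1c_mmol_mol <= 95))
  expect_true(all(d$years_since_diagnosis >= 0 & d$years_since_diagnosis <= 40))
  expect_true(all(d$gender %in% c("male", "female")))
  expect_true(all(d$med_oral %in% 0:1))
  # roughly 60% male as in the target population
  expect_true(abs(mean(d$gender == "male") - 0.6) < 0.15)
})

test_that("injection union semantics: combined masks are the OR of parts", {
  set.seed(13)
  m1 <- inject_iid_dropout(2000, 0.05)
  m2 <- inject_gap_process(2000, 0.01, list(name = "geometric", p = 0.5))
  # union by construction when applied sequentially to the same grid
  expect_identical(m1 | m2, m2 | m1)
  expect_true(all((m1 | m2)[m1]))
})
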