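test_that("extract_gaps equals the brute-force scan, exhaustively to length 12", {
  expect_equal(extract_gaps(c(FALSE, TRUE, TRUE, FALSE, TRUE)), c(2L, 1L))
  expect_equal(extract_gaps(rep(FALSE, 5)), integer())
  expect_equal(extract_gaps(logical()), integer())
  expect_equal(extract_gaps(rep(TRUE, 4)), 4L)

  mismatches <- 0L
  for (len in 1:12) {
    for (code in 0:(2^len - 1)) {
      mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(len - 1)), 1L))
      if (!identical(extract_gaps(mask), gap_scan_oracle(mask))) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("gap pooling truncates at the first low-frequency size", {
  # [1,1,2]: size 1 already has count <= 5, so nothing is retained
  f1 <- pool_gap_frequency(c(1L, 1L, 2L))
  expect_true(f1$insufficient)
  expect_equal(f1$cutoff_size, 1L)
  expect_equal(f1$total_gaps, 3L)

  # counts {1:10, 2:6, 3:5, 4:8}: cutoff at 3, sizes {1, 2} retained
  gaps <- rep(1:4, times = c(10, 6, 5, 8))
  f2 <- pool_gap_frequency(gaps)
  expect_equal(f2$cutoff_size, 3L)
  expect_equal(f2$sizes[f2$retained], 1:2)
  expect_equal(f2$counts[f2$retained], c(10L, 6L))
  expect_equal(f2$total_gaps, 29L)

  # a single abundant size is fully retained
  f3 <- pool_gap_frequency(rep(1L, 100))
  expect_equal(f3$sizes[f3$retained], 1L)
  expect_false(f3$insufficient)

  # zero-count sizes below the cutoff stay in the table with count 0
  f4 <- pool_gap_frequency(rep(c(1L, 3L), times = c(10, 8)))
  expect_equal(f4$sizes[f4$retained], 1:3)
  expect_equal(f4$counts[f4$retained], c(10L, 0L, 8L))

  # no gaps at all: flagged and classified as insufficient downstream
  f5 <- pool_gap_frequency(integer())
  expect_true(f5$insufficient)
  expect_equal(f5$total_gaps, 0L)

  # recordings are accepted directly
  f6 <- pool_gap_frequency(list(mask_recording(c(TRUE, TRUE, FALSE, TRUE)),
                                mask_recording(c(FALSE, TRUE, FALSE, FALSE))))
  expect_equal(f6$total_gaps, 3L)
})

test_that("Planck MLE matches the closed form and a grid-search oracle", {
  cfg0 <- analysis_config(frequency_cutoff_count = 0)
  # gaps [1,1,2]: kbar = 4/3, lambda = ln 4
  f <- pool_gap_frequency(c(1L, 1L, 2L), cfg0)
  fit <- fit_planck(f, cfg0)
  expect_equal(unname(fit$params[["lambda"]]), log(4), tolerance = 1e-12)

  # gaps [2,2,2]: kbar = 2, lambda = ln 2
  f2 <- pool_gap_frequency(c(2L, 2L, 2L), cfg0)
  expect_equal(unname(fit_planck(f2, cfg0)$params[["lambda"]]), log(2),
               tolerance = 1e-12)

  # closed form agrees with a log-likelihood grid search on random samples
  set.seed(101)
  for (i in 1:10) {
    gaps <- 1L + rgeom(500, runif(1, 0.2, 0.8))
    if (all(gaps == 1L)) gaps[1] <- 2L
    fit_i <- fit_planck(pool_gap_frequency(gaps, cfg0), cfg0)
    oracle <- planck_mle_grid_oracle(gaps)
    expect_equal(unname(fit_i$params[["lambda"]]), oracle, tolerance = 1e-6)
  }

  # all gaps of size one: degenerate fit is flagged
  fdeg <- fit_planck(pool_gap_frequency(rep(1L, 50), cfg0), cfg0)
  expect_true(fdeg$degenerate)
  expect_equal(unname(fdeg$params[["lambda"]]), Inf)
  expect_equal(classify_step1(pool_gap_frequency(rep(1L, 50), cfg0), fdeg),
               "insufficient")
})

test_that("Planck parameter recovery within 2% at n = 10^4", {
  set.seed(2024)
  lambda <- 0.5
  gaps <- 1L + rgeom(1e4, 1 - exp(-lambda))
  fit <- fit_planck(pool_gap_frequency(gaps))
  expect_lt(abs(fit$params[["lambda"]] - lambda) / lambda, 0.02)
})

test_that("family fits behave as their parameterisations require", {
  set.seed(77)
  gaps <- 1L + rgeom(2000, 0.6)
  freq <- pool_gap_frequency(gaps)

  # geometric and planck are reparameterisations: equal log-likelihood
  g <- fit_family("geometric", freq)
  p <- fit_family("planck", freq)
  expect_equal(g$loglik, p$loglik, tolerance = 1e-6)
  expect_equal(unname(g$params[["p"]]), 1 - exp(-p$params[["lambda"]]),
               tolerance = 1e-5)

  # zipf exponent recovered within 5% from 10^4 draws
  zg <- rzipf(1e4, 2)
  zf <- fit_family("zipf", pool_gap_frequency(zg))
  expect_lt(abs(zf$params[["a"]] - 2) / 2, 0.05)

  # uniform fit on equal counts has zero SSE
  cfg0 <- analysis_config(frequency_cutoff_count = 0)
  fu <- fit_family("uniform", pool_gap_frequency(rep(1:3, each = 7), cfg0), cfg0)
  expect_equal(fu$sse, 0, tolerance = 1e-12)
  expect_equal(fu$chi2_stat, 0, tolerance = 1e-12)

  expect_error(fit_family("cauchy", freq), "unknown")
})

test_that("fitted pmfs are normalised over their support", {
  set.seed(31)
  gaps <- c(1L + rgeom(400, 0.5), rzipf(100, 2.2))
  freq <- pool_gap_frequency(gaps)
  N <- max(freq$sizes[freq$retained])
  fams <- c("planck", "geometric", "poisson", "logarithmic", "negative_binomial",
            "boltzmann", "zipf", "zipfian", "yule_simon", "uniform",
            "skellam", "discrete_laplace", "beta_binomial", "hypergeometric")
  for (fam in fams) {
    fit <- fit_family(fam, freq)
    if (!isTRUE(fit$converged)) next
    support <- if (fam %in% c("planck", "geometric", "poisson", "logarithmic",
                              "negative_binomial", "zipf", "yule_simon")) {
      1:5000   # infinite support: tail bound
    } else seq_len(fit$N)
    tot <- sum(gap_pmf(fam, support, fit$params, N = fit$N))
    tol <- if (length(support) > 1000) 1e-3 else 1e-9
    expect_true(abs(tot - 1) < tol, label = paste(fam, "normalisation", tot))
  }
})

test_that("chi-square GOF matches hand computation and flags degenerate tables", {
  # obs [8, 2] against a uniform model: expected [5, 5], X2 = 3.6, p = 0.0578
  cfg0 <- analysis_config(frequency_cutoff_count = 0)
  freq <- pool_gap_frequency(rep(1:2, times = c(8, 2)), cfg0)
  fit <- fit_family("uniform", freq, cfg0)
  gof <- chi_square_gof(freq, fit, cfg0)
  expect_equal(gof$statistic, 3.6, tolerance = 1e-12)
  expect_equal(gof$dof, 1L)
  expect_equal(gof$p, pchisq(3.6, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(gof$p, 4), 0.0578)

  # perfect agreement: statistic 0, p = 1
  freq2 <- pool_gap_frequency(rep(1:2, times = c(50, 50)), cfg0)
  gof2 <- chi_square_gof(freq2, fit_family("uniform", freq2, cfg0), cfg0)
  expect_equal(gof2$statistic, 0, tolerance = 1e-12)
  expect_equal(gof2$p, 1)

  # fewer than two retained sizes: test undefined
  freq3 <- pool_gap_frequency(rep(1L, 30))
  gof3 <- chi_square_gof(freq3, fit_family("uniform", freq3))
  expect_true(gof3$flagged)
})

test_that("SSE agrees with hand arithmetic and defines the family ranking", {
  # empirical [0.8, 0.2] against fitted [0.75, 0.25]: SSE = 0.005
  cfg0 <- analysis_config(frequency_cutoff_count = 0)
  freq <- pool_gap_frequency(rep(1:2, times = c(8, 2)), cfg0)
  # boltzmann with lambda = ln 3 renormalises to (0.75, 0.25) on {1, 2}
  fit <- fit_family("boltzmann", freq, cfg0)
  fit$params <- c(lambda = log(3))
  expect_equal(sse_of_fit(freq, fit), 0.005, tolerance = 1e-12)

  # the best family by SSE is the minimiser among converged fits
  set.seed(5)
  gaps <- rzipf(2000, 2)
  models <- fit_gap_models(pool_gap_frequency(gaps),
                           families = c("planck", "zipf"))
  expect_equal(models$best_by_sse, "zipf")
  expect_lt(models$fits$zipf$sse, models$fits$planck$sse)
})

test_that("step-1 verdict applies a strict alpha threshold on the Planck GOF", {
  cfg <- analysis_config()
  mk <- function(p) {
    f <- fit_planck(pool_gap_frequency(rep(1:3, times = c(100, 50, 25))))
    f$chi2_p <- p
    f
  }
  freq <- pool_gap_frequency(rep(1:3, times = c(100, 50, 25)))
  expect_equal(classify_step1(freq, mk(0.99), cfg), "M(C)AR")
  expect_equal(classify_step1(freq, mk(0.0005), cfg), "MNAR")
  expect_equal(classify_step1(freq, mk(0.01), cfg), "M(C)AR")  # boundary: strict <
  expect_equal(classify_step1(freq, mk(0.00999), cfg), "MNAR")
})

test_that("gap-size discrimination: iid dropout keeps, heavy tails break, the decline", {
  verdicts <- vapply(1:20, function(s) {
    gaps <- unlist(lapply(1:10, function(i) {
      extract_gaps(with_seed_local(s * 100 + i, inject_iid_dropout(20000, 0.1)))
    }))
    freq <- pool_gap_frequency(gaps)
    classify_step1(freq, fit_planck(freq))
  }, character(1))
  expect_gte(mean(verdicts == "M(C)AR"), 0.9)

  verdicts2 <- vapply(1:20, function(s) {
    gaps <- unlist(lapply(1:10, function(i) {
      extract_gaps(with_seed_local(s * 100 + i,
        inject_gap_process(20000, 0.015, list(name = "zipf", a = 2))))
    }))
    freq <- pool_gap_frequency(gaps)
    classify_step1(freq, fit_planck(freq))
  }, character(1))
  expect_gte(mean(verdicts2 == "MNAR"), 0.9)
})

test_that("zipfian beats planck on heavy-tailed gaps with excess single gaps", {
  set.seed(9)
  gaps <- c(rzipf(4000, 2), rep(1L, 1500))
  models <- fit_gap_models(pool_gap_frequency(gaps),
                           families = c("planck", "zipfian"))
  expect_lt(models$fits$zipfian$sse, models$fits$planck$sse)
})
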