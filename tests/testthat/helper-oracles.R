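# Independent oracles, coded deliberately differently from the package paths.

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# brute-force run-length scan: walk the mask and count consecutive TRUEs
gap_scan_oracle <- function(mask) {
  gaps <- integer()
  run <- 0L
  for (m in mask) {
    if (isTRUE(m)) {
      run <- run + 1L
    } else if (run > 0L) {
      gaps <- c(gaps, run)
      run <- 0L
    }
  }
  if (run > 0L) gaps <- c(gaps, run)
  gaps
}

# Planck MLE by numeric maximisation of the log-likelihood (no closed form)
planck_mle_grid_oracle <- function(gaps) {
  cnt <- tabulate(gaps)
  sizes <- seq_along(cnt)
  ll <- function(lam) sum(cnt * (log(1 - exp(-lam)) - lam * (sizes - 1)))
  grid <- seq(1e-4, 12, length.out = 4000)
  lam0 <- grid[which.max(vapply(grid, ll, numeric(1)))]
  stats::optimize(ll, c(max(lam0 - 0.01, 1e-6), lam0 + 0.01),
                  maximum = TRUE, tol = 1e-12)$maximum
}

# Dunn post hoc from first principles: explicit loops, pooled ranks with
# average ties, tie correction from an explicit tally of tied values
dunn_oracle <- function(groups) {
  x <- c(); g <- c()
  for (i in seq_along(groups)) {
    v <- groups[[i]]
    v <- v[!is.na(v)]
    x <- c(x, v); g <- c(g, rep(i, length(v)))
  }
  N <- length(x)
  r <- rank(x, ties.method = "average")
  tie_term <- 0
  for (val in unique(x)) {
    t <- sum(x == val)
    tie_term <- tie_term + (t^3 - t)
  }
  k <- length(groups)
  m <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (sum(g == i) > 0 && sum(g == j) > 0) m <- m + 1
  }
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ni <- sum(g == i); nj <- sum(g == j)
    if (ni == 0 || nj == 0) next
    num <- mean(r[g == i]) - mean(r[g == j])
    den <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) * (1 / ni + 1 / nj))
    z <- if (den <= 0) 0 else num / den
    p <- min(1, 2 * (1 - pnorm(abs(z))) * m)
    out[[paste(i, j)]] <- c(i = i, j = j, z = z, p_adj = p)
  }
  do.call(rbind, out)
}

# interval-union coverage: fraction of sample times inside U (s - cap, s]
buffer_coverage_oracle <- function(timestamps, cap, syncs) {
  syncs <- sort(unique(c(syncs, max(timestamps))))
  covered <- vapply(timestamps, function(t) {
    any(t >= syncs - cap & t <= syncs)
  }, logical(1))
  covered
}

# build a recording straight from a missing mask on a uniform grid
mask_recording <- function(mask, subject_id = "S1", modality = "hr",
                           start = "2019-03-07 00:00:00", step_min = 1) {
  start <- as.POSIXct(start, tz = "UTC")
  vals <- ifelse(mask, NA_real_, 1)
  recording(subject_id, modality, start, step_min, seq_along(mask) - 1L,
            vals, mask)
}

# raw series fixture on explicit minute offsets
minutes_series <- function(subject_id, modality, offsets_min, values,
                           start = "2019-03-07 00:00:00") {
  start <- as.POSIXct(start, tz = "UTC")
  raw_series(subject_id, modality, start + offsets_min * 60, values)
}

# a small long-format cohort CSV on disk, returning its path
write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "raw.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
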