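# Step 1: pooled gap-size frequency, discrete pmf fitting, goodness of fit,
# and the exponential-decline (MNAR) decision.

#' Extract gap lengths from a missing mask
#'
#' A gap is a maximal run of consecutive missing samples; runs touching
#' either end of the recording count too.
#'
#' @param mask logical vector, `TRUE` = missing.
#' @return Integer vector of gap lengths (possibly empty).
#' @export
extract_gaps <- function(mask) {
  stopifnot(is.logical(mask))
  if (!length(mask) || !any(mask)) return(integer())
  r <- rle(mask)
  as.integer(r$lengths[r$values])
}

#' Pool gap lengths into a cohort frequency table
#'
#' Gap counts are summed over recordings. Following the validity requirement
#' of the chi-square test for small expected counts, the table is truncated
#' at the first observed gap size (in increasing order) whose count is less
#' than or equal to `frequency_cutoff_count` (5); that size and all larger
#' sizes are dropped. Sizes with zero count below the cutoff are retained
#' with count 0.
#'
#' @param gaps integer vector of gap lengths, or a list of such vectors (one
#'   per recording), or a list of [recording()] objects.
#' @param config an [analysis_config()].
#' @return An object of class `wm_gap_frequency`: `sizes` (1..max observed),
#'   `counts`, `retained` (logical), `total_gaps`, `cutoff_size` (`NA` when
#'   nothing was truncated) and `insufficient` (no retained sizes).
#' @export
pool_gap_frequency <- function(gaps, config = analysis_config()) {
  if (is.list(gaps)) {
    gaps <- unlist(lapply(gaps, function(g) {
      if (inherits(g, "wm_recording")) extract_gaps(g$missing) else g
    }), use.names = FALSE)
  }
  gaps <- as.integer(gaps)
  stopifnot(all(gaps >= 1L) || length(gaps) == 0L)
  if (!length(gaps)) {
    return(structure(list(sizes = integer(), counts = integer(),
                          retained = logical(), total_gaps = 0L,
                          cutoff_size = NA_integer_, insufficient = TRUE),
                     class = "wm_gap_frequency"))
  }
  counts <- tabulate(gaps, nbins = max(gaps))
  sizes <- seq_along(counts)
  observed <- which(counts > 0L)
  low <- observed[counts[observed] <= config$frequency_cutoff_count]
  cutoff <- if (length(low)) low[1L] else NA_integer_
  retained <- if (is.na(cutoff)) rep(TRUE, length(sizes)) else sizes < cutoff
  structure(list(sizes = sizes, counts = as.integer(counts), retained = retained,
                 total_gaps = length(gaps), cutoff_size = cutoff,
                 insufficient = !any(retained)),
            class = "wm_gap_frequency")
}

#' @export
print.wm_gap_frequency <- function(x, ...) {
  cat(sprintf("<wm_gap_frequency> %d gaps, %d sizes (%d retained), cutoff %s\n",
              x$total_gaps, length(x$sizes), sum(x$retained),
              ifelse(is.na(x$cutoff_size), "none", x$cutoff_size)))
  invisible(x)
}

# ---- discrete pmf family registry -------------------------------------------
#
# Gap sizes k are integers >= 1. Families whose standard support is
# {0, 1, ...} (planck, geometric, poisson, negative binomial, boltzmann,
# skellam, discrete laplace, beta-binomial, hypergeometric) are fitted on the
# shifted sizes k - 1; families natively supported on {1, 2, ...} (zipf,
# zeta, zipfian, yule-simon, logarithmic, uniform) are fitted unshifted.
# Bounded-support families use N = the largest retained size as their bound
# and are fitted on the truncated table; infinite-support families are
# fitted on the full table.

planck_pmf <- function(k, lambda) (1 - exp(-lambda)) * exp(-lambda * (k - 1))

gharm <- function(N, a) sum(seq_len(N)^(-a))

family_pmf <- function(family, k, params, N) {
  switch(family,
    planck = planck_pmf(k, params[["lambda"]]),
    geometric = stats::dgeom(k - 1, params[["p"]]),
    poisson = stats::dpois(k - 1, params[["mu"]]),
    logarithmic = {
      p <- params[["p"]]
      -p^k / (k * log(1 - p))
    },
    negative_binomial = stats::dnbinom(k - 1, size = params[["size"]],
                                       prob = params[["prob"]]),
    boltzmann = {
      lam <- params[["lambda"]]
      w <- exp(-lam * (0:(N - 1)))
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      out[ok] <- exp(-lam * (k[ok] - 1)) / sum(w)
      out
    },
    zipf = ,
    zeta = k^(-params[["a"]]) / pracma::zeta(params[["a"]]),
    zipfian = {
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      out[ok] <- k[ok]^(-params[["a"]]) / gharm(N, params[["a"]])
      out
    },
    yule_simon = {
      rho <- params[["rho"]]
      exp(log(rho) + lbeta(k, rho + 1))
    },
    uniform = {
      out <- numeric(length(k))
      out[k >= 1 & k <= N] <- 1 / N
      out
    },
    skellam = {
      m1 <- params[["mu1"]]; m2 <- params[["mu2"]]
      f <- function(x) exp(-(m1 + m2) + (x / 2) * log(m1 / m2)) *
        besselI(2 * sqrt(m1 * m2), abs(x))
      w <- vapply(0:(N - 1), f, numeric(1))
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      out[ok] <- f(k[ok] - 1) / sum(w)
      out
    },
    discrete_laplace = {
      p <- params[["p"]]; m <- params[["m"]]
      w <- p^abs((0:(N - 1)) - m)
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      out[ok] <- p^abs(k[ok] - 1 - m) / sum(w)
      out
    },
    beta_binomial = {
      a <- params[["alpha"]]; b <- params[["beta"]]; n <- N - 1
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      x <- k[ok] - 1
      out[ok] <- exp(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
      out
    },
    hypergeometric = {
      m <- params[["m"]]; n <- N - 1
      out <- numeric(length(k))
      ok <- k >= 1 & k <= N
      out[ok] <- stats::dhyper(k[ok] - 1, m, 2 * n - m, n)
      out
    },
    stop("unknown pmf family: ", family)
  )
}

#' Discrete pmf values for a fitted or hypothetical family
#'
#' @param family family name (see [fit_family()]).
#' @param sizes integer gap sizes (>= 1).
#' @param params named numeric parameter vector.
#' @param N support bound for bounded families.
#' @return Numeric pmf values at `sizes`.
#' @export
gap_pmf <- function(family, sizes, params, N = max(sizes)) {
  family_pmf(family, as.numeric(sizes), params, N)
}

BOUNDED_FAMILIES <- c("boltzmann", "zipfian", "uniform", "skellam",
                      "discrete_laplace", "beta_binomial", "hypergeometric")

#' Fit the Planck (normalised discrete exponential) pmf by maximum likelihood
#'
#' The Planck pmf `P(k) = (1 - e^-lambda) e^-lambda(k-1)`, `k >= 1`, is the
#' exponential-decline reference model for gap sizes under a random
#' (Poisson-like) loss process. Its MLE has the closed form
#' `lambda = log(kbar / (kbar - 1))` with `kbar` the mean gap size; the fit
#' uses the full (untruncated) frequency table, while the goodness-of-fit
#' statistics are evaluated on the truncated table (renormalised over the
#' retained sizes).
#'
#' @param freq a [pool_gap_frequency()] table.
#' @param config an [analysis_config()].
#' @return An object of class `wm_pmf_fit` with elements `family`, `params`,
#'   `loglik`, `chi2_stat`, `chi2_p`, `sse`, `dof`, `degenerate`,
#'   `converged`, `N`.
#' @export
fit_planck <- function(freq, config = analysis_config()) {
  stopifnot(inherits(freq, "wm_gap_frequency"))
  if (freq$total_gaps == 0L) stop("no gaps to fit")
  kbar <- sum(freq$sizes * freq$counts) / sum(freq$counts)
  if (kbar <= 1) {
    fit <- new_pmf_fit("planck", c(lambda = Inf), loglik = 0,
                       degenerate = TRUE, N = max(freq$sizes))
    return(add_gof(fit, freq, config))
  }
  lambda <- log(kbar / (kbar - 1))
  ll <- sum(freq$counts * log(planck_pmf(freq$sizes, lambda)))
  add_gof(new_pmf_fit("planck", c(lambda = lambda), ll, N = max(freq$sizes)),
          freq, config)
}

new_pmf_fit <- function(family, params, loglik, degenerate = FALSE,
                        converged = TRUE, N = NA_integer_) {
  structure(list(family = family, params = params, loglik = loglik,
                 chi2_stat = NA_real_, chi2_p = NA_real_, sse = NA_real_,
                 dof = NA_integer_, degenerate = degenerate,
                 converged = converged, N = N),
            class = "wm_pmf_fit")
}

#' @export
print.wm_pmf_fit <- function(x, ...) {
  cat(sprintf("<wm_pmf_fit> %s(%s), loglik %.3f, chi2 %.3f (p = %.4g), SSE %.3g\n",
              x$family, paste(sprintf("%s = %.4g", names(x$params), x$params),
                              collapse = ", "),
              x$loglik, x$chi2_stat, x$chi2_p, x$sse))
  invisible(x)
}

add_gof <- function(fit, freq, config) {
  gof <- chi_square_gof(freq, fit, config)
  fit$chi2_stat <- gof$statistic
  fit$chi2_p <- gof$p
  fit$dof <- gof$dof
  fit$sse <- sse_of_fit(freq, fit)
  fit
}

# generic bounded numeric MLE on transformed parameters
numeric_mle <- function(nll, start) {
  opt <- try(stats::optim(start, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) return(NULL)
  list(par = opt$par, loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' Fit a named discrete distribution to a gap frequency table
#'
#' Candidate families for ranking the gap-size distribution: `planck`,
#' `geometric`, `poisson`, `logarithmic`, `negative_binomial`, `boltzmann`
#' (truncated discrete exponential), `zipf` / `zeta` (infinite-support power
#' law), `zipfian` (finite-support power law), `yule_simon`, `uniform`,
#' `skellam`, `discrete_laplace`, `beta_binomial`, `hypergeometric`.
#' Infinite-support families are fitted on the full table, bounded families
#' on the truncated table with support bound `N` = largest retained size.
#' Bounded exotic families are ranking candidates only; the MNAR decision
#' uses the Planck fit exclusively.
#'
#' @param family family name.
#' @param freq a [pool_gap_frequency()] table.
#' @param config an [analysis_config()].
#' @return A `wm_pmf_fit`; `converged = FALSE` flags optimiser failure (such
#'   fits are excluded from model ranking).
#' @export
fit_family <- function(family, freq, config = analysis_config()) {
  stopifnot(inherits(freq, "wm_gap_frequency"))
  if (freq$insufficient) stop("no retained sizes to fit")
  N <- max(freq$sizes[freq$retained])
  bounded <- family %in% BOUNDED_FAMILIES
  sel <- if (bounded) freq$retained & freq$sizes <= N else freq$counts > 0L
  sizes <- freq$sizes[sel]
  counts <- freq$counts[sel]
  use <- counts > 0L
  nll_of <- function(par_fun) {
    function(theta) {
      params <- par_fun(theta)
      p <- family_pmf(family, sizes[use], params, N)
      if (any(!is.finite(p)) || any(p <= 0)) return(1e12)
      -sum(counts[use] * log(p))
    }
  }
  kbar <- sum(sizes * counts) / sum(counts)

  if (family == "planck") return(fit_planck(freq, config))
  if (family == "uniform") {
    ll <- -sum(counts) * log(N)
    return(add_gof(new_pmf_fit("uniform", numeric(), ll, N = N), freq, config))
  }

  spec <- switch(family,
    geometric = list(par_fun = function(t) c(p = stats::plogis(t)),
                     start = stats::qlogis(min(max(1 / kbar, 1e-6), 1 - 1e-6))),
    poisson = list(par_fun = function(t) c(mu = exp(t)),
                   start = log(max(kbar - 1, 0.05))),
    logarithmic = list(par_fun = function(t) c(p = stats::plogis(t)),
                       start = stats::qlogis(0.5)),
    negative_binomial = list(
      par_fun = function(t) c(size = exp(t[1]), prob = stats::plogis(t[2])),
      start = c(0, 0)),
    boltzmann = list(par_fun = function(t) c(lambda = exp(t)),
                     start = log(max(log(kbar / max(kbar - 1, 1e-6)), 1e-3))),
    zipf = ,
    zeta = list(par_fun = function(t) c(a = 1 + exp(t)),
                start = log(1)),
    zipfian = list(par_fun = function(t) c(a = exp(t)), start = log(1.5)),
    yule_simon = list(par_fun = function(t) c(rho = exp(t)), start = log(1.5)),
    skellam = list(par_fun = function(t) c(mu1 = exp(t[1]), mu2 = exp(t[2])),
                   start = c(log(max(kbar - 1, 0.5)), 0)),
    discrete_laplace = list(
      par_fun = function(t) c(p = stats::plogis(t[1]), m = t[2]),
      start = c(0, kbar - 1)),
    beta_binomial = list(
      par_fun = function(t) c(alpha = exp(t[1]), beta = exp(t[2])),
      start = c(0, log(max(N / max(kbar - 1, 0.2), 1.5)))),
    hypergeometric = NULL,
    stop("unknown family: ", family)
  )

  if (family == "hypergeometric") {
    # integer success-count parameter: profile over a grid
    n <- N - 1
    if (n < 1) return(add_gof(new_pmf_fit(family, c(m = NA_real_), -Inf,
                                          converged = FALSE, N = N), freq, config))
    ms <- n:(2 * n)
    ll <- vapply(ms, function(m) {
      p <- family_pmf(family, sizes[use], c(m = m), N)
      if (any(p <= 0)) return(-Inf)
      sum(counts[use] * log(p))
    }, numeric(1))
    best <- which.max(ll)
    return(add_gof(new_pmf_fit(family, c(m = ms[best]), ll[best],
                               converged = is.finite(ll[best]), N = N),
                   freq, config))
  }

  if (length(spec$start) == 1L) {
    nll <- nll_of(spec$par_fun)
    opt <- stats::optimize(function(t) nll(t), interval = c(-15, 15), tol = 1e-10)
    params <- spec$par_fun(opt$minimum)
    res <- list(par = opt$minimum, loglik = -opt$objective,
                converged = is.finite(opt$objective) && opt$objective < 1e12)
  } else {
    res <- numeric_mle(nll_of(spec$par_fun), spec$start)
    if (is.null(res)) {
      return(add_gof(new_pmf_fit(family, spec$par_fun(spec$start), -Inf,
                                 converged = FALSE, N = N), freq, config))
    }
    params <- spec$par_fun(res$par)
  }
  add_gof(new_pmf_fit(family, params, res$loglik, converged = res$converged,
                      N = N), freq, config)
}

#' One-way chi-square goodness of fit on the truncated gap table
#'
#' Expected counts are the retained total times the fitted pmf renormalised
#' over the retained sizes, so observed and expected totals agree. Degrees of
#' freedom default to `bins - 1` (plain one-way test); set
#' `reduce_dof_for_params` in the configuration to additionally subtract the
#' number of estimated parameters.
#'
#' @param freq a [pool_gap_frequency()] table.
#' @param fit a `wm_pmf_fit`.
#' @param config an [analysis_config()].
#' @return List with `statistic`, `p`, `dof`, `expected`, and `flagged`
#'   (`TRUE` when the test is undefined: fewer than 2 retained sizes or a
#'   degenerate fit).
#' @export
chi_square_gof <- function(freq, fit, config = analysis_config()) {
  stopifnot(inherits(freq, "wm_gap_frequency"), inherits(fit, "wm_pmf_fit"))
  sizes <- freq$sizes[freq$retained]
  counts <- freq$counts[freq$retained]
  if (length(sizes) < 2L || isTRUE(fit$degenerate) || !isTRUE(fit$converged)) {
    return(list(statistic = NA_real_, p = NA_real_, dof = NA_integer_,
                expected = NULL, flagged = TRUE))
  }
  p <- family_pmf(fit$family, sizes, fit$params, fit$N)
  if (any(!is.finite(p)) || sum(p) <= 0) {
    return(list(statistic = NA_real_, p = NA_real_, dof = NA_integer_,
                expected = NULL, flagged = TRUE))
  }
  p <- p / sum(p)
  expected <- sum(counts) * p
  stat <- sum((counts - expected)^2 / expected)
  dof <- length(sizes) - 1L -
    if (config$reduce_dof_for_params) length(fit$params) else 0L
  dof <- max(dof, 1L)
  list(statistic = stat, p = stats::pchisq(stat, dof, lower.tail = FALSE),
       dof = dof, expected = expected, flagged = FALSE)
}

#' Sum of squared errors between empirical and fitted gap probabilities
#'
#' Computed over the retained sizes with both the empirical distribution and
#' the fitted pmf normalised over those sizes.
#'
#' @param freq a [pool_gap_frequency()] table.
#' @param fit a `wm_pmf_fit`.
#' @return A single nonnegative number (`NA` when undefined).
#' @export
sse_of_fit <- function(freq, fit) {
  stopifnot(inherits(freq, "wm_gap_frequency"), inherits(fit, "wm_pmf_fit"))
  sizes <- freq$sizes[freq$retained]
  counts <- freq$counts[freq$retained]
  if (!length(sizes) || isTRUE(fit$degenerate)) return(NA_real_)
  p <- family_pmf(fit$family, sizes, fit$params, fit$N)
  if (any(!is.finite(p)) || sum(p) <= 0) return(NA_real_)
  p <- p / sum(p)
  emp <- counts / sum(counts)
  sum((emp - p)^2)
}

#' Step-1 decision: does the gap-size distribution decline exponentially?
#'
#' The missing data are labelled MNAR when the pooled gap-size frequency
#' differs significantly (chi-square p below `alpha`, strict) from the
#' fitted Planck pmf; otherwise they are M(C)AR and Step 2 decides between
#' MCAR and MAR. The verdict is `"insufficient"` when the truncated table
#' cannot support the test.
#'
#' @param freq a [pool_gap_frequency()] table.
#' @param planck_fit the [fit_planck()] result.
#' @param config an [analysis_config()].
#' @return `"MNAR"`, `"M(C)AR"` or `"insufficient"`.
#' @export
classify_step1 <- function(freq, planck_fit, config = analysis_config()) {
  stopifnot(inherits(planck_fit, "wm_pmf_fit"))
  if (freq$insufficient || is.na(planck_fit$chi2_p)) return("insufficient")
  if (planck_fit$chi2_p < config$alpha) "MNAR" else "M(C)AR"
}

#' Fit and rank a set of candidate families
#'
#' @param freq a [pool_gap_frequency()] table.
#' @param families character vector of family names.
#' @param config an [analysis_config()].
#' @return List with `fits` (named list of `wm_pmf_fit`) and `best_by_sse`
#'   (name of the converged family with the smallest SSE).
#' @export
fit_gap_models <- function(freq,
                           families = c("planck", "geometric", "zipf", "zipfian",
                                        "poisson", "boltzmann"),
                           config = analysis_config()) {
  fits <- lapply(families, function(f) fit_family(f, freq, config))
  names(fits) <- families
  sses <- vapply(fits, function(f) {
    if (isTRUE(f$converged) && !isTRUE(f$degenerate) && is.finite(f$sse)) f$sse else Inf
  }, numeric(1))
  list(fits = fits,
       best_by_sse = if (all(!is.finite(sses))) NA_character_ else names(which.min(sses)))
}
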