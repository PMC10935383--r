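# Synthetic cohort generator: glucose / heart-rate / step-count recordings
# with known ground-truth missingness, including the device storage-buffer
# mechanisms (flash-CGM FIFO overwrite synchronised by scans; tracker
# stop-when-full synchronised at scheduled visits).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Device storage model
#'
#' Describes how a wearable device buffers samples and when it synchronises.
#' The flash CGM stores 8 h of readings and overwrites the oldest when full;
#' it persists data only at manual scan events. The wrist tracker stores
#' roughly 6 days of combined heart-rate + step recordings, stops recording
#' steps when full, and is synchronised at scheduled study visits.
#'
#' @param type `"cgm"` or `"tracker"`; sets all defaults.
#' @param buffer_capacity_hours on-device storage span, hours.
#' @param sync_policy `"scan_events"` (subject-initiated scans while awake) or
#'   `"scheduled_visits"` (study-protocol visits).
#' @param scan_rate mean scans per waking hour (scan_events policy).
#' @param visit_days day indices (1-based) of synchronisation visits
#'   (scheduled_visits policy); a terminal sync at recording end is implicit.
#' @param visit_hour clock hour of the visit.
#' @param overflow_policy `"overwrite_oldest"` (FIFO) or `"stop_when_full"`.
#' @return An object of class `wm_device`.
#' @export
device_model <- function(type = c("cgm", "tracker"),
                         buffer_capacity_hours = NULL,
                         sync_policy = NULL,
                         scan_rate = 1.5,
                         visit_days = 7,
                         visit_hour = 14,
                         overflow_policy = NULL) {
  type <- match.arg(type)
  if (is.null(buffer_capacity_hours)) {
    buffer_capacity_hours <- if (type == "cgm") 8 else 5.5 * 24
  }
  if (is.null(sync_policy)) {
    sync_policy <- if (type == "cgm") "scan_events" else "scheduled_visits"
  }
  if (is.null(overflow_policy)) {
    overflow_policy <- if (type == "cgm") "overwrite_oldest" else "stop_when_full"
  }
  sync_policy <- match.arg(sync_policy, c("scan_events", "scheduled_visits"))
  overflow_policy <- match.arg(overflow_policy, c("overwrite_oldest", "stop_when_full"))
  stopifnot(buffer_capacity_hours > 0, scan_rate >= 0)
  structure(list(type = type, buffer_capacity_hours = buffer_capacity_hours,
                 sync_policy = sync_policy, scan_rate = scan_rate,
                 visit_days = visit_days, visit_hour = visit_hour,
                 overflow_policy = overflow_policy),
            class = "wm_device")
}

#' Sleep model
#'
#' Nightly sleep onset and duration, jittered per night. Defaults emulate a
#' typical adult schedule: onset around 23:00 and 7.75 h of sleep, so that an
#' 8-h device buffer is close to, and regularly exceeded by, the overnight
#' no-synchronisation span.
#'
#' @param onset_hour mean sleep-onset clock hour.
#' @param onset_sd nightly onset jitter, hours.
#' @param duration_hours mean sleep duration, hours (0 < duration < 24).
#' @param duration_sd nightly duration jitter, hours.
#' @return An object of class `wm_sleep`.
#' @export
sleep_model <- function(onset_hour = 23, onset_sd = 0.5,
                        duration_hours = 7.75, duration_sd = 0.5) {
  stopifnot(duration_hours > 0, duration_hours < 24,
            onset_sd >= 0, duration_sd >= 0)
  structure(list(onset_hour = onset_hour, onset_sd = onset_sd,
                 duration_hours = duration_hours, duration_sd = duration_sd),
            class = "wm_sleep")
}

#' Simulate a nightly sleep schedule
#'
#' @param sleep a [sleep_model()].
#' @param days number of recording days.
#' @param seed optional seed.
#' @return Data frame with one row per night (including the night preceding
#'   recording start) and columns `onset_h`, `wake_h` in hours from the
#'   recording start (midnight of day 1); `onset_h` of the first row is
#'   negative.
#' @export
simulate_sleep_schedule <- function(sleep, days, seed = NULL) {
  stopifnot(inherits(sleep, "wm_sleep"), days >= 1)
  with_seed(seed, {
    nights <- seq.int(-1L, days - 1L)
    onset <- nights * 24 + sleep$onset_hour + stats::rnorm(length(nights), 0, sleep$onset_sd)
    dur <- pmin(pmax(sleep$duration_hours +
                       stats::rnorm(length(nights), 0, sleep$duration_sd), 2), 14)
    data.frame(onset_h = onset, wake_h = onset + dur)
  })
}

#' Missingness mechanism specification
#'
#' @param kind one of `"mcar_iid"` (each sample missing independently),
#'   `"mcar_gap_process"` (iid gap starts with gap sizes drawn from a named
#'   discrete family; a heavy-tailed family such as Zipf manufactures MNAR),
#'   `"mar_time"` (dropout probability depending on the clock hour),
#'   `"mnar_device"` (gap process with an excess of single-sample gaps,
#'   mimicking transient sensor-contact errors), or `"buffer"` (device
#'   storage-buffer loss; realised from the [device_model()] and
#'   [sleep_model()] of the cohort).
#' @param ... kind-specific parameters, see Details.
#'
#' @details Parameters by kind: `mcar_iid`: `rate` in `[0, 1)`.
#'   `mcar_gap_process`: `gap_start_rate`, `family` (list with `name` in
#'   geometric/planck/zipf/poisson/deterministic plus its parameters).
#'   `mar_time`: `hour_profile`, 24 per-hour dropout probabilities.
#'   `mnar_device`: `gap_start_rate`, `excess_single` (probability a gap has
#'   size one), `geom_p` (success parameter of the geometric size law used
#'   otherwise). `buffer`: none.
#'
#'   Every kind except `buffer` also accepts `subject_cv`: the coefficient of
#'   variation of a mean-one lognormal per-subject multiplier on its rate
#'   parameter, emulating between-subject differences in adherence and device
#'   behaviour (real cohorts show per-subject loss spanning an order of
#'   magnitude). The default is 0 (homogeneous) for the random and
#'   time-profile kinds - a rate mixture across subjects would distort their
#'   pooled gap-size signature - and 0.6 for `mnar_device`, whose gap law is
#'   heavy-tailed regardless.
#' @return An object of class `wm_mechanism`.
#' @export
mechanism_spec <- function(kind = c("mcar_iid", "mcar_gap_process", "mar_time",
                                    "mnar_device", "buffer"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    mcar_iid = list(rate = 0.10, subject_cv = 0),
    mcar_gap_process = list(gap_start_rate = 0.017,
                            family = list(name = "zipf", a = 2), subject_cv = 0),
    mar_time = list(hour_profile = night_hour_profile(), subject_cv = 0),
    mnar_device = list(gap_start_rate = 0.02, excess_single = 0.7, geom_p = 0.5,
                       subject_cv = 0.6),
    buffer = list())
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unsupported parameter(s) for mechanism '", kind, "': ",
         paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, params)
  if (kind == "mcar_iid" && (params$rate < 0 || params$rate >= 1)) {
    stop("mcar_iid rate must be in [0, 1)")
  }
  if (kind == "mar_time") {
    if (length(params$hour_profile) != 24 ||
        any(params$hour_profile < 0 | params$hour_profile > 1)) {
      stop("hour_profile must be 24 probabilities in [0, 1]")
    }
  }
  structure(c(list(kind = kind), params), class = "wm_mechanism")
}

#' Night-elevated hourly dropout profile
#'
#' A 24-vector of dropout probabilities with an elevated rate during the
#' night hours. The default contrast (0.08 at night against 0.05 by day) is
#' deliberately moderate: under an hourly profile the pooled gap sizes are a
#' mixture of geometrics, and strong rate contrasts push that mixture
#' measurably away from a single exponential decline, which the gap-size
#' step of the framework then flags; moderate contrasts keep the MAR
#' signature where it belongs, in the time dispersion.
#'
#' @param night dropout probability during `night_hours`.
#' @param day dropout probability elsewhere.
#' @param night_hours integer clock hours counted as night.
#' @return Numeric vector of length 24 (index 1 = hour 0).
#' @export
night_hour_profile <- function(night = 0.08, day = 0.05,
                               night_hours = c(23, 0:6)) {
  profile <- rep(day, 24)
  profile[night_hours + 1L] <- night
  profile
}

#' Inject independent sample dropout
#'
#' Each of `n` grid samples is missing independently with probability `rate`,
#' the discrete-time analogue of a Poisson loss process; runs of consecutive
#' missing samples are geometrically distributed.
#'
#' @param n grid length.
#' @param rate dropout probability, `0 <= rate < 1`.
#' @param seed optional seed.
#' @return Logical mask of length `n`, `TRUE` = missing.
#' @export
inject_iid_dropout <- function(n, rate, seed = NULL) {
  stopifnot(n >= 0, rate >= 0)
  if (rate >= 1) stop("dropout rate must be < 1")
  with_seed(seed, stats::runif(n) < rate)
}

# draw gap sizes (integers >= 1) from a named discrete family
sample_gap_sizes <- function(family, n) {
  stopifnot(is.list(family), !is.null(family$name))
  if (n == 0L) return(integer())
  switch(family$name,
    deterministic = rep.int(as.integer(family$size), n),
    geometric = 1L + stats::rgeom(n, family$p),
    planck = 1L + stats::rgeom(n, 1 - exp(-family$lambda)),
    poisson = 1L + stats::rpois(n, family$mu),
    zipf = rzipf(n, family$a, cap = family$cap %||% 1e5),
    stop("unknown gap size family: ", family$name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample from a Zipf (zeta) distribution
#'
#' Inverse-CDF sampling of `P(k) ~ k^-a` on `1..cap`. The cap only serves to
#' bound the table; for `a = 2` the mass beyond the default cap is below
#' `1e-5` of the total.
#'
#' @param n number of draws.
#' @param a exponent, `> 1`.
#' @param cap support truncation for the sampling table.
#' @return Integer vector of draws.
#' @export
rzipf <- function(n, a, cap = 1e5) {
  stopifnot(a > 1, cap >= 2)
  w <- cumsum(seq_len(cap)^(-a))
  findInterval(stats::runif(n) * w[length(w)], w, left.open = TRUE) + 1L
}

#' Inject a gap process
#'
#' Gap start positions are iid with per-sample probability `gap_start_rate`;
#' each gap's length is drawn from `gap_size_family` and overlapping gaps are
#' merged (union of masks).
#'
#' @param n grid length.
#' @param gap_start_rate per-sample probability that a gap starts there.
#' @param gap_size_family list with `name` (`"geometric"`, `"planck"`,
#'   `"zipf"`, `"poisson"`, `"deterministic"`) and its parameters.
#' @param seed optional seed.
#' @param starts optional explicit start indices overriding the random draw.
#' @return Logical mask of length `n`, `TRUE` = missing.
#' @export
inject_gap_process <- function(n, gap_start_rate, gap_size_family,
                               seed = NULL, starts = NULL) {
  stopifnot(n >= 0, gap_start_rate >= 0, gap_start_rate <= 1)
  known <- c("deterministic", "geometric", "planck", "poisson", "zipf")
  if (is.null(gap_size_family$name) || !gap_size_family$name %in% known) {
    stop("unknown gap size family: ", gap_size_family$name %||% "<missing>")
  }
  with_seed(seed, {
    if (is.null(starts)) starts <- which(stats::runif(n) < gap_start_rate)
    mask <- logical(n)
    if (length(starts)) {
      sizes <- sample_gap_sizes(gap_size_family, length(starts))
      idx <- rep.int(starts, sizes) + sequence(sizes) - 1L
      idx <- idx[idx <= n]
      mask[idx] <- TRUE
    }
    mask
  })
}

#' Inject time-of-day dependent dropout
#'
#' @param times sample times: a `POSIXct` vector or integer clock hours
#'   (0-23) per sample.
#' @param hour_profile 24 dropout probabilities, index 1 = hour 00:00-01:00.
#' @param seed optional seed.
#' @return Logical mask, `TRUE` = missing.
#' @export
inject_time_dependent_dropout <- function(times, hour_profile, seed = NULL) {
  if (length(hour_profile) != 24) stop("hour_profile must have length 24")
  stopifnot(all(hour_profile >= 0 & hour_profile <= 1))
  hours <- if (inherits(times, "POSIXct")) as.POSIXlt(times)$hour else as.integer(times)
  stopifnot(all(hours >= 0 & hours <= 23))
  with_seed(seed, stats::runif(length(hours)) < hour_profile[hours + 1L])
}

#' Inject storage-buffer loss
#'
#' Under the FIFO policy (`"overwrite_oldest"`, flash CGM) a sample taken at
#' time `t` survives if and only if some synchronisation `s` satisfies
#' `s - capacity <= t <= s`: at every sync the device persists exactly the
#' last `capacity` of data and anything older was overwritten. Under
#' `"stop_when_full"` (tracker step channel) the device records from the last
#' sync `e` until its buffer fills at `e + capacity` and resumes at the next
#' sync. A terminal sync at the recording end is appended automatically.
#'
#' @param timestamps numeric sample times (any unit consistent with
#'   `buffer_capacity`), sorted.
#' @param buffer_capacity storage span, same unit as `timestamps`.
#' @param sync_times numeric synchronisation times, sorted (may be empty: the
#'   terminal sync remains).
#' @param policy `"overwrite_oldest"` or `"stop_when_full"`.
#' @return Logical mask along `timestamps`, `TRUE` = missing.
#' @export
inject_buffer_loss <- function(timestamps, buffer_capacity, sync_times = numeric(),
                               policy = c("overwrite_oldest", "stop_when_full")) {
  policy <- match.arg(policy)
  if (length(timestamps) == 0L) stop("empty timestamps")
  stopifnot(buffer_capacity > 0, !is.unsorted(timestamps), !is.unsorted(sync_times))
  syncs <- sort(unique(c(sync_times, max(timestamps))))
  if (policy == "overwrite_oldest") {
    nxt <- syncs[findInterval(timestamps, syncs, left.open = TRUE) + 1L]
    observed <- (nxt - buffer_capacity) <= timestamps
  } else {
    i <- findInterval(timestamps, syncs)
    last <- ifelse(i == 0L, timestamps[1L], syncs[pmax(i, 1L)])
    observed <- timestamps <= last + buffer_capacity
  }
  !observed
}

#' Simulate subject-initiated scan times
#'
#' Scans form a Poisson stream at `scan_rate` per waking hour, restricted to
#' the waking intervals implied by the sleep schedule; no scan happens while
#' the subject sleeps.
#'
#' @param sleep a [sleep_model()] (a schedule is simulated) or a schedule
#'   data frame as returned by [simulate_sleep_schedule()].
#' @param scan_rate mean scans per waking hour, `>= 0`.
#' @param days recording length in days.
#' @param seed optional seed.
#' @return Sorted numeric vector of scan times in hours from recording start.
#' @export
simulate_scan_times <- function(sleep, scan_rate, days, seed = NULL) {
  stopifnot(scan_rate >= 0, days >= 1)
  with_seed(seed, {
    sched <- if (inherits(sleep, "wm_sleep")) {
      simulate_sleep_schedule(sleep, days)
    } else sleep
    stopifnot(is.data.frame(sched), all(c("onset_h", "wake_h") %in% names(sched)))
    end_h <- days * 24
    bounds <- sort(unique(pmin(pmax(c(0, rbind(sched$onset_h, sched$wake_h), end_h), 0), end_h)))
    times <- numeric()
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i]; b <- bounds[i + 1L]
      if (b <= a) next
      mid <- (a + b) / 2
      asleep <- any(sched$onset_h <= mid & mid < sched$wake_h)
      if (!asleep) {
        k <- stats::rpois(1L, scan_rate * (b - a))
        if (k > 0L) times <- c(times, stats::runif(k, a, b))
      }
    }
    sort(times)
  })
}

# ---- signal generators (phenomenological, not physiological) -----------------

sim_glucose_values <- function(n, dt_min = 15) {
  mu <- stats::runif(1, 6, 9)
  theta <- 0.02                      # per-minute mean reversion
  sigma <- 0.25                      # mmol/L per sqrt(min)
  x <- numeric(n)
  x[1] <- mu + stats::rnorm(1, 0, 1)
  a <- exp(-theta * dt_min)
  s <- sigma * sqrt((1 - a^2) / (2 * theta))
  innov <- stats::rnorm(n, 0, s)
  for (i in seq_len(n - 1L)) x[i + 1L] <- mu + a * (x[i] - mu) + innov[i]
  round(pmin(pmax(x, 3.9), 13.5), 1)
}

sim_hr_values <- function(clock_min, asleep) {
  base <- stats::runif(1, 58, 74)
  circ <- 7 * sin(2 * pi * (clock_min / 1440 - 0.25))
  hr <- base + circ - 8 * asleep + stats::rnorm(length(clock_min), 0, 3)
  pmax(40, pmin(150, round(hr)))
}

sim_steps_values <- function(clock_hour, asleep, day_window = c(8, 22)) {
  p <- ifelse(asleep, 0,
              ifelse(clock_hour >= day_window[1] & clock_hour < day_window[2],
                     0.12, 0.08))
  active <- stats::runif(length(p)) < p
  steps <- integer(length(p))
  steps[active] <- stats::rpois(sum(active), 70) + 1L
  steps
}

sample_descriptives <- function(n_subjects) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    gender = ifelse(stats::runif(n_subjects) < 0.60, "male", "female"),
    age_years = round(pmin(pmax(stats::rnorm(n_subjects, 63.5, 9), 35), 88)),
    bmi = round(pmin(pmax(stats::rnorm(n_subjects, 32.8, 4.8), 19), 48), 1),
    hba1c_mmol_mol = round(pmin(pmax(stats::rnorm(n_subjects, 58, 8), 38), 95)),
    years_since_diagnosis = round(pmin(stats::rgamma(n_subjects, shape = 2.2, scale = 6.4), 40), 1),
    med_oral = as.integer(stats::runif(n_subjects) < 0.90),
    med_insulin = as.integer(stats::runif(n_subjects) < 0.56),
    med_other = as.integer(stats::runif(n_subjects) < 0.39),
    stringsAsFactors = FALSE
  )
}

# ---- cohort assembly ---------------------------------------------------------

#' Simulate a wearable-sensor cohort with known missingness
#'
#' Generates a cohort of two-week-style recordings: glucose sampled at a
#' jittered ~15-min interval, heart rate and steps at one sample per minute
#' with device-convention zero coding of absent measurements, per-subject
#' sleep schedules, and descriptive covariates in ranges typical of a type 2
#' diabetes cohort. Missingness is injected per modality according to
#' `mechanisms` and recorded in a ground-truth table.
#'
#' Minutes where heart rate is missing also record zero steps (a wrist device
#' that is not measuring measures neither channel), so step missingness
#' partially inherits heart-rate missingness, as the downstream definition
#' rules expect.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param days recording length, days.
#' @param modalities subset of `c("glucose", "hr", "steps")` to simulate.
#' @param mechanisms named list (by modality) of [mechanism_spec()] objects or
#'   `NULL` for no injected loss.
#' @param devices named list with elements `cgm` and `tracker`
#'   ([device_model()]); used by `"buffer"` mechanisms.
#' @param sleep a [sleep_model()].
#' @param start recording start (`POSIXct` or parseable string); defaults to
#'   a Thursday midnight.
#' @param glucose_jitter_sd per-sample jitter (minutes) of the CGM sampling
#'   times around the nominal 15-min grid, truncated at 1.9 min.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `wm_cohort`: list with `raw` (long data frame
#'   `subject_id`, `modality`, `timestamp`, `value`), `ground_truth` (long
#'   data frame with `injected_missing` 0/1 and `mechanism_label`),
#'   `descriptives`, `schedules` (per-subject sleep schedules), and `meta`.
#' @export
simulate_cohort <- function(n_subjects, days = 14,
                            modalities = c("glucose", "hr", "steps"),
                            mechanisms = list(),
                            devices = list(cgm = device_model("cgm"),
                                           tracker = device_model("tracker")),
                            sleep = sleep_model(),
                            start = "2019-03-07 00:00:00",
                            glucose_jitter_sd = 1,
                            seed = 1) {
  stopifnot(n_subjects >= 1, days >= 1)
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  for (m in names(mechanisms)) {
    if (!is.null(mechanisms[[m]]) && !inherits(mechanisms[[m]], "wm_mechanism")) {
      stop("mechanisms$", m, " is not a wm_mechanism")
    }
  }
  start <- if (inherits(start, "POSIXct")) start else parse_timestamps(start)
  set.seed(seed)
  descr <- sample_descriptives(n_subjects)

  n_min <- as.integer(days * 1440)
  minute_t <- seq_len(n_min) - 1L
  clock_min <- minute_t %% 1440L
  clock_hour <- clock_min %/% 60L
  n_glu <- as.integer(days * 1440 / 15)
  glu_nominal <- (seq_len(n_glu) - 1L) * 15
  start_num <- as.numeric(start)

  # accumulate plain vectors; a single data frame is assembled at the end
  raw_acc <- list(sid = list(), mod = list(), t = list(), val = list())
  gt_acc <- list(sid = list(), mod = list(), t = list(), inj = list(), lab = list())
  push_raw <- function(sid, mod, t_num, val) {
    i <- length(raw_acc$sid) + 1L
    raw_acc$sid[[i]] <<- rep.int(sid, length(t_num))
    raw_acc$mod[[i]] <<- rep.int(mod, length(t_num))
    raw_acc$t[[i]] <<- t_num
    raw_acc$val[[i]] <<- as.numeric(val)
  }
  push_gt <- function(sid, mod, t_num, inj, lab) {
    i <- length(gt_acc$sid) + 1L
    gt_acc$sid[[i]] <<- rep.int(sid, length(t_num))
    gt_acc$mod[[i]] <<- rep.int(mod, length(t_num))
    gt_acc$t[[i]] <<- t_num
    gt_acc$inj[[i]] <<- as.integer(inj)
    gt_acc$lab[[i]] <<- rep.int(lab, length(t_num))
  }
  sched_list <- vector("list", n_subjects)

  for (s in seq_len(n_subjects)) {
    sid <- descr$subject_id[s]
    sched <- simulate_sleep_schedule(sleep, days)
    sched_list[[s]] <- sched
    asleep_min <- logical(n_min)
    for (k in seq_len(nrow(sched))) {
      a <- max(0, sched$onset_h[k] * 60); b <- min(n_min, sched$wake_h[k] * 60)
      if (b > a) asleep_min[(floor(a) + 1L):ceiling(b)] <- TRUE
    }

    hr_missing <- NULL
    if ("hr" %in% modalities || "steps" %in% modalities) {
      hr_missing <- realize_mechanism(mechanisms[["hr"]], n = n_min,
                                      hours = clock_hour, times_h = minute_t / 60,
                                      device = devices$tracker, sched = sched,
                                      days = days)
      hr_val <- sim_hr_values(clock_min, asleep_min)
      hr_val[hr_missing] <- 0
      if ("hr" %in% modalities) {
        push_raw(sid, "hr", start_num + minute_t * 60, hr_val)
        push_gt(sid, "hr", start_num + minute_t * 60, hr_missing,
                mech_label(mechanisms[["hr"]]))
      }
    }

    if ("steps" %in% modalities) {
      st_mech <- realize_mechanism(mechanisms[["steps"]], n = n_min,
                                   hours = clock_hour, times_h = minute_t / 60,
                                   device = devices$tracker, sched = sched,
                                   days = days)
      st_val <- sim_steps_values(clock_hour, asleep_min)
      st_missing <- st_mech | hr_missing
      st_val[st_missing] <- 0L
      push_raw(sid, "steps", start_num + minute_t * 60, st_val)
      push_gt(sid, "steps", start_num + minute_t * 60, st_missing,
              mech_label(mechanisms[["steps"]]))
    }

    if ("glucose" %in% modalities) {
      jit <- pmin(pmax(stats::rnorm(n_glu, 0, glucose_jitter_sd), -1.9), 1.9)
      jit[1] <- 0
      t_raw <- glu_nominal + jit
      val <- sim_glucose_values(n_glu)
      glu_missing <- realize_mechanism(mechanisms[["glucose"]], n = n_glu,
                                       hours = (glu_nominal %/% 60) %% 24L,
                                       times_h = t_raw / 60,
                                       device = devices$cgm, sched = sched,
                                       days = days)
      keep <- !glu_missing
      push_raw(sid, "glucose", start_num + t_raw[keep] * 60, val[keep])
      push_gt(sid, "glucose", start_num + glu_nominal * 60, glu_missing,
              mech_label(mechanisms[["glucose"]]))
    }
  }

  as_posix <- function(t) as.POSIXct(t, tz = "UTC", origin = "1970-01-01")
  raw <- data.frame(subject_id = unlist(raw_acc$sid), modality = unlist(raw_acc$mod),
                    timestamp = as_posix(unlist(raw_acc$t)),
                    value = unlist(raw_acc$val), stringsAsFactors = FALSE)
  gt <- data.frame(subject_id = unlist(gt_acc$sid), modality = unlist(gt_acc$mod),
                   timestamp = as_posix(unlist(gt_acc$t)),
                   injected_missing = unlist(gt_acc$inj),
                   mechanism_label = unlist(gt_acc$lab), stringsAsFactors = FALSE)
  names(sched_list) <- descr$subject_id
  structure(list(raw = raw, ground_truth = gt, descriptives = descr,
                 schedules = sched_list,
                 meta = list(n_subjects = n_subjects, days = days,
                             modalities = modalities, start = start,
                             seed = seed)),
            class = "wm_cohort")
}

mech_label <- function(mech) if (is.null(mech)) "none" else mech$kind

# realize one mechanism as a missing mask over a sampling grid
realize_mechanism <- function(mech, n, hours, times_h, device, sched, days) {
  if (is.null(mech)) return(logical(n))
  cv <- mech$subject_cv %||% 0
  frailty <- if (cv > 0) {
    s2 <- log(1 + cv^2)
    stats::rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else 1
  switch(mech$kind,
    mcar_iid = inject_iid_dropout(n, min(mech$rate * frailty, 0.95)),
    mcar_gap_process = inject_gap_process(n, min(mech$gap_start_rate * frailty, 1),
                                          mech$family),
    mar_time = inject_time_dependent_dropout(hours,
                                             pmin(mech$hour_profile * frailty, 0.95)),
    mnar_device = {
      starts <- which(stats::runif(n) < min(mech$gap_start_rate * frailty, 1))
      sizes <- ifelse(stats::runif(length(starts)) < mech$excess_single, 1L,
                      1L + stats::rgeom(length(starts), mech$geom_p))
      mask <- logical(n)
      if (length(starts)) {
        idx <- rep.int(starts, sizes) + sequence(sizes) - 1L
        mask[idx[idx <= n]] <- TRUE
      }
      mask
    },
    buffer = {
      syncs <- if (device$sync_policy == "scan_events") {
        simulate_scan_times(sched, device$scan_rate, days)
      } else {
        (device$visit_days - 1) * 24 + device$visit_hour
      }
      inject_buffer_loss(times_h, device$buffer_capacity_hours, syncs,
                         policy = device$overflow_policy)
    },
    stop("unsupported mechanism kind: ", mech$kind)
  )
}

#' Default study-like mechanism set
#'
#' The mechanism combination that emulates the observed study conditions:
#' glucose lost through the 8-h CGM FIFO buffer synchronised by waking scans,
#' heart rate lost through short device errors with an excess of
#' single-sample gaps, and steps lost through the ~6-day tracker buffer
#' synchronised at the day-7 visit (plus inheriting heart-rate loss).
#'
#' @return Named list of [mechanism_spec()] objects.
#' @export
study_mechanisms <- function() {
  list(glucose = mechanism_spec("buffer"),
       hr = mechanism_spec("mnar_device"),
       steps = mechanism_spec("buffer"))
}

#' Write cohort files
#'
#' Writes `raw.csv`, `ground_truth.csv` and `descriptives.csv` to a
#' directory, the same schemas [read_raw_series()] and [read_descriptives()]
#' read back.
#'
#' @param cohort a `wm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- cohort$raw
  raw$timestamp <- format_timestamps(raw$timestamp)
  utils::write.csv(raw, file.path(dir, "raw.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  gt$timestamp <- format_timestamps(gt$timestamp)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  invisible(dir)
}
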