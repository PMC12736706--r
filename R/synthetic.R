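#' Condition presets for synthetic PPG cohorts
#'
#' A condition bundles the acquisition-environment parameters of a synthetic
#' recording: motion-artifact burst rate and gain, extra sensor noise, and a
#' multiplier on day-to-day physiological drift. The `laboratory` preset is
#' artifact-free; `real_world` adds artifact bursts (2/min), transient
#' baseline steps, extra noise and 3x drift, emulating naturalistic
#' wrist-worn recordings.
#'
#' @param label `"laboratory"` or `"real_world"`.
#' @return An object of class `ppg_condition`.
#' @examples
#' condition_preset("laboratory")
#' @export
condition_preset <- function(label = c("laboratory", "real_world")) {
  label <- match.arg(label)
  cond <- switch(label,
    laboratory = list(label = "laboratory", artifact_rate = 0, artifact_gain = 1,
                      extra_noise_sd = 0, drift_multiplier = 1),
    real_world = list(label = "real_world", artifact_rate = 2, artifact_gain = 3,
                      extra_noise_sd = 0.08, drift_multiplier = 3)
  )
  structure(cond, class = "ppg_condition")
}

as_condition <- function(condition) {
  if (inherits(condition, "ppg_condition")) return(condition)
  if (is.character(condition) && length(condition) == 1L) {
    return(condition_preset(condition))
  }
  stop("`condition` must be a ppg_condition or a preset label")
}

# Morphology parameters subject to day-to-day log-normal drift.
.drift_fields <- c("hr_mean", "sys_amp", "sys_width", "dicrotic_amp",
                   "dicrotic_delay", "resp_am_depth", "resp_bw_amp")

#' Default population parameter ranges for synthetic users
#'
#' Uniform sampling ranges for each user-profile parameter. Heart rate spans
#' typical resting adult values; the pulse morphology ranges (systolic
#' amplitude/width, dicrotic amplitude/delay) give users distinct but
#' physiologically plausible beat shapes; respiratory rate covers
#' 0.15-0.35 Hz (9-21 breaths/min).
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_population_spec <- function() {
  list(
    hr_mean        = c(55, 85),     # beats/min
    hr_sd          = c(0.5, 3),     # beats/min, beat-to-beat variability
    resp_rate      = c(0.15, 0.35), # Hz
    sys_amp        = c(0.8, 1.2),   # a.u.
    sys_width      = c(0.08, 0.16), # s
    dicrotic_amp   = c(0.1, 0.5),   # fraction of systolic amplitude
    dicrotic_delay = c(0.25, 0.45), # fraction of cycle after systolic peak
    resp_am_depth  = c(0.05, 0.20),
    resp_bw_amp    = c(0.05, 0.25),
    noise_sd       = c(0.01, 0.05),
    drift_sd       = c(0.02, 0.08)  # per-day log-scale morphology drift
  )
}

#' Homogeneous population parameter ranges
#'
#' Narrow sampling ranges emulating a demographically homogeneous cohort
#' (e.g. same-age university students): users share similar heart rates and
#' pulse morphology, so their PPG signatures crowd together and each
#' additional enrolled user makes identification genuinely harder. Use with
#' [synthesize_cohort()] for user-scaling and unseen-user protocols.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
homogeneous_population_spec <- function() {
  list(
    hr_mean        = c(62, 78),
    hr_sd          = c(1, 3),
    resp_rate      = c(0.2, 0.3),
    sys_amp        = c(0.95, 1.05),
    sys_width      = c(0.10, 0.13),
    dicrotic_amp   = c(0.25, 0.40),
    dicrotic_delay = c(0.32, 0.40),
    resp_am_depth  = c(0.08, 0.15),
    resp_bw_amp    = c(0.10, 0.20),
    noise_sd       = c(0.03, 0.05),
    drift_sd       = c(0.04, 0.08)
  )
}

validate_profile <- function(p) {
  req <- c(.drift_fields, "hr_sd", "resp_rate", "noise_sd", "drift_sd", "user_id")
  missing <- setdiff(req, names(p))
  if (length(missing)) stop("profile missing fields: ", paste(missing, collapse = ", "))
  if (p$hr_mean < 40 || p$hr_mean > 180) stop("hr_mean must be in [40, 180]")
  if (p$hr_sd < 0) stop("hr_sd must be >= 0")
  if (p$resp_rate < 0.1 || p$resp_rate > 0.5) stop("resp_rate must be in [0.1, 0.5]")
  if (p$sys_amp <= 0) stop("sys_amp must be > 0")
  if (p$dicrotic_amp < 0) stop("dicrotic_amp must be >= 0")
  if (p$dicrotic_delay <= 0 || p$dicrotic_delay >= 1) stop("dicrotic_delay must be in (0, 1)")
  for (f in c("resp_am_depth", "resp_bw_amp", "noise_sd", "drift_sd")) {
    if (p[[f]] < 0) stop(f, " must be >= 0")
  }
  invisible(p)
}

#' Sample a synthetic user profile
#'
#' Draws each waveform-morphology parameter uniformly from its population
#' range. A fixed seed always reproduces the same profile; distinct seeds
#' give distinct morphologies almost surely.
#'
#' @param seed Integer seed.
#' @param population_spec Named list of `c(min, max)` ranges, as returned by
#'   [default_population_spec()].
#' @param user_id Identifier attached to the profile (default `"U<seed>"`).
#' @return An object of class `ppg_profile`.
#' @examples
#' p <- sample_user_profile(seed = 1)
#' p$hr_mean
#' @export
sample_user_profile <- function(seed, population_spec = default_population_spec(),
                                user_id = sprintf("U%d", seed)) {
  spec <- utils::modifyList(default_population_spec(), population_spec)
  for (f in names(spec)) {
    r <- spec[[f]]
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2]) {
      stop(sprintf("invalid range for `%s` (need min <= max)", f))
    }
  }
  prof <- with_seed(seed, {
    vals <- lapply(spec, function(r) stats::runif(1, r[1], r[2]))
    c(list(user_id = user_id), vals)
  })
  structure(validate_profile(prof), class = "ppg_profile")
}

#' Apply day-to-day physiological drift to a profile
#'
#' Day 0 is the enrollment day and returns the profile unchanged. For later
#' days every morphology parameter (heart rate, pulse amplitude/width,
#' dicrotic amplitude/delay, respiratory modulation depths) is multiplied by
#' an independent log-normal factor with log-sd
#' `drift_sd * condition$drift_multiplier`, modelling varying daily
#' physiological state. Identity fields (user id, noise level, drift rate)
#' are untouched.
#'
#' @param profile A `ppg_profile`.
#' @param day_index Nonnegative integer day.
#' @param condition Condition preset or label.
#' @param seed Integer seed.
#' @return A drifted `ppg_profile`.
#' @export
apply_day_drift <- function(profile, day_index, condition = "laboratory", seed = 1) {
  stopifnot(inherits(profile, "ppg_profile"))
  if (!is.numeric(day_index) || length(day_index) != 1L || day_index < 0 ||
      day_index != round(day_index)) {
    stop("`day_index` must be a nonnegative integer")
  }
  condition <- as_condition(condition)
  log_sd <- profile$drift_sd * condition$drift_multiplier
  if (day_index == 0 || log_sd == 0) return(profile)
  out <- with_seed(seed, {
    p <- profile
    factors <- exp(stats::rnorm(length(.drift_fields), 0, log_sd))
    for (i in seq_along(.drift_fields)) {
      f <- .drift_fields[i]
      p[[f]] <- p[[f]] * factors[i]
    }
    # keep drifted values inside the physiological domain
    p$hr_mean <- min(max(p$hr_mean, 40), 180)
    p$dicrotic_delay <- min(max(p$dicrotic_delay, 0.05), 0.95)
    p
  })
  structure(validate_profile(out), class = "ppg_profile")
}

#' Synthesise one PPG session
#'
#' Waveform model: a train of beats with lengths drawn from
#' `hr_mean`/`hr_sd` (Gaussian jitter truncated at +/-3 sd), each beat a
#' systolic Gaussian plus a delayed, wider dicrotic Gaussian; respiratory
#' amplitude modulation and additive baseline wander at `resp_rate`; white
#' sensor noise. Under a real-world condition, artifact bursts (0.5-2 s
#' segments scaled by `artifact_gain` plus transient baseline steps) are
#' injected at `artifact_rate` events/min.
#'
#' True beat times are attached as attribute `beat_times` for use as ground
#' truth when validating peak detectors.
#'
#' @param profile A `ppg_profile`.
#' @param duration_s Session length, seconds.
#' @param fs Sampling rate, Hz (must be >= 25 to resolve the dicrotic wave).
#' @param condition Condition preset or label.
#' @param day_index Day of recording (metadata only; apply drift beforehand
#'   via [apply_day_drift()] or use [synthesize_cohort()]).
#' @param seed Integer seed.
#' @return A [ppg_record()].
#' @examples
#' p <- sample_user_profile(1)
#' rec <- synthesize_session(p, duration_s = 30, fs = 50, seed = 2)
#' length(rec$samples) # 1500
#' @export
synthesize_session <- function(profile, duration_s, fs, condition = "laboratory",
                               day_index = 0, seed = 1) {
  stopifnot(inherits(profile, "ppg_profile"))
  stopifnot_scalar_num(duration_s, "duration_s", lo = 1e-9)
  stopifnot_scalar_num(fs, "fs")
  if (fs < 25) stop("fs < 25 Hz cannot resolve the dicrotic component")
  if (duration_s * profile$hr_mean / 60 < 2) {
    stop("duration_s too short: need at least 2 beats at hr_mean")
  }
  condition <- as_condition(condition)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  rec <- with_seed(seed, {
    period_mean <- 60 / profile$hr_mean
    period_sd <- 60 * profile$hr_sd / profile$hr_mean^2
    n_beats <- ceiling(duration_s / period_mean) + 4L
    jitter <- stats::rnorm(n_beats)
    jitter <- pmin(pmax(jitter, -3), 3)
    periods <- pmax(period_mean + period_sd * jitter, 60 / 180)
    beat_times <- period_mean / 2 + cumsum(c(0, periods[-n_beats]))
    keep <- beat_times < duration_s + 2 * period_mean
    beat_times <- beat_times[keep]
    periods <- periods[keep]

    pulse <- numeric(n)
    w <- profile$sys_width
    w_dic <- 1.6 * w
    for (i in seq_along(beat_times)) {
      tb <- beat_times[i]
      td <- tb + profile$dicrotic_delay * periods[i]
      lo <- max(1L, floor((tb - 4 * w) * fs) + 1L)
      hi <- min(n, ceiling((td + 4 * w_dic) * fs) + 1L)
      if (lo > n || hi < 1L) next
      idx <- lo:hi
      tt <- t[idx]
      pulse[idx] <- pulse[idx] +
        profile$sys_amp * exp(-(tt - tb)^2 / (2 * w^2)) +
        profile$dicrotic_amp * profile$sys_amp * exp(-(tt - td)^2 / (2 * w_dic^2))
    }

    phase <- stats::runif(2, 0, 2 * pi)
    am <- 1 + profile$resp_am_depth * sin(2 * pi * profile$resp_rate * t + phase[1])
    bw <- profile$resp_bw_amp * sin(2 * pi * profile$resp_rate * t + phase[2])
    noise_sd <- profile$noise_sd + condition$extra_noise_sd
    x <- pulse * am + bw + stats::rnorm(n, 0, noise_sd)

    if (condition$artifact_rate > 0) {
      n_events <- stats::rpois(1, condition$artifact_rate * duration_s / 60)
      if (n_events > 0) {
        starts <- stats::runif(n_events, 0, duration_s)
        lens <- stats::runif(n_events, 0.5, 2)
        steps <- stats::runif(n_events, -1, 1) * condition$artifact_gain * 0.3
        for (e in seq_len(n_events)) {
          i0 <- max(1L, round(starts[e] * fs))
          i1 <- min(n, round((starts[e] + lens[e]) * fs))
          if (i1 >= i0) {
            seg <- i0:i1
            x[seg] <- x[seg] * condition$artifact_gain + steps[e]
          }
        }
      }
    }
    list(x = x, beat_times = beat_times[beat_times >= 0 & beat_times < duration_s])
  })

  out <- ppg_record(rec$x, fs = fs, user_id = profile$user_id,
                    session_id = sprintf("%s_d%02d", profile$user_id, day_index),
                    day_index = day_index, condition = condition$label)
  attr(out, "beat_times") <- rec$beat_times
  out
}

#' Synthesise a multi-user, multi-day PPG cohort
#'
#' One session per (user, day). Each user's base morphology is sampled once;
#' for day > 0 the profile is drifted via [apply_day_drift()] before
#' synthesis, so identity is stable but daily presentation varies.
#'
#' @param n_users Number of users (>= 2; a recognition task needs at least
#'   two identities).
#' @param n_days Number of recording days (>= 1).
#' @param session_s Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param condition Condition preset or label applied to every session.
#' @param seed Master seed; all per-user and per-day randomness derives
#'   from it, so a fixed seed regenerates the cohort exactly.
#' @param population_spec Parameter ranges for [sample_user_profile()].
#' @return An object of class `ppg_cohort`: a list of [ppg_record()]s with
#'   the generating parameters attached as attributes.
#' @examples
#' coh <- synthesize_cohort(n_users = 2, n_days = 1, session_s = 30, fs = 50, seed = 1)
#' length(coh) # 2
#' @export
synthesize_cohort <- function(n_users, n_days = 1, session_s = 480, fs = 125,
                              condition = "laboratory", seed = 1,
                              population_spec = default_population_spec()) {
  if (n_users < 2) stop("n_users must be >= 2 (no recognition task exists for one user)")
  if (n_days < 1) stop("n_days must be >= 1")
  condition <- as_condition(condition)
  seeds <- matrix(derive_seeds(seed, n_users * (2 * n_days + 1)),
                  nrow = n_users)
  records <- vector("list", n_users * n_days)
  k <- 0L
  for (u in seq_len(n_users)) {
    prof <- sample_user_profile(seeds[u, 1], population_spec,
                                user_id = sprintf("U%02d", u))
    for (d in seq_len(n_days)) {
      day <- d - 1L
      dprof <- apply_day_drift(prof, day, condition, seed = seeds[u, 1 + d])
      k <- k + 1L
      records[[k]] <- synthesize_session(dprof, session_s, fs, condition,
                                         day_index = day,
                                         seed = seeds[u, 1 + n_days + d])
    }
  }
  structure(records, class = "ppg_cohort",
            n_users = n_users, n_days = n_days, fs = fs,
            condition = condition$label, seed = seed)
}

#' Write a cohort to disk as plain-text CSV sessions plus a manifest
#'
#' One `time_s,ppg` CSV per session and a `manifest.csv` listing
#' `user_id, day_index, file, condition, fs, session_id`.
#'
#' @param cohort A `ppg_cohort` (or list of [ppg_record()]s).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(r) {
    file <- sprintf("%s.csv", r$session_id)
    df <- data.frame(time_s = (seq_along(r$samples) - 1) / r$fs, ppg = r$samples)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    data.frame(user_id = r$user_id, day_index = r$day_index, file = file,
               condition = r$condition, fs = r$fs, session_id = r$session_id,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and per-session CSVs.
#' @return A `ppg_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    read_session_csv(file.path(dir, m$file), fs = m$fs,
                     metadata = list(user_id = m$user_id, session_id = m$session_id,
                                     day_index = m$day_index, condition = m$condition))
  })
  structure(records, class = "ppg_cohort",
            n_users = length(unique(manifest$user_id)),
            n_days = length(unique(manifest$day_index)),
            fs = manifest$fs[1], condition = manifest$condition[1], seed = NA)
}
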