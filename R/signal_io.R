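#' Construct a PPG session record
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), all finite.
#' @param fs Sampling rate, Hz.
#' @param user_id,session_id,day_index,condition Provenance metadata.
#' @return Object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, user_id = NA_character_,
                       session_id = NA_character_, day_index = 0L,
                       condition = NA_character_) {
  stopifnot_scalar_num(fs, "fs", lo = 1e-12)
  if (length(samples) < 1L) stop("record must contain at least one sample")
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("all samples must be finite numbers")
  }
  structure(list(samples = as.numeric(samples), fs = fs, user_id = user_id,
                 session_id = session_id, day_index = as.integer(day_index),
                 condition = condition),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s (%s, day %d): %.1f s at %g Hz\n",
              x$user_id, x$condition, x$day_index,
              length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Construct a fixed-duration PPG window
#'
#' Windows of 40 s (identification) and 6 s (re-identification) are the two
#' standard durations; other durations are valid but flagged via the
#' `standard_duration` field.
#'
#' @param samples Numeric samples.
#' @param fs Sampling rate, Hz.
#' @param user_id,session_id,day_index Provenance.
#' @param start_s Offset of the window within its session, seconds.
#' @return Object of class `ppg_window`.
#' @export
ppg_window <- function(samples, fs, user_id = NA_character_,
                       session_id = NA_character_, day_index = 0L,
                       start_s = 0) {
  stopifnot_scalar_num(fs, "fs", lo = 1e-12)
  if (!is.numeric(samples) || length(samples) < 1L) stop("empty window")
  duration_s <- length(samples) / fs
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = duration_s, user_id = user_id,
                 session_id = session_id, day_index = as.integer(day_index),
                 start_s = start_s,
                 standard_duration = isTRUE(abs(duration_s - 40) < 1 / fs) ||
                   isTRUE(abs(duration_s - 6) < 1 / fs)),
            class = "ppg_window")
}

#' Read one PPG session from CSV
#'
#' Accepts either a single numeric column (with or without header) or a file
#' containing a `ppg` column (e.g. as written by [write_cohort()]).
#'
#' @param path File path.
#' @param fs Sampling rate, Hz.
#' @param metadata Named list merged into the record (`user_id`,
#'   `session_id`, `day_index`, `condition`).
#' @return A [ppg_record()].
#' @export
read_session_csv <- function(path, fs, metadata = list()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- any(grepl("[A-Za-z]", strsplit(first, ",")[[1]]))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (nrow(df) == 0) stop("no data rows in ", path)
  col <- if ("ppg" %in% names(df)) df$ppg else if (ncol(df) == 1L) df[[1]] else
    stop("cannot locate a sample column in ", path,
         " (need a single column or one named 'ppg')")
  vals <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric sample at data row %d of %s", bad[1], path))
  }
  ppg_record(vals, fs = fs,
             user_id = metadata$user_id %||% NA_character_,
             session_id = metadata$session_id %||% basename(path),
             day_index = metadata$day_index %||% 0L,
             condition = metadata$condition %||% NA_character_)
}

#' Resample a session to a new rate
#'
#' Polyphase anti-aliased resampling (via [signal::resample()]) at the
#' rational approximation of `target_fs / fs`; duration is preserved to
#' within one output sample and in-band spectral content is unchanged.
#'
#' @param record A [ppg_record()].
#' @param target_fs Target rate, Hz.
#' @return A resampled [ppg_record()].
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "ppg_record"))
  stopifnot_scalar_num(target_fs, "target_fs", lo = 1e-12)
  if (isTRUE(all.equal(target_fs, record$fs))) return(record)
  frac <- rational_approx(target_fs / record$fs)
  y <- signal::resample(record$samples, frac[1], frac[2])
  n_out <- round(length(record$samples) * target_fs / record$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  out <- record
  out$samples <- as.numeric(y)
  out$fs <- target_fs
  out
}

# best rational p/q approximation with bounded denominator (continued fractions)
rational_approx <- function(x, max_den = 4096L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Trim session edges
#'
#' Discards the first and last `trim_s` seconds of a session (default
#' 5 min), keeping only the stable interior of a recording -- e.g. avoiding
#' the noise of putting on or removing a device.
#'
#' @param record A [ppg_record()].
#' @param trim_s Seconds trimmed from each end.
#' @return The interior [ppg_record()]; errors if the session is not longer
#'   than `2 * trim_s` rather than returning an empty record.
#' @export
trim_session <- function(record, trim_s = 300) {
  stopifnot(inherits(record, "ppg_record"))
  stopifnot_scalar_num(trim_s, "trim_s", lo = 0)
  n <- length(record$samples)
  dur <- n / record$fs
  if (dur <= 2 * trim_s) {
    stop(sprintf("session of %.1f s is unusable with trim_s = %g (needs > %g s)",
                 dur, trim_s, 2 * trim_s))
  }
  k <- round(trim_s * record$fs)
  out <- record
  out$samples <- record$samples[(k + 1):(n - k)]
  attr(out, "start_offset_s") <- (attr(record, "start_offset_s") %||% 0) + k / record$fs
  out
}

#' Extract the central segment of a session
#'
#' Returns the `middle_s`-second segment centred within the session
#' (the whole session if it is shorter).
#'
#' @param record A [ppg_record()].
#' @param middle_s Segment length, seconds.
#' @return A [ppg_record()].
#' @export
middle_segment <- function(record, middle_s) {
  stopifnot(inherits(record, "ppg_record"))
  n <- length(record$samples)
  m <- round(middle_s * record$fs)
  if (m >= n) return(record)
  i0 <- floor((n - m) / 2)
  out <- record
  out$samples <- record$samples[(i0 + 1):(i0 + m)]
  attr(out, "start_offset_s") <- (attr(record, "start_offset_s") %||% 0) + i0 / record$fs
  out
}

#' Segment a session into fixed-duration windows
#'
#' Tiles the session with half-open windows `[start, start + window_s)`.
#' With `overlap_s = 0` the tiling is exact and non-overlapping; a trailing
#' remainder shorter than `window_s` is discarded (a 480 s session yields
#' exactly 12 windows of 40 s). Windows inherit the session's metadata.
#'
#' @param record A [ppg_record()].
#' @param window_s Window duration, seconds.
#' @param overlap_s Overlap between consecutive windows (0 <= overlap_s <
#'   window_s).
#' @return List of [ppg_window()]s (empty if the session is shorter than one
#'   window).
#' @export
segment_record <- function(record, window_s, overlap_s = 0) {
  stopifnot(inherits(record, "ppg_record"))
  stopifnot_scalar_num(window_s, "window_s", lo = 1e-12)
  if (overlap_s < 0 || overlap_s >= window_s) {
    stop("need 0 <= overlap_s < window_s")
  }
  fs <- record$fs
  wlen <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  n <- length(record$samples)
  if (n < wlen) return(list())
  starts <- seq.int(0L, n - wlen, by = hop)
  base_off <- attr(record, "start_offset_s") %||% 0
  lapply(starts, function(s0) {
    ppg_window(record$samples[(s0 + 1):(s0 + wlen)], fs = fs,
               user_id = record$user_id, session_id = record$session_id,
               day_index = record$day_index, start_s = base_off + s0 / fs)
  })
}

#' Metadata table for a list of windows
#'
#' @param windows List of [ppg_window()]s.
#' @return data.frame with `user_id`, `session_id`, `day_index`, `start_s`,
#'   `duration_s`, one row per window.
#' @export
window_meta <- function(windows) {
  do.call(rbind, lapply(windows, function(w) {
    data.frame(user_id = w$user_id, session_id = w$session_id,
               day_index = w$day_index, start_s = w$start_s,
               duration_s = w$duration_s, stringsAsFactors = FALSE)
  }))
}

#' Subsample a fixed number of windows per user
#'
#' Draws exactly `n_per_user` windows for every user. With
#' `even_across_days`, the draw is balanced over that user's recording days
#' (per-day counts differ by at most one) -- e.g. 24 windows over 12 days
#' selects 2 per day. Selection is random but reproducible for a fixed seed.
#'
#' @param windows List of [ppg_window()]s.
#' @param n_per_user Windows to keep per user.
#' @param even_across_days Balance the draw across days.
#' @param seed Integer seed.
#' @return List of selected windows.
#' @export
subsample_per_user <- function(windows, n_per_user, even_across_days = FALSE,
                               seed = 1) {
  meta <- window_meta(windows)
  users <- unique(meta$user_id)
  with_seed(seed, {
    keep <- integer(0)
    for (u in users) {
      iu <- which(meta$user_id == u)
      if (length(iu) < n_per_user) {
        stop(sprintf("user %s has only %d windows (< %d requested)",
                     u, length(iu), n_per_user))
      }
      if (!even_across_days) {
        keep <- c(keep, sample_exact(iu, n_per_user))
      } else {
        days <- sort(unique(meta$day_index[iu]))
        nd <- length(days)
        base <- n_per_user %/% nd
        extra <- n_per_user %% nd
        bonus_days <- if (extra > 0) sample_exact(days, extra) else integer(0)
        for (d in days) {
          quota <- base + as.integer(d %in% bonus_days)
          if (quota == 0) next
          id <- iu[meta$day_index[iu] == d]
          if (length(id) < quota) {
            stop(sprintf("user %s, day %d has only %d windows (< %d needed)",
                         u, d, length(id), quota))
          }
          keep <- c(keep, sample_exact(id, quota))
        }
      }
    }
    windows[sort(keep)]
  })
}

# sample() without the length-1 surprise
sample_exact <- function(x, k) {
  if (length(x) == 1L) return(rep(x, min(k, 1L)))
  sample(x, k)
}
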