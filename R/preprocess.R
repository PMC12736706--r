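#' Remove the least-squares linear trend from a window
#'
#' Fits `a + b*t` by least squares and subtracts it; the output has zero
#' mean and zero correlation with the sample index. A constant window maps
#' to all zeros. Used to sharpen systolic peaks before peak detection.
#'
#' @param window A [ppg_window()] (or numeric vector).
#' @return Object of the same kind with the trend removed.
#' @export
linear_detrend <- function(window) {
  x <- if (inherits(window, "ppg_window")) window$samples else window
  n <- length(x)
  if (n < 2) stop("window must contain at least 2 samples")
  t <- seq_len(n) - (n + 1) / 2              # centred index
  b <- sum(t * (x - mean(x))) / sum(t * t)
  resid <- x - mean(x) - b * t
  if (inherits(window, "ppg_window")) {
    window$samples <- resid
    window
  } else {
    resid
  }
}

# order-4 Butterworth forward-backward low-pass (zero-phase response).
# Odd-reflection padding suppresses the start/end transients that otherwise
# dominate at very low cutoff frequencies.
zp_lowpass <- function(x, fs, cutoff) {
  ba <- signal::butter(4, cutoff / (fs / 2), type = "low")
  n <- length(x)
  npad <- min(n - 1L, round(3 * fs / cutoff))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(ba, c(head_pad, x, tail_pad)))
  y[(npad + 1):(npad + n)]
}

#' Decompose a PPG window into AC, RS and DC components
#'
#' Splits a window into three zero-phase bands: DC (below `f1`, slow
#' blood-volume trend), RS (`[f1, f2]`, respiratory), and AC
#' (`[f2, ac_high]`, cardiac pulsatile). Defaults put the respiratory band
#' at 0.1-0.5 Hz and the cardiac band at 0.5-8 Hz. The bands are built as
#' a complementary bank of forward-backward order-4 Butterworth low-pass
#' filters (`dc = L_f1(x)`, `rs = L_f2(x) - L_f1(x)`,
#' `ac = L_high(x) - L_f2(x)`), which is zero-phase, numerically stable at
#' very low normalised cutoffs, and makes the three components sum to the
#' low-passed window exactly.
#'
#' @param window A [ppg_window()] of at least 10 s at fs >= 16 Hz.
#' @param f1 DC/RS band edge, Hz.
#' @param f2 RS/AC band edge, Hz.
#' @param ac_high Upper cardiac band edge, Hz (clipped below Nyquist).
#' @return Object of class `ppg_components` with elements `ac`, `rs`, `dc`,
#'   `fs`, each series the same length as the window.
#' @export
decompose_bands <- function(window, f1 = 0.1, f2 = 0.5, ac_high = 8) {
  stopifnot(inherits(window, "ppg_window"))
  fs <- window$fs
  if (fs < 16) stop("fs must be >= 16 Hz to separate the bands")
  if (window$duration_s < 10) {
    stop("window too short to resolve the DC band (need >= 10 s)")
  }
  x <- window$samples
  if (!all(is.finite(x))) stop("window contains non-finite samples")
  hi <- min(ac_high, 0.45 * fs)
  lp1 <- zp_lowpass(x, fs, f1)
  lp2 <- zp_lowpass(x, fs, f2)
  lp3 <- zp_lowpass(x, fs, hi)
  dc <- lp1
  rs <- lp2 - lp1
  ac <- lp3 - lp2
  structure(list(ac = ac, rs = rs, dc = dc, fs = fs,
                 band_edges = c(f1 = f1, f2 = f2, ac_high = hi)),
            class = "ppg_components")
}

#' Detect systolic peaks
#'
#' Local-maximum detector with a prominence threshold of
#' `0.5 * sd(window)` and a minimum spacing of 0.6 times the beat period,
#' floored at the physiological bound `fs * 60/180`. The beat period is
#' estimated as the autocorrelation argmax within the 40-180 beats/min lag
#' band -- unlike a spectral estimate this is robust to a strong dicrotic
#' wave, whose half-cycle alignment can dominate the spectrum but never
#' the full-period autocorrelation peak. The adaptive spacing suppresses
#' dicrotic secondary maxima while never rejecting true beats at up to 180
#' beats/min. Flat or near-flat windows return an empty index vector.
#' Indices are 1-based positions into the window.
#'
#' @param window A [ppg_window()] of at least 2 s (or numeric vector plus
#'   `fs`).
#' @param fs Sampling rate when `window` is a bare numeric vector.
#' @return Strictly increasing integer vector of peak indices.
#' @export
detect_peaks <- function(window, fs = NULL) {
  if (inherits(window, "ppg_window")) {
    x <- window$samples
    fs <- window$fs
    if (window$duration_s < 2) stop("window must be at least 2 s")
  } else {
    x <- window
    if (is.null(fs)) stop("fs required for a bare numeric vector")
  }
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (i > 1) min_until_higher(x, i, -1L) else x[i]
    right <- if (i < n) min_until_higher(x, i, +1L) else x[i]
    x[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= 0.5 * s]
  if (!length(cand)) return(integer(0))
  min_dist <- round(fs * 60 / 180)
  period <- beat_period_acf(x, fs)
  if (is.finite(period)) min_dist <- max(min_dist, round(0.6 * fs * period))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# beat period (s) as the autocorrelation argmax in the 40-180 bpm lag band
beat_period_acf <- function(x, fs) {
  lag_min <- max(1L, round(fs * 60 / 180))
  lag_max <- min(length(x) - 2L, round(fs * 60 / 40))
  if (lag_max <= lag_min) return(NA_real_)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1]
  lag <- which.max(ac[lag_min:lag_max]) + lag_min - 1L
  lag / fs
}

# minimum of x from peak i walking in direction dir until a higher sample
min_until_higher <- function(x, i, dir) {
  lo <- x[i]
  j <- i + dir
  n <- length(x)
  while (j >= 1 && j <= n && x[j] <= x[i]) {
    if (x[j] < lo) lo <- x[j]
    j <- j + dir
  }
  lo
}

#' Quadratic-spline interpolation
#'
#' C1 piecewise-quadratic interpolant through `(x, y)`; the initial slope is
#' taken from the parabola through the first three points, which makes the
#' scheme exactly reproduce polynomials of degree <= 2. Two points fall back
#' to linear interpolation.
#'
#' @param x Strictly increasing abscissae.
#' @param y Ordinates.
#' @param xout Evaluation points within `[min(x), max(x)]`.
#' @return Interpolated values at `xout`.
#' @export
quad_spline_interp <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2, all(diff(x) > 0))
  if (n == 2) {
    return(y[1] + (y[2] - y[1]) * (xout - x[1]) / (x[2] - x[1]))
  }
  h <- diff(x)
  # slope at x1 from the interpolating parabola through points 1..3
  x1 <- x[1]; x2 <- x[2]; x3 <- x[3]
  z1 <- y[1] * (2 * x1 - x2 - x3) / ((x1 - x2) * (x1 - x3)) +
        y[2] * (x1 - x3) / ((x2 - x1) * (x2 - x3)) +
        y[3] * (x1 - x2) / ((x3 - x1) * (x3 - x2))
  z <- numeric(n)
  z[1] <- z1
  for (i in seq_len(n - 1)) {
    z[i + 1] <- 2 * (y[i + 1] - y[i]) / h[i] - z[i]
  }
  idx <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  u <- xout - x[idx]
  y[idx] + z[idx] * u + (z[idx + 1] - z[idx]) / (2 * h[idx]) * u^2
}

#' Standardise beat cycles to a common length and average them
#'
#' Each systolic-peak-to-next-systolic-peak segment is resampled to exactly
#' `L` points by quadratic-spline interpolation; the template is the
#' element-wise mean of the standardised cycles (multicycle averaging),
#' suppressing beat-level noise while preserving user-specific morphology.
#'
#' @param window A [ppg_window()] (or numeric vector).
#' @param peaks Peak indices from [detect_peaks()]; at least 2 are required
#'   (one complete cycle).
#' @param L Standardised cycle length in samples.
#' @return Object of class `cycle_set`: `cycles` (L x n matrix), `template`
#'   (length-L mean cycle), `n_source_beats`, `L`.
#' @export
standardize_cycles <- function(window, peaks, L = 100) {
  x <- if (inherits(window, "ppg_window")) window$samples else window
  peaks <- as.integer(peaks)
  if (length(peaks) < 2) stop("unusable window: need >= 2 peaks for one complete cycle")
  if (any(diff(peaks) < 2)) stop("peaks must be strictly increasing and separated")
  n_cyc <- length(peaks) - 1L
  cycles <- matrix(0, nrow = L, ncol = n_cyc)
  for (i in seq_len(n_cyc)) {
    i0 <- peaks[i]; i1 <- peaks[i + 1]
    seg <- i0:i1
    # half-open cycle [peak_i, peak_{i+1})
    xout <- i0 + (seq_len(L) - 1) / L * (i1 - i0)
    cycles[, i] <- quad_spline_interp(seg, x[seg], xout)
  }
  structure(list(cycles = cycles, template = rowMeans(cycles),
                 n_source_beats = length(peaks), L = L),
            class = "cycle_set")
}

#' Full cycle-template preprocessing for one window
#'
#' Detrend, detect peaks, standardise cycles, return the multicycle-average
#' template (z-scored when `normalize` is `TRUE`, making the template
#' amplitude-invariant for metric learning). Returns `NULL` for windows
#' with fewer than 2 detected beats.
#'
#' @param window A [ppg_window()].
#' @param L Standardised cycle length.
#' @param normalize Z-score the template.
#' @return Numeric template of length `L`, or `NULL` for unusable windows.
#' @export
cycle_template <- function(window, L = 100, normalize = TRUE) {
  w <- linear_detrend(window)
  pk <- detect_peaks(w)
  if (length(pk) < 2) return(NULL)
  tpl <- standardize_cycles(w, pk, L = L)$template
  if (normalize) {
    s <- stats::sd(tpl)
    tpl <- if (s > 0) (tpl - mean(tpl)) / s else tpl * 0
  }
  tpl
}
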