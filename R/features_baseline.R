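# Discrete wavelet machinery. Analysis filters are the canonical
# Daubechies/Symlet coefficients; decomposition uses periodization, so the
# coefficient count at each level is ceil(m/2) and a 4-level transform of an
# N-sample window carries about N coefficients in total.

wavelet_filters <- function(name = c("db1", "db4", "sym4")) {
  name <- match.arg(name)
  lo <- switch(name,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    sym4 = c(-0.07576571478935668, -0.029635527645954293, 0.49761866763256290,
             0.80373875180538600, 0.29785779560560505, -0.09921954357695636,
             -0.012603967262261821, 0.032223100604071306))
  F <- length(lo)
  # quadrature mirror: hi[n] = (-1)^(n+1) lo[F-1-n] (n 0-based)
  hi <- rev(lo) * (-1)^seq_len(F)
  list(lo = lo, hi = hi, len = F)
}

# one periodized analysis step: returns approximation and detail coefficients
dwt_step <- function(x, filt) {
  m <- length(x)
  if (m %% 2L == 1L) { x <- c(x, x[m]); m <- m + 1L }
  F <- filt$len
  half <- m %/% 2L
  a <- numeric(half); d <- numeric(half)
  # periodized convolution with the standard F/2 - 1 phase offset
  for (n in seq_len(F)) {
    idx <- (2 * seq_len(half) + F %/% 2L - n - 1L) %% m + 1L
    a <- a + filt$lo[n] * x[idx]
    d <- d + filt$hi[n] * x[idx]
  }
  list(a = a, d = d)
}

#' Multilevel discrete wavelet decomposition (periodization mode)
#'
#' @param x Numeric series.
#' @param wavelet One of `"db1"`, `"db4"`, `"sym4"`.
#' @param level Decomposition depth; reduced (with a message) when the
#'   series is too short for the requested depth.
#' @return List `coeffs` = list(a_J, d_J, ..., d_1), `level` actually used.
#' @export
wavedec <- function(x, wavelet = "db4", level = 4) {
  filt <- wavelet_filters(wavelet)
  max_level <- floor(log2(length(x) / (filt$len - 1)))
  if (wavelet == "db1") max_level <- floor(log2(length(x)))
  use <- max(1L, min(level, max_level))
  if (use < level) {
    message(sprintf("series of length %d supports only %d %s levels (requested %d)",
                    length(x), use, wavelet, level))
  }
  details <- vector("list", use)
  a <- x
  for (j in seq_len(use)) {
    st <- dwt_step(a, filt)
    a <- st$a
    details[[j]] <- st$d
  }
  list(coeffs = c(list(a), rev(details)), level = use)
}

#' Derived signal components for the 160-feature extractor
#'
#' Six named series per window: the raw samples, the FFT magnitude
#' spectrum, the Welch power spectral density, and one concatenated 4-level
#' coefficient series per wavelet family (db1, db4, sym4).
#'
#' @param window A [ppg_window()] of at least 6 s.
#' @return Object of class `ppg_baseline_components`: named list of six
#'   series plus the one-sided spectral axes used downstream.
#' @export
compute_components <- function(window) {
  stopifnot(inherits(window, "ppg_window"))
  if (window$duration_s < 6 - 1 / window$fs) stop("window must be at least 6 s")
  x <- window$samples
  if (!all(is.finite(x))) stop("window contains non-finite samples")
  fs <- window$fs
  n <- length(x)
  fftm <- Mod(stats::fft(x))
  psd <- welch_psd(x, fs)
  wl <- lapply(c(db1 = "db1", db4 = "db4", sym4 = "sym4"), function(wv) {
    unlist(wavedec(x, wv, level = 4)$coeffs, use.names = FALSE)
  })
  half <- n %/% 2L + 1L
  structure(list(raw = x, fft = fftm, welch = psd$power,
                 db1 = wl$db1, db4 = wl$db4, sym4 = wl$sym4,
                 fft_freq = (seq_len(half) - 1) * fs / n,
                 fft_power = fftm[seq_len(half)]^2,
                 welch_freq = psd$freq, fs = fs),
            class = "ppg_baseline_components")
}

#' 24 time-domain statistics of a series
#'
#' The fixed statistic set applied uniformly to every derived component:
#' mean, sd, variance, min, max, range, median, IQR, median absolute
#' deviation, skewness, excess kurtosis, RMS, energy, 16-bin histogram
#' Shannon entropy, zero-crossing rate of the mean-removed series, mean
#' absolute first difference, sd of first differences, mean absolute second
#' difference, lag-1 autocorrelation, Hjorth mobility and complexity, 10th
#' and 90th percentiles, crest factor. Dispersion-normalised statistics of
#' a constant series are 0 by convention.
#'
#' @param series Numeric series of length >= 4.
#' @return Named numeric vector of length 24 (names prefixed `td_`).
#' @export
time_domain_stats <- function(series) {
  x <- series
  n <- length(x)
  if (n < 4) stop("series must have length >= 4")
  s <- stats::sd(x)
  mu <- mean(x)
  rms <- sqrt(mean(x^2))
  d1 <- diff(x)
  d2 <- diff(d1)
  sd_d1 <- stats::sd(d1)
  x0 <- x - mu
  zcr <- sum(x0[-n] * x0[-1] < 0) / (n - 1)
  rng <- max(x) - min(x)
  hist_ent <- if (rng == 0) 0 else {
    counts <- tabulate(pmin(floor((x - min(x)) / rng * 16) + 1L, 16L), 16L)
    p <- counts / n
    p <- p[p > 0]
    -sum(p * log(p))
  }
  acf1 <- if (s == 0) 0 else stats::cor(x[-n], x[-1])
  mob <- if (s == 0) 0 else sd_d1 / s
  mob_d <- if (sd_d1 == 0) 0 else stats::sd(d2) / sd_d1
  cplx <- if (mob == 0) 0 else mob_d / mob
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  out <- c(mean = mu, sd = s, var = s^2, min = min(x), max = max(x),
           range = rng, median = q[3], iqr = q[4] - q[2],
           mad = stats::median(abs(x - q[3])),
           skewness = skewness0(x), kurtosis = kurtosis0(x),
           rms = rms, energy = sum(x^2), hist_entropy = hist_ent,
           zcr = zcr, mean_abs_diff = mean(abs(d1)), sd_diff = sd_d1,
           mean_abs_diff2 = mean(abs(d2)), acf1 = acf1,
           hjorth_mobility = mob, hjorth_complexity = cplx,
           p10 = q[1], p90 = q[5],
           crest = if (rms == 0) 0 else max(abs(x)) / rms)
  stats::setNames(out, paste0("td_", names(out)))
}

#' 8 frequency-domain statistics of a power spectrum
#'
#' Spectral centroid, spread, dominant frequency, normalised spectral
#' entropy, flatness, band power 0.5-2 Hz, band power 2-5 Hz, and the ratio
#' of the two band powers. An all-zero spectrum returns all zeros.
#'
#' @param spectrum Nonnegative power weights.
#' @param freqs Matching frequency axis, Hz.
#' @return Named numeric vector of length 8 (names prefixed `fd_`).
#' @export
frequency_domain_stats <- function(spectrum, freqs) {
  if (length(spectrum) != length(freqs)) stop("spectrum/freqs length mismatch")
  tot <- sum(spectrum)
  nm <- paste0("fd_", c("centroid", "spread", "dominant", "entropy",
                        "flatness", "bp_05_2", "bp_2_5", "bp_ratio"))
  if (tot == 0) return(stats::setNames(numeric(8), nm))
  p <- spectrum / tot
  centroid <- sum(freqs * p)
  spread <- sqrt(sum((freqs - centroid)^2 * p))
  dominant <- freqs[which.max(spectrum)]
  entropy <- spectral_entropy_norm(spectrum)
  flat <- exp(mean(log(pmax(spectrum, .Machine$double.xmin)))) / mean(spectrum)
  bp1 <- sum(spectrum[freqs >= 0.5 & freqs <= 2])
  bp2 <- sum(spectrum[freqs > 2 & freqs <= 5])
  stats::setNames(c(centroid, spread, dominant, entropy, flat, bp1, bp2,
                    if (bp2 == 0) 0 else bp1 / bp2), nm)
}

#' 160-value time/frequency feature vector
#'
#' 24 time-domain statistics on each of the six derived components (144
#' values) plus 8 frequency-domain statistics on each of the two spectral
#' representations -- the one-sided FFT power spectrum and the Welch PSD --
#' (16 values), in a fixed order.
#'
#' @param window A [ppg_window()] (40 s identification / 6 s
#'   re-identification).
#' @return A [feature_vector()] of length 160 with `extractor_id`
#'   `"baseline160"`.
#' @export
baseline_features <- function(window) {
  comp <- compute_components(window)
  td <- unlist(lapply(c("raw", "fft", "welch", "db1", "db4", "sym4"),
                      function(nm) {
                        v <- time_domain_stats(comp[[nm]])
                        stats::setNames(v, paste0(nm, "_", names(v)))
                      }))
  fd <- c(stats::setNames(frequency_domain_stats(comp$fft_power, comp$fft_freq),
                          paste0("fftspec_", names(frequency_domain_stats(0, 0)))),
          stats::setNames(frequency_domain_stats(comp$welch, comp$welch_freq),
                          paste0("welch_", names(frequency_domain_stats(0, 0)))))
  feature_vector(c(td, fd), c(names(td), names(fd)), extractor_id = "baseline160")
}
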