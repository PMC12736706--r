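# Spectral helpers shared by the feature extractors.

#' Welch power spectral density
#'
#' Hann-tapered, 50%-overlapped segment-averaged one-sided PSD. Default
#' segment length is `min(4 s * fs, floor(N/2))` samples, which resolves
#' both the respiratory and cardiac bands in a 6 s window while remaining
#' valid at 40 s.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in samples.
#' @return List with `freq` (Hz) and `power` (one-sided PSD).
#' @export
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(round(4 * fs), floor(n / 2))
  seg_len <- max(8L, as.integer(seg_len))
  if (seg_len > n) seg_len <- n
  hop <- max(1L, seg_len %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  U <- sum(w^2)
  starts <- seq.int(0L, n - seg_len, by = hop)
  nfft <- seg_len
  half <- nfft %/% 2L + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[(s0 + 1):(s0 + seg_len)] * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    p1 <- P[seq_len(half)]
    # one-sided scaling: double interior bins
    if (nfft %% 2L == 0L) {
      p1[2:(half - 1L)] <- 2 * p1[2:(half - 1L)]
    } else {
      p1[2:half] <- 2 * p1[2:half]
    }
    acc <- acc + p1
  }
  list(freq = (seq_len(half) - 1) * fs / nfft, power = acc / length(starts))
}

#' Dominant frequency of a series
#'
#' Argmax of the Welch PSD, excluding the zero-frequency bin.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @return Frequency in Hz (0 for a constant series).
#' @export
dominant_frequency <- function(x, fs) {
  if (stats::sd(x) == 0) return(0)
  psd <- welch_psd(x - mean(x), fs)
  keep <- psd$freq > 0
  psd$freq[keep][which.max(psd$power[keep])]
}

# normalized spectral (Shannon) entropy of a power vector, in [0, 1]
spectral_entropy_norm <- function(p) {
  p <- p[p > 0]
  if (length(p) <= 1) return(0)
  q <- p / sum(p)
  -sum(q * log(q)) / log(length(q))
}

# power within [lo, hi] Hz from a one-sided PSD
band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  df <- if (length(psd$freq) > 1) psd$freq[2] - psd$freq[1] else 1
  sum(psd$power[sel]) * df
}

# population skewness / excess kurtosis, 0 by convention for constants
skewness0 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

kurtosis0 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}
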