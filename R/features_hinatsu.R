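#' Construct a named feature vector
#'
#' @param values Numeric values.
#' @param names Unique labels, same length as `values`.
#' @param extractor_id Label of the extractor that produced the vector.
#' @return Named numeric vector of class `feature_vector`.
#' @export
feature_vector <- function(values, names, extractor_id) {
  if (length(values) != length(names)) stop("values/names length mismatch")
  if (anyDuplicated(names)) stop("feature names must be unique")
  if (!all(is.finite(values))) {
    bad <- names[!is.finite(values)]
    stop("non-finite feature value(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(stats::setNames(as.numeric(values), names),
            class = "feature_vector", extractor_id = extractor_id)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s: %d features\n",
              attr(x, "extractor_id"), length(x)))
  invisible(x)
}

# 10 spectral/statistical descriptors of one band-limited component
component_stats10 <- function(x, fs, band) {
  psd <- welch_psd(x, fs)
  c(max = max(x), min = min(x), mean = mean(x), sd = stats::sd(x),
    skewness = skewness0(x), kurtosis = kurtosis0(x),
    rms = sqrt(mean(x^2)),
    dominant_frequency = dominant_frequency(x, fs),
    spectral_entropy = spectral_entropy_norm(psd$power),
    inband_power = band_power(psd, band[1], band[2]))
}

#' Spectral and statistical features of an AC/RS/DC component set
#'
#' 10 descriptors each for the cardiac (AC) and respiratory (RS) components
#' -- max, min, mean, sd, skewness, kurtosis, RMS, dominant frequency,
#' spectral entropy, in-band power -- plus 5 for the slow blood-volume (DC)
#' component: mean, max, min, sd and linear slope. 25 values in total.
#' Skewness and kurtosis of a constant component are defined as 0.
#'
#' @param components A `ppg_components` object from [decompose_bands()].
#' @return A [feature_vector()] of length 25.
#' @export
component_spectral_stat_features <- function(components) {
  stopifnot(inherits(components, "ppg_components"))
  fs <- components$fs
  be <- components$band_edges
  ac <- component_stats10(components$ac, fs, c(be["f2"], be["ac_high"]))
  rs <- component_stats10(components$rs, fs, c(be["f1"], be["f2"]))
  dcx <- components$dc
  t <- seq_along(dcx) / fs
  tc <- t - mean(t)
  slope <- sum(tc * (dcx - mean(dcx))) / sum(tc * tc)
  dc <- c(mean = mean(dcx), max = max(dcx), min = min(dcx),
          sd = stats::sd(dcx), slope = slope)
  feature_vector(c(ac, rs, dc),
                 c(paste0("ac_", names(ac)), paste0("rs_", names(rs)),
                   paste0("dc_", names(dc))),
                 extractor_id = "component25")
}

# triangular mel filterbank: rows = filters, cols = FFT bins (one-sided)
mel_filterbank <- function(n_mels, nfft, fs) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  half <- nfft %/% 2L + 1L
  freqs <- (seq_len(half) - 1) * fs / nfft
  pts <- mel2hz(seq(hz2mel(0), hz2mel(fs / 2), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, half)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix (n_out x n_in)
dct2_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  b <- seq_len(n_in) - 0.5
  M <- sqrt(2 / n_in) * cos(pi * outer(k, b) / n_in)
  M[1, ] <- sqrt(1 / n_in)
  M
}

#' Mel-frequency cepstrum coefficients of a PPG window
#'
#' Frames of `frame_s` seconds with 50% hop, Hann taper, power spectrum,
#' `n_mels` triangular mel filters spanning 0 to fs/2, log filterbank
#' energies, orthonormal DCT-II; the first `n_coeff` coefficients are
#' averaged over frames. The 2 s default frame spans multiple beats, suited
#' to the sub-10 Hz energy of PPG. Because the log separates gain from
#' shape, amplitude scaling moves only coefficient 0.
#'
#' @param window A [ppg_window()] of at least one frame.
#' @param n_coeff Number of coefficients (default 13).
#' @param frame_s Frame length, seconds.
#' @param n_mels Number of mel bands.
#' @return A [feature_vector()] of length `n_coeff` named `mfcc_00`...
#' @export
mfcc_features <- function(window, n_coeff = 13, frame_s = 2, n_mels = 20) {
  stopifnot(inherits(window, "ppg_window"))
  fs <- window$fs
  x <- window$samples
  if (!all(is.finite(x))) stop("window contains non-finite samples")
  flen <- round(frame_s * fs)
  if (length(x) < flen) stop("window shorter than one MFCC frame")
  hop <- max(1L, flen %/% 2L)
  starts <- seq.int(0L, length(x) - flen, by = hop)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1))
  fb <- mel_filterbank(n_mels, flen, fs)
  D <- dct2_matrix(n_coeff, n_mels)
  half <- flen %/% 2L + 1L
  acc <- numeric(n_coeff)
  for (s0 in starts) {
    seg <- x[(s0 + 1):(s0 + flen)] * taper
    P <- Mod(stats::fft(seg))[seq_len(half)]^2
    E <- as.numeric(fb %*% P)
    logE <- log(pmax(E, .Machine$double.xmin))
    acc <- acc + as.numeric(D %*% logE)
  }
  feature_vector(acc / length(starts),
                 sprintf("mfcc_%02d", seq_len(n_coeff) - 1),
                 extractor_id = sprintf("mfcc%d", n_coeff))
}

#' 38-value heartbeat + respiration feature vector
#'
#' Full identification-feature chain for a (nominally 40 s) window: AC/RS/DC
#' band decomposition, 25 component spectral/statistical features, and 13
#' frame-averaged MFCCs, concatenated in a stable order.
#'
#' @param window A [ppg_window()] of at least 10 s.
#' @param f1,f2,ac_high Band edges passed to [decompose_bands()].
#' @return A [feature_vector()] of length 38 with `extractor_id`
#'   `"hinatsu38"`.
#' @export
hinatsu_features <- function(window, f1 = 0.1, f2 = 0.5, ac_high = 8) {
  stopifnot(inherits(window, "ppg_window"))
  if (!all(is.finite(window$samples))) stop("window contains non-finite samples")
  comp <- decompose_bands(window, f1 = f1, f2 = f2, ac_high = ac_high)
  a <- component_spectral_stat_features(comp)
  b <- mfcc_features(window)
  feature_vector(c(as.numeric(a), as.numeric(b)), c(names(a), names(b)),
                 extractor_id = "hinatsu38")
}
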