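test_that("linear detrending removes exactly the least-squares line", {
  fs <- 50
  t <- (0:499) / fs
  w <- make_window(3 * t + 2, fs)
  expect_equal(linear_detrend(w)$samples, rep(0, 500), tolerance = 1e-10)

  x <- sin(2 * pi * 1.1 * t) + 0.5 * t + 1
  d <- linear_detrend(make_window(x, fs))$samples
  expect_lt(abs(cor(d, seq_along(d))), 1e-10)
  expect_lt(abs(mean(d)), 1e-12)

  # idempotence
  expect_equal(linear_detrend(d), d, tolerance = 1e-10)

  # constant window -> all zeros, not an error
  expect_equal(linear_detrend(make_window(rep(5, 100), fs))$samples, rep(0, 100))
})

test_that("band decomposition routes tones to their own component", {
  fs <- 50
  t <- (0:(20 * fs - 1)) / fs
  frac_in <- function(f_tone, comp) {
    w <- make_window(sin(2 * pi * f_tone * t), fs)
    cs <- decompose_bands(w)
    v <- c(ac = var(cs$ac), rs = var(cs$rs), dc = var(cs$dc))
    v[comp] / sum(v)
  }
  expect_gte(frac_in(0.05, "dc"), 0.95)
  expect_gte(frac_in(0.30, "rs"), 0.90)
  expect_gte(frac_in(1.20, "ac"), 0.95)

  # three-tone mixture: >= 90% of each tone's variance lands in its own band
  x <- 2 * sin(2 * pi * 0.05 * t) + sin(2 * pi * 0.3 * t) + sin(2 * pi * 1.2 * t)
  cs <- decompose_bands(make_window(x, fs))
  expect_gt(var(cs$dc) / var(2 * sin(2 * pi * 0.05 * t)), 0.9)
  expect_gt(var(cs$rs) / var(sin(2 * pi * 0.3 * t)), 0.9)
  expect_gt(var(cs$ac) / var(sin(2 * pi * 1.2 * t)), 0.9)

  # cardiac output is (numerically) zero-mean; lengths match the source
  expect_lt(abs(mean(cs$ac)), 0.01 * sd(x))
  expect_length(cs$ac, length(x))
  expect_length(cs$dc, length(x))

  expect_error(decompose_bands(make_window(rnorm(100), 50)), "too short")
})

test_that("peak detection matches ground-truth beats on synthetic signals", {
  expect_identical(detect_peaks(make_window(rep(0, 500), 50)), integer(0))

  # noisy 75 bpm: within 1 beat of the generator's truth over 30 s
  p <- clean_profile(75); p$noise_sd <- 0.05; p$hr_sd <- 1
  rec <- synthesize_session(p, 30, 125, seed = 21)
  pk <- detect_peaks(ppg_window(rec$samples, 125))
  expect_lte(abs(length(pk) - length(attr(rec, "beat_times"))), 1)

  # inter-peak spacing respects the physiological floor
  expect_true(all(diff(pk) >= round(125 * 60 / 180)))
})

test_that("quadratic-spline cycle standardisation is exact and equivariant", {
  # exactness on polynomials of degree <= 2
  x <- 1:31
  for (co in list(c(2, 0, 0), c(1, -3, 0), c(0.5, 2, -7))) {
    y <- co[1] + co[2] * x + co[3] * x^2
    xo <- seq(1, 31, by = 0.37)
    expect_equal(quad_spline_interp(x, y, xo),
                 co[1] + co[2] * xo + co[3] * xo^2, tolerance = 1e-8)
  }

  # identical repeated beats -> every standardised cycle equals the template
  beat <- sin(2 * pi * (0:49) / 50)
  xsig <- rep(beat, 6)
  peaks <- which(diff(sign(diff(xsig))) < 0) + 1L
  peaks <- peaks[seq(1, length(peaks), by = 2)]  # one max per cycle
  cs <- standardize_cycles(xsig, peaks, L = 100)
  expect_equal(cs$template, cs$cycles[, 1], tolerance = 1e-8)
  expect_true(all(apply(cs$cycles, 2, function(c) max(abs(c - cs$template))) < 1e-8))

  # raw cycle lengths {80, 95, 110} all standardised to L = 100
  pk <- cumsum(c(1, 80, 95, 110))
  sig <- rnorm(max(pk) + 5)
  cs2 <- standardize_cycles(sig, pk, L = 100)
  expect_equal(dim(cs2$cycles), c(100, 3))
  expect_length(cs2$template, 100)
  expect_equal(cs2$n_source_beats, 4)

  # scale equivariance
  cs3 <- standardize_cycles(3 * sig, pk, L = 100)
  expect_equal(cs3$cycles, 3 * cs2$cycles, tolerance = 1e-10)
  expect_equal(cs3$template, 3 * cs2$template, tolerance = 1e-10)

  expect_error(standardize_cycles(sig, pk[1], L = 100), "2 peaks")
})
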