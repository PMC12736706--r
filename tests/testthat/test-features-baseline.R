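test_that("time-domain statistics match a brute-force oracle", {
  # hand arithmetic
  v <- time_domain_stats(c(1, 2, 3, 4))
  expect_equal(unname(v["td_mean"]), 2.5)
  expect_equal(unname(v["td_range"]), 3)
  expect_equal(unname(v["td_rms"]), sqrt(7.5))

  # constant series conventions
  vc <- time_domain_stats(rep(4, 50))
  expect_equal(unname(vc["td_mean"]), 4)
  expect_equal(unname(vc["td_sd"]), 0)
  expect_equal(unname(vc["td_zcr"]), 0)
  expect_equal(unname(vc["td_skewness"]), 0)
  expect_equal(unname(vc["td_hjorth_mobility"]), 0)

  set.seed(11)
  for (k in 1:100) {
    x <- switch(k %% 4 + 1, rnorm(50), rt(50, 3), cumsum(rnorm(50)),
                rpois(50, 4) + runif(50))
    expect_equal(unname(time_domain_stats(x)), naive_time_stats(x),
                 tolerance = 1e-10)
  }
})

test_that("frequency-domain statistics have exact degenerate behaviour", {
  freqs <- seq(0, 5, by = 0.5)
  # single nonzero bin at 1.5 Hz
  sp <- numeric(length(freqs)); sp[freqs == 1.5] <- 2
  v <- frequency_domain_stats(sp, freqs)
  expect_equal(unname(v["fd_centroid"]), 1.5)
  expect_equal(unname(v["fd_spread"]), 0)
  expect_equal(unname(v["fd_entropy"]), 0)

  # flat spectrum -> flatness exactly 1
  vf <- frequency_domain_stats(rep(3, length(freqs)), freqs)
  expect_equal(unname(vf["fd_flatness"]), 1)

  # two-tone: centroid is the power-weighted mean of the tone frequencies
  sp2 <- numeric(length(freqs)); sp2[freqs == 1] <- 3; sp2[freqs == 4] <- 1
  v2 <- frequency_domain_stats(sp2, freqs)
  expect_equal(unname(v2["fd_centroid"]), (3 * 1 + 1 * 4) / 4)

  # all-zero spectrum -> all zeros by convention
  expect_equal(unname(frequency_domain_stats(numeric(11), freqs)), rep(0, 8))
})

test_that("wavelet decomposition matches the reference transform", {
  # frozen oracle values: PyWavelets wavedec(0:31, mode='periodization', level=2)
  x <- as.numeric(0:31)
  wd <- wavedec(x, "db4", level = 2)
  expect_equal(wd$coeffs[[1]],
               c(55.738406, 46.770869, 5.730725, 12.032359, 20.032359,
                 28.028766, 35.932015, 43.7345), tolerance = 1e-6)
  expect_equal(wd$coeffs[[2]],
               c(8.591309, -1.892669, -0.078125, 0, 0, -0.078125,
                 -2.622706, -19.811936), tolerance = 1e-6)
  expect_equal(wd$coeffs[[3]][1:4], c(-0.404449, -0.339117, 0, 0),
               tolerance = 1e-6)

  ws <- wavedec(x, "sym4", level = 2)
  expect_equal(ws$coeffs[[1]],
               c(3.769689, 15.070808, 22.120418, 30.087192, 38.087192,
                 45.903497, 59.28738, 33.673824), tolerance = 1e-6)

  wh <- wavedec(x, "db1", level = 2)
  expect_equal(wh$coeffs[[1]], c(3, 11, 19, 27, 35, 43, 51, 59), tolerance = 1e-10)
  expect_equal(wh$coeffs[[2]], rep(-2, 8), tolerance = 1e-10)

  # short series: levels reduced with a message, never an error
  expect_message(wavedec(rnorm(20), "db4", level = 4), "supports only")
})

test_that("derived components satisfy their structural contracts", {
  w <- make_window(rnorm(300), 50)
  comp <- compute_components(w)
  expect_length(setdiff(c("raw", "fft", "welch", "db1", "db4", "sym4"),
                        names(comp)), 0)

  # Parseval: sum |FFT|^2 / N = sum x^2
  expect_equal(sum(comp$fft^2) / length(w$samples), sum(w$samples^2),
               tolerance = 1e-6)

  # linearity: all-zero window -> all-zero components
  comp0 <- compute_components(make_window(rep(0, 300), 50))
  for (nm in c("raw", "fft", "welch", "db1", "db4", "sym4")) {
    expect_equal(comp0[[nm]], rep(0, length(comp0[[nm]])))
  }

  expect_error(compute_components(make_window(rnorm(100), 50)), "6 s")
})

test_that("the 160-feature vector has the contracted layout and scaling", {
  w <- lab_windows_40s()[[1]]
  fv <- baseline_features(w)
  expect_length(fv, 160)
  td <- grepl("_td_", names(fv))
  expect_equal(sum(td), 144)
  expect_equal(sum(grepl("_fd_", names(fv))), 16)
  expect_identical(attr(fv, "extractor_id"), "baseline160")
  expect_identical(baseline_features(w), fv)  # determinism

  # amplitude scaling: equivariant features scale by c, invariant ones do not
  c0 <- 3.7
  ws <- w; ws$samples <- c0 * w$samples
  fs_ <- baseline_features(ws)
  expect_equal(unname(fs_["raw_td_mean"]), c0 * unname(fv["raw_td_mean"]),
               tolerance = 1e-8)
  expect_equal(unname(fs_["raw_td_sd"]), c0 * unname(fv["raw_td_sd"]),
               tolerance = 1e-8)
  expect_equal(unname(fs_["raw_td_skewness"]), unname(fv["raw_td_skewness"]),
               tolerance = 1e-8)
  expect_equal(unname(fs_["raw_td_crest"]), unname(fv["raw_td_crest"]),
               tolerance = 1e-8)
  expect_equal(unname(fs_["welch_fd_flatness"]), unname(fv["welch_fd_flatness"]),
               tolerance = 1e-8)
  expect_equal(unname(fs_["fftspec_fd_bp_ratio"]), unname(fv["fftspec_fd_bp_ratio"]),
               tolerance = 1e-8)
})
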