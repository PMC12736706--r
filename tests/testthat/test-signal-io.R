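test_that("session CSVs are read back with exact sample counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ppg", sprintf("%.4f", sin(1:300))), path)
  rec <- read_session_csv(path, fs = 50)
  expect_length(rec$samples, 300)
  expect_equal(length(rec$samples) / rec$fs, 6)   # 6 s segment at 50 Hz

  # headerless single column
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%.4f", cos(1:100)), path2)
  expect_length(read_session_csv(path2, fs = 25)$samples, 100)

  # empty file: error, no partial record
  path3 <- withr::local_tempfile(fileext = ".csv")
  file.create(path3)
  expect_error(read_session_csv(path3, fs = 50), "empty")

  # non-numeric row named in the error
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ppg", "1.0", "2.0", "oops", "4.0"), path4)
  expect_error(read_session_csv(path4, fs = 50), "row 3")
})

test_that("resampling preserves duration and spectral content", {
  rec <- ppg_record(sin(2 * pi * 1.2 * (0:1249) / 125), fs = 125)
  expect_identical(resample_record(rec, 125), rec)     # identity case

  r50 <- resample_record(rec, 50)
  expect_length(r50$samples, 500)                      # 10 s at 50 Hz
  psd <- welch_psd(r50$samples, 50, seg_len = 500)
  f_peak <- psd$freq[which.max(psd$power)]
  expect_equal(f_peak, 1.2, tolerance = 0.05)
})

test_that("edge trimming keeps the interior and rejects unusable sessions", {
  fs <- 10
  rec90 <- ppg_record(rnorm(90 * 60 * fs), fs = fs)
  trimmed <- trim_session(rec90, trim_s = 300)
  expect_equal(length(trimmed$samples) / fs, 80 * 60)  # 80 min retained

  rec11 <- ppg_record(rnorm(11 * 60 * fs), fs = fs)
  expect_equal(length(trim_session(rec11, 300)$samples) / fs, 60)

  rec9 <- ppg_record(rnorm(9 * 60 * fs), fs = fs)
  expect_error(trim_session(rec9, 300), "unusable")
})

test_that("segmentation tiles sessions exactly and inherits metadata", {
  rec <- ppg_record(rnorm(480 * 125), fs = 125, user_id = "U07",
                    session_id = "S1", day_index = 3L)
  w40 <- segment_record(rec, 40)
  expect_length(w40, 12)                    # 480 s / 40 s
  expect_length(segment_record(rec, 6), 80) # floor(480 / 6)
  expect_length(segment_record(ppg_record(rnorm(39 * 125), 125), 40), 0)

  # metadata inherited through trim + segment
  w <- segment_record(trim_session(ppg_record(rnorm(700 * 125), fs = 125,
                                              user_id = "U07", session_id = "S1",
                                              day_index = 3L), 60), 40)
  expect_true(all(vapply(w, `[[`, character(1), "user_id") == "U07"))
  expect_true(all(vapply(w, `[[`, integer(1), "day_index") == 3L))
  expect_equal(w[[1]]$start_s, 60)
  expect_equal(diff(vapply(w, `[[`, numeric(1), "start_s")),
               rep(40, length(w) - 1))
})

test_that("per-user subsampling is exact, balanced and reproducible", {
  # 2 users x 12 days x 4 windows/day
  windows <- list()
  for (u in c("A", "B")) for (d in 0:11) for (k in 0:3) {
    windows <- c(windows, list(make_window(rnorm(10), 5, u, d, k * 2)))
  }
  sel <- subsample_per_user(windows, 24, even_across_days = TRUE, seed = 3)
  meta <- window_meta(sel)
  expect_equal(as.vector(table(meta$user_id)), c(24, 24))
  perday <- table(meta$user_id, meta$day_index)
  expect_true(all(perday == 2))             # 24 over 12 days -> 2 per day

  # exhaustive case: requesting all windows returns all of them
  one_user <- windows[1:8]
  expect_length(subsample_per_user(one_user, 8, seed = 1), 8)

  expect_identical(subsample_per_user(windows, 10, seed = 5),
                   subsample_per_user(windows, 10, seed = 5))
  expect_error(subsample_per_user(windows, 100, seed = 1), "user A")

  # total-count invariant over random configurations
  for (s in 1:5) {
    n_per <- sample(4:20, 1)
    sel <- subsample_per_user(windows, n_per, seed = s)
    expect_equal(nrow(window_meta(sel)), 2 * n_per)
  }
})
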