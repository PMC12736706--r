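# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small laboratory cohort: 10 users, one day, 480 s at 50 Hz -> 12 x 40 s
# windows per user
lab_cohort <- function() {
  fixture("lab_cohort", function() {
    synthesize_cohort(n_users = 10, n_days = 1, session_s = 480, fs = 50,
                      condition = "laboratory", seed = 42)
  })
}

lab_windows_40s <- function() {
  fixture("lab_windows_40s", function() {
    unlist(lapply(lab_cohort(), segment_record, window_s = 40),
           recursive = FALSE)
  })
}

# 30-minute-protocol cohort: sessions long enough for a 1800 s middle
# segment (~45 windows of 40 s per user)
scaling_cohort <- function(condition = "laboratory") {
  fixture(paste0("scaling_cohort_", condition), function() {
    synthesize_cohort(n_users = 10, n_days = 1, session_s = 1920, fs = 50,
                      condition = condition, seed = 42)
  })
}

lab_features_baseline <- function() {
  fixture("lab_features_baseline", function() {
    feature_matrix(lab_windows_40s(), "baseline")
  })
}

# deterministic beat-train profile: fixed morphology, no jitter, no noise
clean_profile <- function(hr = 60) {
  p <- sample_user_profile(1)
  p$hr_mean <- hr; p$hr_sd <- 0; p$noise_sd <- 0
  p$sys_amp <- 1; p$sys_width <- 0.1
  p$dicrotic_amp <- 0.3; p$dicrotic_delay <- 0.35
  p$resp_am_depth <- 0.1; p$resp_bw_amp <- 0.1; p$resp_rate <- 0.25
  p
}

make_window <- function(x, fs, user = "U1", day = 0L, start_s = 0) {
  ppg_window(x, fs, user_id = user, session_id = paste0(user, "_s"),
             day_index = day, start_s = start_s)
}

# Independent MCC oracle: Pearson correlation of one-hot encodings,
# rebuilt sample-by-sample from the confusion counts.
mcc_onehot_oracle <- function(cm) {
  k <- nrow(cm)
  yt <- integer(0); yp <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    yt <- c(yt, rep(i, cm[i, j])); yp <- c(yp, rep(j, cm[i, j]))
  }
  Ti <- outer(yt, seq_len(k), "==") * 1
  Pi <- outer(yp, seq_len(k), "==") * 1
  num <- sum(diag(cov(Ti, Pi)))
  den <- sqrt(sum(diag(cov(Ti))) * sum(diag(cov(Pi))))
  if (den == 0) 0 else num / den
}

# Independent straight-loop reference for the 24 time-domain statistics.
naive_time_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  s2 <- sum((x - mu)^2) / (n - 1)
  s <- sqrt(s2)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  d1 <- x[-1] - x[-n]
  d2 <- d1[-1] - d1[-length(d1)]
  sdd <- sqrt(sum((d1 - mean(d1))^2) / (length(d1) - 1))
  rms <- sqrt(sum(x^2) / n)
  rng <- max(x) - min(x)
  ent <- 0
  if (rng > 0) {
    bins <- pmin(floor((x - min(x)) / rng * 16) + 1, 16)
    p <- as.numeric(table(factor(bins, levels = 1:16))) / n
    p <- p[p > 0]
    ent <- -sum(p * log(p))
  }
  x0 <- x - mu
  zc <- 0
  for (i in 1:(n - 1)) if (x0[i] * x0[i + 1] < 0) zc <- zc + 1
  mob <- if (s == 0) 0 else sdd / s
  sdd2 <- sqrt(sum((d2 - mean(d2))^2) / (length(d2) - 1))
  mobd <- if (sdd == 0) 0 else sdd2 / sdd
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  c(mu, s, s2, min(x), max(x), rng, q[3], q[4] - q[2],
    median(abs(x - q[3])),
    if (m2 == 0) 0 else m3 / m2^1.5,
    if (m2 == 0) 0 else m4 / m2^2 - 3,
    rms, sum(x^2), ent, zc / (n - 1), mean(abs(d1)), sdd, mean(abs(d2)),
    if (s == 0) 0 else cor(x[-n], x[-1]),
    mob, if (mob == 0) 0 else mobd / mob,
    q[1], q[5], if (rms == 0) 0 else max(abs(x)) / rms)
}
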