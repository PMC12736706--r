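test_that("the temporal-split experiment reports both splits and a p-value", {
  out_dir <- withr::local_tempdir()
  cfg <- list(data = list(n_users = 5, n_days = 3, session_s = 120, fs = 50,
                          condition = "real_world", seed = 3),
              method = "baseline_gbt", n_seeds = 5, out_dir = out_dir,
              model = list(nrounds = 40))
  payload <- run_named_experiment("temporal_split", cfg)
  expect_named(payload$reports, c("random_split", "temporal_split"))
  expect_true(is.numeric(payload$wilcoxon_p_temporal_lt_random))
  expect_true(file.exists(file.path(out_dir, "report.json")))
  expect_true(file.exists(file.path(out_dir, "report.csv")))
  log <- readLines(file.path(out_dir, "run_log.txt"))
  expect_match(log[1], "config_hash=")
  expect_length(grep("split=temporal", log), 5)   # one line per seed

  # rerun with the same config: identical CSV (tree models are deterministic)
  csv1 <- readLines(file.path(out_dir, "report.csv"))
  run_named_experiment("temporal_split", cfg)
  expect_identical(readLines(file.path(out_dir, "report.csv")), csv1)
})

test_that("the user-scaling experiment writes one curve row per grid point", {
  out_dir <- withr::local_tempdir()
  cfg <- list(data = list(n_users = 6, n_days = 1, session_s = 240, fs = 50,
                          seed = 4),
              n_users_grid = c(2, 4, 6), n_seeds = 2, out_dir = out_dir,
              middle_s = 240, model = list(nrounds = 40))
  payload <- run_named_experiment("user_scaling", cfg)
  expect_equal(nrow(payload$curve), 3)
  csv <- utils::read.csv(file.path(out_dir, "scaling_curve.csv"))
  expect_equal(csv$n_users, c(2, 4, 6))
})

test_that("unknown experiment names list the valid ones", {
  expect_error(run_named_experiment("nope", list()),
               "benchmark_identification.*temporal_split")
})

test_that("configs load from YAML files", {
  out_dir <- withr::local_tempdir()
  cfg_path <- file.path(out_dir, "cfg.yaml")
  writeLines(c("data:", "  n_users: 4", "  n_days: 1", "  session_s: 120",
               "  fs: 50", "  seed: 5", "n_seeds: 2",
               "split_kind: random", "method: random_id",
               paste0("out_dir: ", out_dir)), cfg_path)
  payload <- run_named_experiment("benchmark_identification", cfg_path)
  expect_named(payload$reports, c("method", "random_baseline"))
})

test_that("guideline adherence is scored pass/fail/unknown per rule", {
  full <- guideline_report(list(
    n_users = 42, min_days_per_user = 26, conditions = "real_world",
    split_kinds = c("random", "temporal"), unseen_users_tested = TRUE,
    metrics = c("accuracy", "MCC"), documented = TRUE,
    open_code = TRUE, open_data = FALSE))
  expect_equal(nrow(full), 11)
  get <- function(id) full$status[full$id == id]
  expect_equal(get("longitudinal_data"), "pass")
  expect_equal(get("n_users_gt_35"), "pass")
  expect_equal(get("temporal_split"), "pass")
  expect_equal(get("balanced_evaluation"), "pass")
  expect_equal(get("open_data"), "fail")
  # demographic fields absent -> unknown, never a silent pass
  expect_equal(get("demographic_diversity"), "unknown")
  expect_equal(get("health_condition_diversity"), "unknown")

  single_day <- guideline_report(list(min_days_per_user = 1))
  expect_equal(single_day$status[single_day$id == "longitudinal_data"], "fail")
})
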