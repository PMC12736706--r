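#' Feature matrix for a list of windows
#'
#' @param windows List of [ppg_window()]s.
#' @param extractor `"baseline"` (160 features) or `"hinatsu"` (38).
#' @return List: `X` (numeric matrix, one row per window) and `meta`
#'   ([window_meta()] data.frame).
#' @export
feature_matrix <- function(windows, extractor = c("baseline", "hinatsu")) {
  extractor <- match.arg(extractor)
  fn <- switch(extractor, baseline = baseline_features, hinatsu = hinatsu_features)
  rows <- lapply(windows, fn)
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- names(rows[[1]])
  list(X = X, meta = window_meta(windows))
}

method_info <- function(method) {
  switch(method,
    hinatsu_rf = list(task = "identification", extractor = "hinatsu", kind = "forest_id"),
    baseline_gbt = list(task = "identification", extractor = "baseline", kind = "gbt_id"),
    random_id = list(task = "identification", extractor = NULL, kind = "random"),
    seok_siamese = list(task = "re-identification", extractor = "template", kind = "siamese_reid"),
    baseline_gbt_reid = list(task = "re-identification", extractor = "baseline", kind = "gbt_reid"),
    random_reid = list(task = "re-identification", extractor = NULL, kind = "random"),
    stop("unknown method: ", method,
         " (valid: hinatsu_rf, baseline_gbt, random_id, seok_siamese, ",
         "baseline_gbt_reid, random_reid)")
  )
}

new_metric_report <- function(per_seed, method, split_kind, config) {
  means <- colMeans(per_seed[, c("accuracy", "balanced_accuracy", "mcc"), drop = FALSE])
  n <- nrow(per_seed)
  ses <- apply(per_seed[, c("accuracy", "balanced_accuracy", "mcc"), drop = FALSE],
               2, stats::sd) / sqrt(n)
  if (n == 1) ses[] <- 0   # degenerate single-seed report: zero-width
  structure(list(per_seed = per_seed,
                 mean = means, se = ses, n_seeds = n,
                 method = method, split_kind = split_kind,
                 config_hash = fnv1a_hash(config)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s / %s split (%d seeds)\n",
              x$method, x$split_kind, x$n_seeds))
  for (m in names(x$mean)) {
    cat(sprintf("  %-18s %.3f +/- %.3f\n", m, x$mean[m], x$se[m]))
  }
  invisible(x)
}

run_identification_seed <- function(X, meta, kind, split_kind, config, seed) {
  split_params <- config$split_params %||% list()
  eval_plan <- function(plan) {
    y_tr <- meta$user_id[plan$train_ids]
    y_te <- meta$user_id[plan$test_ids]
    y_hat <- if (kind == "random") {
      random_baseline(y_tr, length(y_te), seed = seed)
    } else {
      m <- train_identifier(X[plan$train_ids, , drop = FALSE], y_tr, kind,
                            config = config$model %||% list(), seed = seed)
      predict_identifier(m, X[plan$test_ids, , drop = FALSE])
    }
    list(true = y_te, pred = y_hat)
  }
  if (split_kind == "loo") {
    folds <- plan_split(meta, "loo")
    out <- lapply(folds, eval_plan)
    truth <- unlist(lapply(out, `[[`, "true"))
    preds <- unlist(lapply(out, `[[`, "pred"))
  } else {
    plan <- plan_split(meta, split_kind, split_params, seed = seed)
    res <- eval_plan(plan)
    truth <- res$true; preds <- res$pred
  }
  classification_metrics(truth, preds, sort(unique(c(truth, preds, meta$user_id))))
}

run_reid_seed <- function(items, meta, kind, split_kind, config, seed) {
  split_params <- config$split_params %||% list()
  plan <- plan_split(meta, split_kind, split_params, seed = seed)
  pair_args <- function(ids) {
    cap <- config$max_pairs
    if (is.null(cap)) {
      make_pairs(items[ids], "all_unordered", user_ids = meta$user_id[ids])
    } else {
      make_pairs(items[ids], "capped", cap = cap, seed = seed,
                 user_ids = meta$user_id[ids])
    }
  }
  test_pairs <- pair_args(plan$test_ids)
  if (kind == "random") {
    dec <- as.integer(random_baseline(c(0, 1), nrow(test_pairs$pairs), seed = seed))
    truth <- test_pairs$pairs$label
  } else {
    train_pairs <- pair_args(plan$train_ids)
    m <- train_reid(train_pairs, kind, config = config$model %||% list(), seed = seed)
    pr <- predict_reid(m, test_pairs, threshold = config$threshold %||% 0.5)
    dec <- pr$decision
    truth <- pr$label
  }
  classification_metrics(as.character(truth), as.character(dec), c("0", "1"))
}

#' Run one evaluation protocol over repeated seeds
#'
#' Trains and evaluates one method under one split kind, repeated over
#' `n_seeds` seeds (default ten, seeds 0-9); each seed controls the model
#' initialisation and, for random splits, the split draw. Reports
#' per-seed accuracy, balanced accuracy and multi-class MCC with means and
#' standard errors (`sd / sqrt(n_seeds)`).
#'
#' @param windows List of [ppg_window()]s.
#' @param method One of `"hinatsu_rf"`, `"baseline_gbt"`, `"random_id"`
#'   (identification); `"seok_siamese"`, `"baseline_gbt_reid"`,
#'   `"random_reid"` (re-identification).
#' @param split_kind `"random"`, `"temporal"`, `"loo"` or `"predefined"`
#'   (identification); `"random"`, `"temporal"` or `"predefined"`
#'   (re-identification pairs are formed within each side of the split).
#' @param n_seeds Number of seeds.
#' @param config List: `seeds` (explicit seed vector), `split_params`,
#'   `model` (hyperparameter overrides), `max_pairs`, `threshold`,
#'   `template_L`.
#' @return A `metric_report`.
#' @export
run_experiment <- function(windows, method, split_kind = "random",
                           n_seeds = 10, config = list()) {
  info <- method_info(method)
  seeds <- config$seeds %||% (seq_len(n_seeds) - 1L)
  if (info$task == "identification") {
    if (is.null(info$extractor)) {
      fm <- list(X = NULL, meta = window_meta(windows))
    } else {
      fm <- feature_matrix(windows, info$extractor)
    }
    per <- lapply(seeds, function(s) {
      run_identification_seed(fm$X, fm$meta, info$kind, split_kind, config, s)
    })
  } else {
    if (split_kind == "loo") stop("leave-one-out is an identification protocol")
    if (identical(info$extractor, "template")) {
      L <- config$template_L %||% 100
      items <- lapply(windows, cycle_template, L = L)
      ok <- !vapply(items, is.null, logical(1))
      if (!all(ok)) {
        message(sprintf("dropping %d window(s) with < 2 detected beats", sum(!ok)))
      }
      items <- items[ok]
      meta <- window_meta(windows[ok])
    } else if (is.null(info$extractor)) {
      items <- windows
      meta <- window_meta(windows)
    } else {
      fm <- feature_matrix(windows, info$extractor)
      items <- lapply(seq_len(nrow(fm$X)), function(i) {
        feature_vector(fm$X[i, ], colnames(fm$X), extractor_id = info$extractor)
      })
      meta <- fm$meta
    }
    per <- lapply(seeds, function(s) {
      run_reid_seed(items, meta, info$kind, split_kind, config, s)
    })
  }
  per_seed <- cbind(data.frame(seed = seeds), do.call(rbind, per))
  new_metric_report(per_seed, method, split_kind, config)
}

prepare_scaling_windows <- function(cohort, middle_s, window_s) {
  windows <- list()
  for (rec in cohort) {
    seg <- middle_segment(rec, middle_s)
    windows <- c(windows, segment_record(seg, window_s))
  }
  windows
}

#' MCC as a function of the number of enrolled users
#'
#' For each user count n in the grid: sample n users, take each user's
#' central `middle_s`-second segment cut into `window_s` windows, hold out
#' a random `test_frac`, train the identifier and score it, alongside the
#' uniform random baseline. Repeated over `n_seeds` seeds per grid point.
#' Features are extracted once for the full cohort and reused.
#'
#' @param cohort A `ppg_cohort` (single-day records).
#' @param n_users_grid Increasing user counts (max <= cohort users).
#' @param method Identification method (default `"baseline_gbt"`).
#' @param n_seeds Seeds per grid point.
#' @param seed Master seed.
#' @param config List: `middle_s` (default 1800), `window_s` (40),
#'   `test_frac` (0.3), `model` overrides.
#' @return data.frame of class `scaling_curve`: one row per grid point with
#'   mean/se MCC and accuracy for the method and the random baseline;
#'   per-seed values attached as attribute `per_seed`.
#' @export
user_scaling_curve <- function(cohort, n_users_grid, method = "baseline_gbt",
                               n_seeds = 10, seed = 0, config = list()) {
  info <- method_info(method)
  if (info$task != "identification") stop("user scaling is an identification protocol")
  windows <- prepare_scaling_windows(cohort, config$middle_s %||% 1800,
                                     config$window_s %||% 40)
  fm <- feature_matrix(windows, info$extractor %||% "baseline")
  users <- sort(unique(fm$meta$user_id))
  if (max(n_users_grid) > length(users)) {
    stop("grid exceeds cohort size (", length(users), " users)")
  }
  test_frac <- config$test_frac %||% 0.3
  seeds <- derive_seeds(seed, n_seeds)
  rows <- list(); per_seed <- list()
  for (n in n_users_grid) {
    vals <- lapply(seq_len(n_seeds), function(si) {
      s <- seeds[si]
      sel_users <- with_seed(s, sample_exact(users, n))
      ids <- which(fm$meta$user_id %in% sel_users)
      meta_n <- fm$meta[ids, , drop = FALSE]
      plan <- plan_split(meta_n, "random", list(test_frac = test_frac), seed = s)
      tr <- ids[plan$train_ids]; te <- ids[plan$test_ids]
      mod <- train_identifier(fm$X[tr, , drop = FALSE], fm$meta$user_id[tr],
                              info$kind, config = config$model %||% list(), seed = s)
      y_hat <- predict_identifier(mod, fm$X[te, , drop = FALSE])
      mm <- classification_metrics(fm$meta$user_id[te], y_hat, sel_users)
      rb <- random_baseline(fm$meta$user_id[tr], length(te), seed = s)
      bb <- classification_metrics(fm$meta$user_id[te], rb, sel_users)
      c(mm, baseline_accuracy = unname(bb["accuracy"]), baseline_mcc = unname(bb["mcc"]))
    })
    V <- do.call(rbind, vals)
    per_seed[[as.character(n)]] <- cbind(n_users = n, seed = seeds, as.data.frame(V))
    rows[[as.character(n)]] <- data.frame(
      n_users = n,
      mean_mcc = mean(V[, "mcc"]), se_mcc = stats::sd(V[, "mcc"]) / sqrt(n_seeds),
      mean_accuracy = mean(V[, "accuracy"]),
      se_accuracy = stats::sd(V[, "accuracy"]) / sqrt(n_seeds),
      baseline_mean_accuracy = mean(V[, "baseline_accuracy"]),
      baseline_mean_mcc = mean(V[, "baseline_mcc"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("scaling_curve", "data.frame"),
            per_seed = do.call(rbind, per_seed))
}

#' Closed-set identification under unseen users
#'
#' Trains on `n_train_users` known users only, then evaluates on the known
#' users' held-out windows plus all windows of j unseen users for each j in
#' `unseen_grid` (unseen-user sets are nested across j). The confusion
#' matrix is built over the union of known and unseen labels; because a
#' closed-set identifier can only emit training labels, every unseen window
#' is misassigned by construction, and MCC decays as j grows.
#'
#' @param cohort A `ppg_cohort` (single-day records).
#' @param n_train_users Known users enrolled in training.
#' @param unseen_grid Numbers of unseen users to add (0 = closed set).
#' @param method Identification method.
#' @param n_seeds Seeds.
#' @param seed Master seed.
#' @param config As in [user_scaling_curve()]; `known_test_frac` (0.3).
#' @return data.frame of class `unseen_curve`: per j, mean/se MCC and the
#'   observed fraction of unseen windows misassigned (always 1);
#'   per-seed values attached as attribute `per_seed`.
#' @export
unseen_user_eval <- function(cohort, n_train_users = 15,
                             unseen_grid = c(0, 9, 18, 27),
                             method = "baseline_gbt", n_seeds = 10, seed = 0,
                             config = list()) {
  info <- method_info(method)
  if (info$task != "identification") stop("unseen-user evaluation needs an identification method")
  windows <- prepare_scaling_windows(cohort, config$middle_s %||% 1800,
                                     config$window_s %||% 40)
  fm <- feature_matrix(windows, info$extractor %||% "baseline")
  users <- sort(unique(fm$meta$user_id))
  if (n_train_users + max(unseen_grid) > length(users)) {
    stop("cohort has too few users for n_train_users + max(unseen_grid)")
  }
  test_frac <- config$known_test_frac %||% 0.3
  seeds <- derive_seeds(seed, n_seeds)
  acc <- list()
  for (si in seq_len(n_seeds)) {
    s <- seeds[si]
    known <- with_seed(s, sample_exact(users, n_train_users))
    unseen_pool <- with_seed(s + 1, sample(setdiff(users, known)))
    kid <- which(fm$meta$user_id %in% known)
    meta_k <- fm$meta[kid, , drop = FALSE]
    plan <- plan_split(meta_k, "random", list(test_frac = test_frac), seed = s)
    tr <- kid[plan$train_ids]; te_known <- kid[plan$test_ids]
    mod <- train_identifier(fm$X[tr, , drop = FALSE], fm$meta$user_id[tr],
                            info$kind, config = config$model %||% list(), seed = s)
    for (j in unseen_grid) {
      uj <- unseen_pool[seq_len(j)]
      te_unseen <- which(fm$meta$user_id %in% uj)
      te <- c(te_known, te_unseen)
      y_hat <- predict_identifier(mod, fm$X[te, , drop = FALSE])
      y_true <- fm$meta$user_id[te]
      labels <- sort(unique(c(known, uj)))
      mm <- classification_metrics(y_true, y_hat, labels)
      mis <- if (length(te_unseen)) {
        mean(y_hat[match(te_unseen, te)] != y_true[match(te_unseen, te)])
      } else NA_real_
      acc[[length(acc) + 1]] <- data.frame(
        n_unseen = j, seed = s, accuracy = mm["accuracy"],
        balanced_accuracy = mm["balanced_accuracy"], mcc = mm["mcc"],
        unseen_misassigned = mis, n_unseen_windows = length(te_unseen))
    }
  }
  per_seed <- do.call(rbind, acc)
  rownames(per_seed) <- NULL
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$n_unseen), function(d) {
    data.frame(n_unseen = d$n_unseen[1],
               mean_mcc = mean(d$mcc), se_mcc = stats::sd(d$mcc) / sqrt(nrow(d)),
               mean_accuracy = mean(d$accuracy),
               unseen_misassigned = mean(d$unseen_misassigned),
               n_unseen_windows = d$n_unseen_windows[1])
  }))
  rownames(agg) <- NULL
  structure(agg[order(agg$n_unseen), ], class = c("unseen_curve", "data.frame"),
            per_seed = per_seed)
}
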