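sep_features <- function(n_users = 2, n_per = 10, noise = 0.05, seed = 1) {
  # well-separated synthetic feature clusters
  set.seed(seed)
  centers <- matrix(rnorm(n_users * 8, sd = 3), n_users)
  X <- do.call(rbind, lapply(seq_len(n_users), function(u) {
    sweep(matrix(rnorm(n_per * 8, sd = noise), n_per), 2, centers[u, ], "+")
  }))
  colnames(X) <- sprintf("f%d", 1:8)
  list(X = X, y = rep(sprintf("u%02d", seq_len(n_users)), each = n_per))
}

test_that("identifiers fit separable data and are seed-deterministic", {
  d <- sep_features()
  for (kind in c("forest_id", "gbt_id")) {
    m <- train_identifier(d$X, d$y, kind, config = list(nrounds = 50), seed = 1)
    expect_equal(mean(predict_identifier(m, d$X) == d$y), 1)  # separable case
    m2 <- train_identifier(d$X, d$y, kind, config = list(nrounds = 50), seed = 1)
    expect_identical(predict_identifier(m2, d$X), predict_identifier(m, d$X))
  }
  expect_error(train_identifier(d$X, rep("u01", nrow(d$X)), "gbt_id"),
               "2 distinct")
})

test_that("permuted labels yield chance-level out-of-sample MCC", {
  d <- sep_features(4, 30, seed = 2)
  mccs <- vapply(1:10, function(s) {
    set.seed(s)
    y_perm <- sample(d$y)   # destroy the label-feature link
    tr <- seq_len(nrow(d$X)) %% 3 != 0
    m <- train_identifier(d$X[tr, ], y_perm[tr], "gbt_id",
                          config = list(nrounds = 30), seed = s)
    unname(classification_metrics(y_perm[!tr],
                                  predict_identifier(m, d$X[!tr, ]))["mcc"])
  }, numeric(1))
  expect_lt(max(abs(mccs)), 0.35)
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("identifiers are closed-set: outputs never leave class_labels", {
  d <- sep_features(3, 10)
  m <- train_identifier(d$X, d$y, "forest_id", seed = 1)
  # memorisation: training rows come back with training labels
  expect_equal(predict_identifier(m, d$X[c(1, 15, 25), ]), d$y[c(1, 15, 25)])
  # arbitrary inputs, including windows of unseen users, stay in the set
  set.seed(4)
  Xnew <- matrix(rnorm(50 * 8, sd = 5), 50, dimnames = list(NULL, colnames(d$X)))
  expect_true(all(predict_identifier(m, Xnew) %in% m$class_labels))
  # unseen-user windows are 0% correct by construction
  expect_equal(sum(predict_identifier(m, Xnew) == "unseen_user"), 0)
  expect_error(predict_identifier(m, Xnew[, 1:4]), "dimensionality")
})

test_that("pair construction enumerates and labels correctly", {
  mk <- function(u) structure(rnorm(4), user_id = u)
  items10 <- lapply(sprintf("u%d", 1:10), mk)
  expect_equal(nrow(make_pairs(items10)$pairs), 45)   # n(n-1)/2

  # 2 users x 2 samples: 2 positive, 4 negative pairs
  items4 <- lapply(c("a", "a", "b", "b"), mk)
  p4 <- make_pairs(items4)$pairs
  expect_equal(sum(p4$label == 1), 2)
  expect_equal(sum(p4$label == 0), 4)

  # cap above the population returns everything, silently
  expect_equal(nrow(make_pairs(items10, "capped", cap = 100)$pairs), 45)
  # cap below subsamples, preserving the ratio, with a warning
  expect_warning(pc <- make_pairs(lapply(rep(c("a", "b"), each = 10), mk),
                                  "capped", cap = 50, seed = 1),
                 "exhaustive")
  expect_equal(nrow(pc$pairs), 50)
  expect_error(make_pairs(items10, "capped", cap = 1), "cap >= 2")
})

test_that("pair vectors concatenate with disjoint prefixed names", {
  a <- feature_vector(1:3, c("x", "y", "z"), "demo")
  b <- feature_vector(4:6, c("x", "y", "z"), "demo")
  pv <- pair_vector(a, b)
  expect_length(pv, 6)
  expect_identical(names(pv), c("left_x", "left_y", "left_z",
                                "right_x", "right_y", "right_z"))
  self <- pair_vector(a, a)
  expect_equal(unname(self[1:3]), unname(self[4:6]))
  bad <- feature_vector(1:3, c("x", "y", "z"), "other")
  expect_error(pair_vector(a, bad), "extractor mismatch")
})

test_that("pairwise gradient boosting separates users on held-out pairs", {
  d <- sep_features(4, 8, seed = 3)
  items <- lapply(seq_len(nrow(d$X)), function(i) {
    structure(feature_vector(d$X[i, ], colnames(d$X), "demo"),
              user_id = d$y[i])
  })
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    te <- sample(length(items), 10)
    m <- train_reid(make_pairs(items[-te]), "gbt_reid",
                    config = list(nrounds = 60), seed = s)
    pr <- predict_reid(m, make_pairs(items[te]))
    mean(pr$decision == pr$label)
  }, numeric(1))
  expect_gt(mean(accs), 0.9)   # separable laboratory-style benchmark

  # shuffled pair labels -> chance-level MCC
  set.seed(9)
  items_shuf <- lapply(items, function(it) {
    attr(it, "user_id") <- sample(d$y, 1); it
  })
  m0 <- train_reid(make_pairs(items_shuf[1:24]), "gbt_reid",
                   config = list(nrounds = 40), seed = 1)
  pr0 <- predict_reid(m0, make_pairs(items_shuf[25:32]))
  expect_lt(abs(classification_metrics(as.character(pr0$label),
                                       as.character(pr0$decision),
                                       c("0", "1"))["mcc"]), 0.5)

  single <- make_pairs(lapply(rep("a", 4), function(u) {
    structure(feature_vector(rnorm(3), c("x", "y", "z"), "demo"), user_id = u)
  }))
  expect_error(train_reid(single, "gbt_reid"), "both same-user and different")
})

test_that("the Siamese network scores pairs sensibly and reproducibly", {
  # cycle templates from a small synthetic cohort
  coh <- synthesize_cohort(4, 1, 60, 50, "laboratory", seed = 13)
  windows <- unlist(lapply(coh, segment_record, window_s = 6), recursive = FALSE)
  items <- lapply(windows, function(w) {
    tpl <- cycle_template(w)
    if (is.null(tpl)) NULL else structure(tpl, user_id = w$user_id)
  })
  items <- Filter(Negate(is.null), items)
  pairs <- make_pairs(items)
  m <- train_reid(pairs, "siamese_reid",
                  config = list(epochs = 10, batch = 32), seed = 1)
  pr <- predict_reid(m, pairs)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  # metric-learning sanity: same-user pairs score higher on average
  expect_gt(mean(pr$score[pr$label == 1]), mean(pr$score[pr$label == 0]))

  # fixed seed reproduces the scores
  m2 <- train_reid(pairs, "siamese_reid",
                   config = list(epochs = 10, batch = 32), seed = 1)
  expect_equal(predict_reid(m2, pairs)$score, pr$score, tolerance = 1e-6)

  # threshold boundaries
  expect_true(all(predict_reid(m, pairs, threshold = 0)$decision == 1))
  expect_true(all(predict_reid(m, pairs, threshold = 1 + 1e-9)$decision == 0))
})

test_that("models round-trip through save/load", {
  d <- sep_features()
  m <- train_identifier(d$X, d$y, "gbt_id", config = list(nrounds = 20), seed = 1)
  dir <- withr::local_tempdir()
  save_model(m, file.path(dir, "m1"))
  m2 <- load_model(file.path(dir, "m1"))
  expect_identical(predict_identifier(m2, d$X), predict_identifier(m, d$X))
  meta <- jsonlite::read_json(file.path(dir, "m1", "meta.json"))
  expect_identical(meta$kind, "gbt_id")
})
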