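#' Train a closed-set user identifier
#'
#' Two tree-ensemble identifiers over feature matrices:
#' * `forest_id`: random forest (500 trees, unlimited depth, sqrt-features
#'   per split) via \pkg{ranger};
#' * `gbt_id`: gradient-boosted trees (300 rounds, depth 6, learning rate
#'   0.1, subsample 0.8) via \pkg{xgboost} with a softmax multi-class
#'   objective.
#'
#' The fitted model stores `class_labels = sort(unique(y))` and can only
#' ever emit labels from that set -- the closed-set property that forces
#' unseen users to be misassigned.
#'
#' @param X Numeric feature matrix (rows = windows) with column names.
#' @param y User labels (>= 2 distinct).
#' @param kind `"forest_id"` or `"gbt_id"`.
#' @param config Optional overrides: `num_trees`, `nrounds`, `max_depth`,
#'   `eta`, `subsample`.
#' @param seed Integer seed; training is deterministic for a fixed seed.
#' @return Object of class `ppg_model`.
#' @export
train_identifier <- function(X, y, kind = c("forest_id", "gbt_id"),
                             config = list(), seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  class_labels <- sort(unique(y))
  if (length(class_labels) < 2) stop("need at least 2 distinct user labels")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))

  fit <- with_seed(seed, {
    if (kind == "forest_id") {
      ranger::ranger(x = X, y = factor(y, levels = class_labels),
                     num.trees = config$num_trees %||% 500,
                     mtry = floor(sqrt(ncol(X))), min.node.size = 1,
                     seed = seed, num.threads = 1)
    } else {
      dtrain <- xgboost::xgb.DMatrix(X, label = match(y, class_labels) - 1)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(class_labels),
                      max_depth = config$max_depth %||% 6,
                      eta = config$eta %||% 0.1,
                      subsample = config$subsample %||% 0.8,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = config$nrounds %||% 300, verbose = 0)
    }
  })
  structure(list(kind = kind, class_labels = class_labels, fit = fit,
                 seed = seed, feature_names = colnames(X), config = config),
            class = "ppg_model")
}

#' @export
print.ppg_model <- function(x, ...) {
  cat(sprintf("<ppg_model> %s%s\n", x$kind,
              if (!is.null(x$class_labels))
                sprintf(" over %d classes", length(x$class_labels)) else ""))
  invisible(x)
}

#' Predict user labels with a closed-set identifier
#'
#' Every prediction is drawn from the model's `class_labels`; windows of
#' users absent from training are necessarily assigned to a known user.
#'
#' @param model A `ppg_model` of an identification kind.
#' @param X Feature matrix with the training columns.
#' @return Character vector of predicted labels.
#' @export
predict_identifier <- function(model, X) {
  stopifnot(inherits(model, "ppg_model"))
  if (!model$kind %in% c("forest_id", "gbt_id")) {
    stop("model kind ", model$kind, " is not an identification model")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  if (ncol(X) != length(model$feature_names) ||
      !all(colnames(X) == model$feature_names)) {
    stop("feature dimensionality/names do not match training")
  }
  if (model$kind == "forest_id") {
    as.character(stats::predict(model$fit, data = X, num.threads = 1)$predictions)
  } else {
    pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
    P <- if (is.matrix(pr)) pr else
      matrix(pr, ncol = length(model$class_labels), byrow = TRUE)
    model$class_labels[max.col(P, ties.method = "first")]
  }
}

item_user <- function(x) {
  u <- attr(x, "user_id", exact = TRUE)
  if (!is.null(u)) return(u)
  if (is.list(x) && !is.null(x$user_id)) return(x$user_id)
  NA_character_
}

#' Cross-reference items into labelled same-user pairs
#'
#' `all_unordered` enumerates all n(n-1)/2 unordered pairs (the exhaustive
#' pairing a Siamese re-identifier is trained on); `capped` draws a
#' seed-reproducible stratified subsample of at most `cap` pairs preserving
#' the positive/negative ratio, and warns that this departs from exhaustive
#' pairing.
#'
#' @param items List of items carrying user metadata ([ppg_window()]s,
#'   feature vectors or templates with a `user_id` attribute).
#' @param mode `"all_unordered"` or `"capped"`.
#' @param cap Maximum pairs for `capped` mode (>= 2).
#' @param seed Integer seed.
#' @param user_ids Optional explicit user label per item (overrides
#'   item metadata).
#' @return Object of class `pair_set`: the items plus an index table
#'   `(i, j, label)` with `label = 1` iff both items share a user.
#' @export
make_pairs <- function(items, mode = c("all_unordered", "capped"), cap = NULL,
                       seed = 1, user_ids = NULL) {
  mode <- match.arg(mode)
  n <- length(items)
  if (n < 2) stop("need at least 2 items to pair")
  if (is.null(user_ids)) user_ids <- vapply(items, item_user, character(1))
  if (anyNA(user_ids)) stop("items without user metadata")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2])
  pairs$label <- as.integer(user_ids[pairs$i] == user_ids[pairs$j])
  if (mode == "capped") {
    if (is.null(cap) || cap < 2) stop("capped mode needs cap >= 2")
    if (nrow(pairs) > cap) {
      warning("subsampling ", cap, " of ", nrow(pairs),
              " pairs; this departs from exhaustive pairing")
      pos <- which(pairs$label == 1)
      neg <- which(pairs$label == 0)
      n_pos <- max(1L, min(length(pos), round(cap * length(pos) / nrow(pairs))))
      n_neg <- cap - n_pos
      keep <- with_seed(seed, c(sample_exact(pos, n_pos), sample_exact(neg, n_neg)))
      pairs <- pairs[sort(keep), , drop = FALSE]
    }
  }
  structure(list(items = items, pairs = pairs, user_ids = user_ids),
            class = "pair_set")
}

#' Concatenate two feature vectors into one pair vector
#'
#' @param a,b [feature_vector()]s from the same extractor.
#' @return A [feature_vector()] of length `length(a) + length(b)` with
#'   `left_`/`right_`-prefixed names.
#' @export
pair_vector <- function(a, b) {
  ea <- attr(a, "extractor_id"); eb <- attr(b, "extractor_id")
  if (!identical(ea, eb)) stop("extractor mismatch: ", ea, " vs ", eb)
  feature_vector(c(as.numeric(a), as.numeric(b)),
                 c(paste0("left_", names(a)), paste0("right_", names(b))),
                 extractor_id = paste0("pair_", ea))
}

pairset_matrices <- function(pairs) {
  items <- pairs$items
  first <- items[[1]]
  if (inherits(first, "feature_vector")) {
    M <- do.call(rbind, lapply(items, as.numeric))
    colnames(M) <- names(first)
  } else {
    M <- do.call(rbind, lapply(items, as.numeric))
    colnames(M) <- sprintf("s%03d", seq_len(ncol(M)))
  }
  list(left = M[pairs$pairs$i, , drop = FALSE],
       right = M[pairs$pairs$j, , drop = FALSE],
       label = pairs$pairs$label)
}

#' Train a pairwise re-identifier
#'
#' * `gbt_reid` consumes concatenated feature-vector pairs through
#'   gradient-boosted trees; because concatenation is ordered, training
#'   augments every pair with both orders so the decision is effectively
#'   symmetric.
#' * `siamese_reid` consumes standardised cycle templates through two
#'   weight-shared 1D convolutional branches whose embedding distance
#'   drives a same/different sigmoid score (see package docs for the
#'   architecture).
#'
#' @param pairs A `pair_set` from [make_pairs()]; items must be feature
#'   vectors (`gbt_reid`) or equal-length numeric templates
#'   (`siamese_reid`). Both labels must be present.
#' @param kind `"gbt_reid"` or `"siamese_reid"`.
#' @param config Hyperparameter overrides (`nrounds`, `epochs`, `lr`,
#'   `batch`, ...).
#' @param seed Integer seed.
#' @return Object of class `ppg_model`.
#' @export
train_reid <- function(pairs, kind = c("gbt_reid", "siamese_reid"),
                       config = list(), seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(pairs, "pair_set"))
  mats <- pairset_matrices(pairs)
  if (length(unique(mats$label)) < 2) {
    stop("pair set must contain both same-user and different-user pairs")
  }
  fit <- with_seed(seed, {
    if (kind == "gbt_reid") {
      Xa <- cbind(mats$left, mats$right)
      Xb <- cbind(mats$right, mats$left)
      colnames(Xa) <- colnames(Xb) <-
        c(paste0("left_", colnames(mats$left)), paste0("right_", colnames(mats$right)))
      X <- rbind(Xa, Xb)                      # order augmentation
      ylab <- c(mats$label, mats$label)
      dtrain <- xgboost::xgb.DMatrix(X, label = ylab)
      list(kind = "xgb",
           model = xgboost::xgb.train(
             params = list(objective = "binary:logistic",
                           max_depth = config$max_depth %||% 6,
                           eta = config$eta %||% 0.1,
                           subsample = config$subsample %||% 0.8,
                           nthread = 1, seed = seed),
             data = dtrain, nrounds = config$nrounds %||% 300, verbose = 0),
           feature_names = colnames(Xa))
    } else {
      list(kind = "siamese",
           model = siamese_train(mats$left, mats$right, mats$label,
                                 config = config, seed = seed))
    }
  })
  structure(list(kind = kind, class_labels = NULL, fit = fit, seed = seed,
                 config = config), class = "ppg_model")
}

#' Score pairs with a trained re-identifier
#'
#' @param model A `ppg_model` of a re-identification kind.
#' @param pairs A `pair_set` of the same item kind used in training.
#' @param threshold Decision threshold on the same-user score.
#' @return data.frame with `score` in `[0, 1]`, binary `decision`, and the
#'   ground-truth `label`.
#' @export
predict_reid <- function(model, pairs, threshold = 0.5) {
  stopifnot(inherits(model, "ppg_model"))
  if (!model$kind %in% c("gbt_reid", "siamese_reid")) {
    stop("model kind ", model$kind, " is not a re-identification model")
  }
  mats <- pairset_matrices(pairs)
  score <- if (model$kind == "gbt_reid") {
    X <- cbind(mats$left, mats$right)
    colnames(X) <- model$fit$feature_names
    stats::predict(model$fit$model, xgboost::xgb.DMatrix(X))
  } else {
    siamese_predict(model$fit$model, mats$left, mats$right)
  }
  data.frame(score = as.numeric(score),
             decision = as.integer(score >= threshold),
             label = mats$label)
}

#' Save / load a trained model
#'
#' Writes a directory with a JSON metadata file (`kind`, `class_labels`,
#' `seed`, config, package version) and the fitted state.
#'
#' @param model A `ppg_model`.
#' @param path Directory to create.
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppg_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = model$kind, class_labels = model$class_labels,
               seed = model$seed, config = model$config,
               feature_names = model$feature_names,
               package_version = as.character(utils::packageVersion("ppgbiom")))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  saveRDS(model, file.path(path, "model.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(file.path(path, "model.rds"))
}
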