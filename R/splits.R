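#' Plan a train/test split
#'
#' Split planners over a list of windows (or any items with window-style
#' metadata):
#' * `random`: seeded random draw of `params$test_frac` (default 0.3) of
#'   the items.
#' * `temporal`: per user, items are ordered chronologically by
#'   `(day_index, start_s)`; the first `params$train_frac` (default 0.5)
#'   trains and the rest tests, so every training item strictly precedes
#'   every test item of the same user. Errors when a user's chronology
#'   carries no usable ordering.
#' * `loo`: returns a list of n single-item-test folds (leave-one-out).
#' * `predefined`: passthrough of `params$train_ids` / `params$test_ids`
#'   (checked for disjointness).
#'
#' @param items List of [ppg_window()]s, or a data.frame with `user_id`,
#'   `day_index`, `start_s` columns.
#' @param kind One of `"random"`, `"temporal"`, `"loo"`, `"predefined"`.
#' @param params Named list of parameters (see above).
#' @param seed Integer seed (random kind only).
#' @return A `split_plan` (list with `train_ids`, `test_ids`, `kind`), or a
#'   list of plans for `kind = "loo"`.
#' @export
plan_split <- function(items, kind = c("random", "temporal", "loo", "predefined"),
                       params = list(), seed = 1) {
  kind <- match.arg(kind)
  meta <- if (is.data.frame(items)) items else window_meta(items)
  n <- nrow(meta)
  if (n < 2) stop("need at least 2 items to split")
  new_plan <- function(train, test, k = kind) {
    if (length(intersect(train, test))) stop("train/test overlap")
    structure(list(train_ids = sort(train), test_ids = sort(test), kind = k),
              class = "split_plan")
  }
  switch(kind,
    random = {
      frac <- params$test_frac %||% 0.3
      n_test <- max(1L, round(frac * n))
      test <- with_seed(seed, sample.int(n, n_test))
      new_plan(setdiff(seq_len(n), test), test)
    },
    temporal = {
      frac <- params$train_frac %||% 0.5
      train <- integer(0); test <- integer(0)
      for (u in unique(meta$user_id)) {
        iu <- which(meta$user_id == u)
        key <- order(meta$day_index[iu], meta$start_s[iu])
        ord <- iu[key]
        ks <- paste(meta$day_index[ord], meta$start_s[ord])
        if (length(unique(ks)) < 2) {
          stop(sprintf("user %s has no temporal ordering (single day, no session order)", u))
        }
        k <- floor(length(ord) * frac)
        k <- max(1L, min(k, length(ord) - 1L))
        # boundary must be strict in time: back off over ties
        while (k > 1 && ks[k] == ks[k + 1]) k <- k - 1L
        if (ks[k] == ks[k + 1]) stop(sprintf("user %s: no strict temporal boundary", u))
        train <- c(train, ord[seq_len(k)])
        test <- c(test, ord[(k + 1):length(ord)])
      }
      new_plan(train, test)
    },
    loo = {
      lapply(seq_len(n), function(i) new_plan(setdiff(seq_len(n), i), i, "loo_fold"))
    },
    predefined = {
      if (is.null(params$train_ids) || is.null(params$test_ids)) {
        stop("predefined split needs params$train_ids and params$test_ids")
      }
      new_plan(params$train_ids, params$test_ids)
    }
  )
}
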