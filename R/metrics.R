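#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, over an explicit label
#' set that may include classes never seen in training (unseen-user
#' evaluation) or never predicted.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param class_labels Ordered label set; defaults to the sorted union of
#'   both vectors. Any label outside the set is an error naming it.
#' @return Integer k x k matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, class_labels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true/y_pred length mismatch")
  if (is.null(class_labels)) class_labels <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), class_labels)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  cm <- table(factor(y_true, levels = class_labels),
              factor(y_pred, levels = class_labels))
  structure(matrix(as.integer(cm), nrow = length(class_labels),
                   dimnames = list(true = class_labels, pred = class_labels)),
            class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("need a square confusion matrix")
  if (sum(cm) == 0) stop("empty confusion matrix")
  invisible(cm)
}

#' Overall accuracy from a confusion matrix
#' @param cm Confusion matrix (true rows x predicted columns).
#' @return Fraction of correctly classified samples.
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean per-class recall, averaged only over classes actually present in
#' the truth vector (rows with at least one sample), so evaluations whose
#' label set includes never-observed classes remain well defined.
#'
#' @param cm Confusion matrix.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  check_cm(cm)
  rs <- rowSums(cm)
  present <- rs > 0
  mean(diag(cm)[present] / rs[present])
}

#' Multi-class Matthews correlation coefficient
#'
#' `MCC = (c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the sample count, and `p_k`/`t_k` the predicted/
#' true marginals; equals the Pearson correlation between the one-hot
#' encodings of truth and prediction, and reduces to the classical binary
#' MCC for 2x2 matrices. Defined as 0 when a denominator factor vanishes
#' (e.g. a constant predictor), the standard convention.
#'
#' @param cm Confusion matrix.
#' @return Value in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  check_cm(cm)
  cm <- matrix(as.numeric(cm), nrow = nrow(cm))
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Uniform random-prediction baseline
#'
#' Predicts uniformly at random from the unique classes observed in the
#' training labels. With k balanced classes its expected accuracy is 1/k
#' and its MCC is 0.
#'
#' @param train_labels Labels seen in training.
#' @param n_test Number of predictions to draw.
#' @param seed Integer seed.
#' @return Character vector of `n_test` predictions.
#' @export
random_baseline <- function(train_labels, n_test, seed = 1) {
  classes <- sort(unique(as.character(train_labels)))
  if (!length(classes)) stop("no training labels")
  with_seed(seed, classes[sample.int(length(classes), n_test, replace = TRUE)])
}

#' One-sided Wilcoxon signed-rank test (alternative: a < b)
#'
#' Paired test of whether `a` is stochastically smaller than `b`. Zero
#' differences are dropped (signed-rank convention). For n <= 25 retained
#' pairs the p-value is exact, computed by enumerating the signed-rank-sum
#' distribution via generating-function convolution over doubled midranks
#' (so tied ranks are handled exactly); larger n uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Paired metric vectors of equal length >= 5.
#' @return p-value for the alternative `a < b`.
#' @export
wilcoxon_one_sided <- function(a, b) {
  if (length(a) != length(b)) stop("a/b length mismatch")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- round(2 * r)               # doubled midranks are integers
    total <- sum(r2)
    counts <- c(1, numeric(total))   # counts[s + 1] = #subsets with sum s
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1 - rr)])
      counts <- counts + shifted
    }
    p <- sum(counts[seq_len(round(2 * w_pos) + 1)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm((w_pos - mu + 0.5) / sqrt(sig2))
  }
  min(1, p)
}

#' Bonferroni correction
#'
#' @param p_values Raw p-values.
#' @param m Number of comparisons (>= length of `p_values`).
#' @return Adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be >= number of p-values")
  pmin(1, p_values * m)
}

#' All three evaluation metrics at once
#'
#' @param y_true,y_pred Label vectors.
#' @param class_labels Optional explicit label set.
#' @return Named numeric: `accuracy`, `balanced_accuracy`, `mcc`.
#' @export
classification_metrics <- function(y_true, y_pred, class_labels = NULL) {
  cm <- confusion(y_true, y_pred, class_labels)
  c(accuracy = accuracy(cm), balanced_accuracy = balanced_accuracy(cm),
    mcc = mcc_multiclass(cm))
}
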